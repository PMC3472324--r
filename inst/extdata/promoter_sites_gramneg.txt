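# Synthetic consensus-seeded promoter box site collections (Gram-negative).
# Same canonical hexamer consensus (-35 TTGACA, -10 TATAAT) with a different
# minority-variant mix. Rebuild with build_pspm().
>minus35
TTGACA
TTGACA
TTGACA
TTGACA
TTGACA
TTGACA
TTGACA
TTGACG
TTGCCA
TTCACA
TAGACA
GTGACA
TTGACT
>minus10
TATAAT
TATAAT
TATAAT
TATAAT
TATAAT
TATAAT
TATAAT
TATACT
TAAAAT
TCTAAT
GATAAT
TATAGT
TATAAC
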