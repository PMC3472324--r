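# Synthetic consensus-seeded promoter box site collections (Gram-positive).
# Sites are centred on the canonical sigma70 hexamers (-35 TTGACA, -10 TATAAT
# Pribnow box) with minority variants so the rebuilt PSPM keeps the canonical
# consensus while carrying realistic degeneracy. Rebuild with build_pspm().
>minus35
TTGACA
TTGACA
TTGACA
TTGACA
TTGACA
TTGACA
TTGACA
TTGACT
TTGATA
TTTACA
TGGACA
CTGACA
TTGACC
>minus10
TATAAT
TATAAT
TATAAT
TATAAT
TATAAT
TATAAT
TATAAT
TATAAA
TACAAT
TGTAAT
CATAAT
TATGAT
TATTAT
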