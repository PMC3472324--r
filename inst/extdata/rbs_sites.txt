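# Synthetic anti-Shine-Dalgarno-derived ribosome binding site collection,
# seeded on the AGGAGG consensus. Rebuild with build_pspm().
>rbs
AGGAGG
AGGAGG
AGGAGG
AGGAGG
AGGAGG
AGGAGG
AGGAGG
AGGAGA
AGAAGG
GGGAGG
AGGTGG
AGGAAG
AAGAGG
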