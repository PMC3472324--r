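# regumine

Regulatory annotation and regulon transfer for bacterial genomes.

Bacterial transcription is organised around a small vocabulary of DNA
signals: transcription-factor binding sites (TFBSs) upstream of the
genes/operons a regulator controls, sigma70 promoters built from a −35
hexamer (consensus `TTGACA`) and a −10 Pribnow box (consensus `TATAAT`)
separated by a 16–18 nt spacer, Shine–Dalgarno ribosome binding sites
(`AGGAGG`-like) ahead of start codons, and rho-independent terminators
(stem-loop + U-rich tail). `regumine` detects all of these and, on top of
them, answers the comparative question biologists actually ask: *given a
regulon characterised in one organism, which genes form the corresponding
regulon in my genome?*

## The method in brief

**Motif scoring.** Aligned binding sites become a position-specific
probability matrix (PSPM); against a background composition *b* this yields
a log-odds position weight matrix, `PWM(j, a) = log2(p'(j, a) / b_a)` (bits).
Scan cutoffs are stated as p-values and converted to score thresholds
*exactly*, by dynamic programming over the discretised score distribution of
a random background word (1/1000-bit lattice) — no Gaussian or permutation
approximations.

**Promoters.** The two boxes are scanned independently at a per-box
p ≤ 1e-3, then paired: a complete promoter requires a spacer of 16–18 nt
between the boxes and is scored by the summed box scores; unpaired boxes are
reported as incomplete calls. The TSS is placed 10 nt downstream of the −10
box start.

**Regulon transfer** (`mine_regulon()`) runs two independent evidence
channels: exact Smith–Waterman protein homology (BLOSUM62, affine gaps 11/1,
Karlin–Altschul E-values, best hit at E ≤ 1e-20) and a scan of each operon's
upstream region for the known TFBS (p ≤ 1e-5). The union of both pools is
handed to a ZOOPS expectation-maximisation motif search, and final members
must carry a site of the refined motif (p ≤ 1e-5). Every step is
deterministic, including EM seeding.

A synthetic-genome simulator (`simulate_genome()`) plants genes, a diverged
regulon protein family, TFBS instances and promoter boxes with full truth
tables, so the complete pipeline is testable offline against known ground
truth.

## Worked example

```r
library(regumine)

sim  <- simulate_genome(sim_spec(rng_seed = 7))
sim$genome
#> genome_record SIMGENOME  linear  23641 bp  50 features

sim$regulon$tfbs
#> TFBS entry simTF [source_organism]  width=15  consensus=AATTTTCTGAAAATT  cutoff p<=1e-05 (score 13.175 bits)

pred <- mine_regulon(sim$regulon, sim$genome)
pred
#> regulon_prediction simTF in SIMGENOME
#>   pool Ia (homology): 4 operons
#>   pool Ib (known TFBS): 8 operons
#>   pool II (final, refined-motif gated): 8 operons
#>   refined motif: AATTTTCAGAAAATT (width 15, 8 sites)
#>   members: gene_002, gene_015, gene_019, gene_026, gene_028, gene_031, gene_039, gene_042

truth <- sim$truth$regulon_members$feature_id
c(recall    = mean(truth %in% pred$pool_II),
  precision = mean(pred$pool_II %in% truth))
#>    recall precision
#>         1         1
```

Reading the output: 4 of the 8 planted members were recovered by protein
homology alone (the family is 20% diverged per residue, and best-hits
collide when members resemble each other), all 8 by the TFBS scan; the
refined 15-mer motif — a CodY-box-like `AATTTTCWGAAAATT` with 29 bits of
information content — then confirms exactly the 8 planted members, i.e.
perfect recall and precision on this replicate.

The same flow runs from the shell:

```sh
Rscript inst/cli/regumine.R simulate --seed 7 --out-dir demo
Rscript inst/cli/regumine.R mine-regulon \
  --genome demo/simulated.gbk --regulon demo/regulon_members.faa \
  --library demo/simulated_tfbs.meme --tf simTF --out-dir demo
```

Other entry points: `annotate_intergenic()` (whole-genome TFBS + promoter +
RBS + terminator annotation, GFF3/TSV output), `mine_multi()` (members ×
genomes conservation-tier grid), `discover_motifs()`, `find_promoters()`,
`find_terminators()`, `read_genbank()` / `read_fasta()` /
`read_motif_library()`.

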