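---
title: "Methods: promoter, binding-site and regulon mining in regumine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter, binding-site and regulon mining in regumine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regumine)
```

# Scope and model overview

`regumine` annotates the regulatory landscape of bacterial genomes and
transfers known regulons between organisms. Its computational core is built
from four pieces:

1. **TFBS models** — position-specific probability matrices (PSPMs) built
   from aligned binding sites, converted to base-2 log-odds position weight
   matrices (PWMs) against a background composition, with *exact* p-value
   score thresholds computed by dynamic programming.
2. **Promoter calls** — independent scans for the two sigma70 hexamer boxes
   (-35, consensus TTGACA; -10 Pribnow box, consensus TATAAT) paired under a
   16-18 nt spacer constraint.
3. **De-novo motif discovery** — expectation-maximisation under the ZOOPS
   model (zero or one site per sequence) on upstream intergenic regions.
4. **Homology transfer** — exact Smith-Waterman local alignment with affine
   gaps and an analytic Karlin-Altschul E-value, mapped to conservation
   tiers.

The all-in-one flow (`mine_regulon()`) combines channels 1 and 4 as two
independent evidence sources, refines the motif de novo on the pooled
candidate regions, and gates final membership on carrying a site of the
refined motif.

# Coordinates

All coordinates are 1-based inclusive on the forward strand, the
GenBank/GFF3 convention. This makes file I/O an identity mapping and matches
`substring()` semantics in R; upstream regions additionally carry their own
gene-oriented local frame, with `region_to_genome()` converting back.

# Motif scoring

## PSPM and PWM construction

`build_pspm()` estimates column probabilities as
`(count + pseudocount) / (n_sites + 4 * pseudocount)`. `pspm_to_pwm()` forms
`log2(p' / bg)` with the background-weighted regularisation
`p' = (p + c * bg_b) / (1 + c)`; with total pseudocount `c = 0.01` a unit
column maps to `log2(0.9925/0.25)` under uniform background. Scores are in
bits throughout; no natural-log scoring is used anywhere.

Gapped dyad sites (e.g. the WalR-type TGTAA-n6-TGTAA box) are represented as
full-width PSPMs whose spacer columns simply carry the composition of the
sites' spacers — no explicit gap model. This matches what alignment-based
site collections produce and keeps scanning uniform.

## Exact score thresholds

A scan cutoff is stated as a p-value: the probability that a random
background word of the motif's width scores at or above the threshold.
`score_threshold()` discretises the PWM to a lattice (default 1/1000 bit, a
config knob recorded in the entry) and convolves the per-column score
distributions exactly. The returned threshold is the smallest *achievable*
lattice score whose upper tail is within the requested p-value, so it is
conservative at the stated granularity and agrees with full `4^w`
enumeration (asserted in the test suite for widths up to 8). Scanning
decides hits on the continuous window score; reported p-values are looked up
at the window's lattice score on the same table, so they match enumeration
exactly. Ambiguous bases (N) score 0 bits, i.e. behave as background.

Per-entry cutoffs default to p <= 1e-5 and are stored with the motif in the
library format, because scan stringency is a property of the motif, not of
the scan; raw-score cutoffs can be emulated by setting the entry's
`cutoff_score` directly.

## Motif library format

Libraries are read and written as MEME-minimal text with probabilities at 6
decimals and the per-motif cutoff carried on a `# cutoff_pvalue=` comment
line, making the round trip lossless for name, width, site count,
probabilities and cutoff. Parsed columns off by at most 1e-3 are
renormalised (silently within print precision, with a warning beyond);
larger deviations are an error naming the line.

# Promoter model

The -35 and -10 boxes are scanned separately on the gene-facing strand at a
per-box p-value of 1e-3. Promoter boxes are individually weak motifs; a
stricter per-box threshold would discard real boxes, so significance lives
in the *pairing*: every hit pair whose spacer (gap between the -35 hexamer's
end and the -10 hexamer's start) lies in 16-18 nt becomes a complete call
scored by the sum of the box scores, and unpaired hits are reported as
incomplete calls rather than dropped. The spacer window acts as the duration
constraint that a two-state promoter HMM would impose; a trained HMM
topology is not part of this package because no published topology for this
tool class is available to rebuild from. Ranking by summed box score (rather
than a joint probability) was chosen for transparency; the two orderings
agree except between calls with nearly equal evidence.

The packaged -35/-10 site collections are synthetic, consensus-seeded sets
(13 sites each) whose consensus is exactly the canonical hexamer, shipped as
plain text so the models are rebuildable with `build_pspm()`; Gram-positive
and Gram-negative variants differ in their minority-variant mix. The TSS is
placed 10 nt downstream of the -10 box start (4 nt past the hexamer), the
canonical Pribnow-box-to-TSS distance; the offset is configurable.

# RBS, start adjustment, terminators

The ribosome-binding-site model is a width-6 AGGAGG-seeded PWM scanned in
the 4-15 nt spacing window upstream of the start codon; ties go to the
window nearer the start. Minimum reported score defaults to 5 bits.
`adjust_start()` applies only to naive ORF calls (never to annotated genes):
among in-frame alternative starts within 30 nt it picks the one with the
best RBS score, keeping the original start unless strictly beaten.

The terminator caller is a deliberately simplified stem-loop + U-tail
scorer, not a thermodynamic model: stems of 4-12 bp score GC=3, AT=2 and GU
wobble pairs 1 (their low score being the penalty), mismatches are
forbidden, loops of 3-9 nt cost 1 point per nt, and the tail score is a
position-weighted T count over the 8 nt 3' of the stem (weights 1.5 down to
0.8). Calls at total score >= 12 are reported — with these pair scores a
minimal perfect 4-bp GC stem plus a modest tail is needed to qualify. All
qualifying stem-loops are reported by default; `reduce = TRUE` keeps the
best call per overlapping cluster for annotation output, which is flagged
`simplified-transterm` in the GFF source column.

# ZOOPS EM discovery

`discover_motifs()` runs EM per width with a sequence-level mixture: a
sequence either has no site (probability `1 - gamma`) or exactly one site
uniform over its windows (both strands by default, matching promoter-region
biology). Seeding is deterministic: candidate words are ranked by the number
of sequences containing them exactly (repeated words are likely motif
instances), a capped candidate set is scored by summed best-window log-odds
under a sharp seed matrix (0.7 consensus / 0.1 elsewhere), and the top
`n_seeds` (default 3) run to convergence (|delta log-likelihood| < 1e-4 bits
or 100 iterations). Determinism by construction means the `rng_seed` field
is provenance only; identical inputs give bit-identical output, and the EM
log-likelihood trace is attached to each result (the suite asserts it never
decreases).

The reported PSPM is rebuilt from the hard site assignments (responsibility
> 0.5), so the site list and the matrix are mutually consistent by
reconstruction. Significance is `log2_evalue = -(LLR - 3 w log2(N))` with
`LLR` the summed site log-odds in bits, `w` the width and `N` the number of
scanned windows — a BIC-like surrogate used only for ranking across widths.
It is *not* comparable to MEME's E-value; `evalue_like = 2^log2_evalue` can
underflow to zero for strong motifs, which is why ranking and tests use the
log-scale field.

`refine_library_entry()` mechanises the comparison of a discovered motif
with a reference site model: mean per-column Pearson correlation over the
best ungapped alignment (all offsets with the narrower matrix fully
contained, both orientations). Zero-variance columns correlate 1 only with
an equal column, else 0, so a uniform matrix scores ~0 against any informative
reference.

# Homology and E-values

`local_align()` is an exact Gotoh Smith-Waterman in C++ with BLOSUM62 (from
Biostrings' packaged data) and affine gaps costing `open + L * extend`
(defaults 11/1, the classic gapped protein defaults). E-values use the
analytic Karlin-Altschul form `E = K m n exp(-lambda S)` with the published
gapped BLOSUM62 parameters lambda = 0.267, K = 0.041; `n` is the total
residue count of the searched proteome. BLAST's composition-based statistics,
seeding and masking are deliberately not reproduced — at desk scale the
search is exact all-vs-all — so E-values are approximate where BLAST's would
be rescaled. Conservation tiers default to strong <= 1e-50 < moderate <=
1e-20 < weak <= 1e-5 < absent, with 1e-20 as the conventional
"high-similarity" transfer cutoff.

# The all-in-one flow

`mine_regulon()` collects candidate operons (consecutive same-strand genes
with gaps <= 50 nt, a standard bacterial heuristic and a config knob; the
candidate unit is the operon's lead-gene upstream region) through two
channels: pool Ia, operons whose proteins receive a best hit at E <= 1e-20
from any regulon member; pool Ib, operons whose upstream region (up to 300
nt, truncated at any neighbouring feature boundary, plus the first 20 nt of
the gene) carries the known TFBS at p <= 1e-5. The pools are **unioned**
before refinement (configurable to intersection): the union preserves
members detectable by only one channel, and the refined-motif gate supplies
the specificity the union gives up. Discovery runs at the known TFBS's width
when one is given — the step is a refinement of a known site, not blind
discovery — and sweeps 6-18 otherwise. Final membership (pool II) requires a
site of the top refined motif at p <= 1e-5, after which member regions are
annotated with promoter, RBS and terminator calls. The scan background is
estimated from all upstream regions of the target genome, the natural
intergenic composition model.

Upstream extraction stops at the nearest feature boundary regardless of its
strand (configurable in principle to same-strand-only): a neighbouring gene
body is never regulatory sequence for the anchor gene, whatever its
orientation.

# The simulator and what it does (not) show

`simulate_genome()` builds a linear genome of alternating intergenic spacers
and genes with random strands. Regulon member proteins derive from a common
ancestor at 20% per-residue divergence (both the planted targets and the
"source organism" definition, so query-target identity is realistic rather
than perfect); genes are back-translated with uniformly sampled synonymous
codons (bacterial code). Each regulon gene's upstream region carries one
TFBS instance sampled from the planted matrix (default: the CodY-box-like
degenerate 15-mer) with a 5% per-position mutation rate, placed so promoter
block and site never collide; every gene optionally gets a canonical
TTGACA-N17-TATAAT promoter. The standard conditions are 50 genes (~100
codons each), ~150 nt intergenic spacers and an 8-member regulon. A planted
site must belong unambiguously to its gene, so the non-regulon neighbour
across a planted spacer is oriented away from it; two adjacent regulon genes
may still share a divergent spacer. The whole simulation is a deterministic
function of the spec including its seed.

What passing on simulated data does **not** show: real intergenic DNA is not
i.i.d. background (bacterial genomes are AT-skewed with phased signals);
real regulons share operons and overlapping regulatory sites; real motif
instances co-vary with spacer length and flanking context; and homology in
real genomes includes paralogs and domain-level similarity that exact SW
best-hits do not disambiguate. The simulation validates the machinery and
its contracts, not biological recall on any particular organism.

# Numerical choices and degenerate inputs

* Score lattice 1/1000 bit; thresholds conservative at that granularity.
* `pvalue = 1` admits everything (threshold = minimum score); `pvalue <= 0`
  is an error.
* Sequences shorter than a motif yield empty hit sets, not errors; an
  all-gene genome yields an empty, valid annotation set.
* Fewer than two candidate operons cannot support motif refinement:
  `mine_regulon()` then returns the evidence pools with an empty final pool.
  A regulon with neither a TFBS nor any homology hit has no evidence channel
  at all and is an error.
* EM ties and seed ordering are broken lexicographically, so all outputs are
  reproducible without seed sweeps.
* Problem sizes in the validation suite (2 kb scan sequences, widths <= 12
  against the naive scanner, 4^w enumeration up to width 8, 20 simulation
  replicates for the end-to-end check) were chosen as the smallest sizes at
  which each property is convincingly exercised.

# Known limitations

* The naive ORF caller is a stand-in for a real gene finder and is flagged
  as such in its output; it reports maximal ORFs only.
* No dinucleotide or higher-order background models.
* Terminator calls ignore free-energy thermodynamics and secondary-structure
  alternatives.
* E-values are analytic approximations; counts transferred from published
  BLAST-based analyses can differ by small amounts near any cutoff.
* Single-motif discovery only (best motif per width; no iterative erasure).
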