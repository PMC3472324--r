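Package: regumine
Title: Bacterial Promoter Element, Binding-Site and Regulon Mining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolbox for regulatory annotation of bacterial genomes: builds
    transcription-factor binding-site (TFBS) libraries as probability and
    log-odds matrices with exact p-value score thresholds, scans genomes and
    upstream intergenic regions for TFBS, predicts sigma70-type promoters as
    paired -35/-10 hexamer boxes under a 16-18 nt spacer constraint, detects
    Shine-Dalgarno ribosome binding sites and rho-independent transcription
    terminators, and transfers known regulons to a query genome by combining
    Smith-Waterman protein homology with motif evidence and de-novo ZOOPS EM
    motif refinement. Includes a deterministic synthetic-genome simulator with
    planted regulatory elements for end-to-end validation, GenBank/FASTA input,
    GFF3 output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    jsonlite
Config/testthat/edition: 3
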