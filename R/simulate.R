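# Synthetic genome generator: builds a fully specified bacterial-like genome
# with genes, a planted regulon protein family derived from a common
# ancestor, planted TFBS instances sampled from a given probability matrix,
# and optional planted sigma70 promoter boxes — together with truth tables,
# so every downstream prediction can be scored against known ground truth.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

#' Degenerate CodY-box-like PSPM
#'
#' Expansion of the degenerate consensus AATTTTCWGAAAATT (W = A/T at
#' position 8): a width-15 matrix with unit columns everywhere except the
#' half-A/half-T column 8. Used as the default planted TFBS of the
#' simulator.
#'
#' @return A `pspm`.
#' @export
cody_box_pspm <- function() {
  build_pspm(c("AATTTTCAGAAAATT", "AATTTTCTGAAAATT"))
}

#' Simulation specification
#'
#' The defaults define the standard study conditions used throughout the
#' package's validation: a 50-gene genome with an 8-member regulon, a
#' CodY-box-like planted TFBS, 20% protein family divergence and planted
#' canonical promoter boxes.
#'
#' @param n_genes Number of genes (default 50).
#' @param mean_gene_len Mean gene length in nt (default 300, i.e. ~100
#'   codons).
#' @param mean_intergenic_len Target mean intergenic length in nt
#'   (default 150); must be at least 60.
#' @param regulon_size Number of planted regulon members (default 8; must
#'   not exceed `n_genes`).
#' @param tfbs_pspm `pspm` the planted sites are sampled from (default
#'   [cody_box_pspm()]).
#' @param tfbs_mutation_rate Extra per-position substitution rate applied to
#'   each planted site (default 0.05).
#' @param plant_promoters Plant TTGACA-N17-TATAAT boxes upstream of every
#'   gene (default TRUE).
#' @param homolog_divergence Per-residue substitution rate between the
#'   ancestor and each family member (default 0.2).
#' @param rng_seed Integer seed; the whole simulation is a deterministic
#'   function of the spec.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(n_genes = 50L, mean_gene_len = 300L,
                     mean_intergenic_len = 150L, regulon_size = 8L,
                     tfbs_pspm = cody_box_pspm(), tfbs_mutation_rate = 0.05,
                     plant_promoters = TRUE, homolog_divergence = 0.2,
                     rng_seed = 1L) {
  if (regulon_size > n_genes) stop("regulon_size must not exceed n_genes")
  if (mean_intergenic_len < 60L)
    stop("infeasible packing: mean_intergenic_len below 60 nt cannot host the planted elements")
  if (mean_gene_len < 60L) stop("infeasible packing: mean_gene_len below 60 nt")
  stopifnot(tfbs_mutation_rate >= 0, tfbs_mutation_rate <= 1,
            homolog_divergence >= 0, homolog_divergence <= 1)
  structure(list(n_genes = as.integer(n_genes),
                 mean_gene_len = as.integer(mean_gene_len),
                 mean_intergenic_len = as.integer(mean_intergenic_len),
                 regulon_size = as.integer(regulon_size),
                 tfbs_pspm = tfbs_pspm,
                 tfbs_mutation_rate = tfbs_mutation_rate,
                 plant_promoters = plant_promoters,
                 homolog_divergence = homolog_divergence,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_spec")
}

.random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

.mutate_protein <- function(protein, rate) {
  if (rate == 0) return(protein)
  aa <- strsplit(protein, "")[[1L]]
  hit <- which(stats::runif(length(aa)) < rate)
  for (i in hit) aa[i] <- sample(setdiff(AA20, aa[i]), 1L)
  paste(aa, collapse = "")
}

.mutate_dna <- function(site, rate) {
  if (rate == 0) return(site)
  nt <- strsplit(site, "")[[1L]]
  hit <- which(stats::runif(length(nt)) < rate)
  for (i in hit) nt[i] <- sample(setdiff(DNA_BASES, nt[i]), 1L)
  paste(nt, collapse = "")
}

.sample_site <- function(pspm) {
  p <- unclass(pspm)
  paste(vapply(seq_len(ncol(p)), function(j)
    sample(DNA_BASES, 1L, prob = p[, j]), ""), collapse = "")
}

# reverse translation with uniformly sampled synonymous codons (code 11)
.backtranslate <- function(protein) {
  code <- Biostrings::getGeneticCode("11")
  code <- code[code != "*"]
  aa <- strsplit(protein, "")[[1L]]
  codons <- vapply(aa, function(a) {
    opts <- names(code)[code == a]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, "")
  paste0("ATG", paste(codons[-1L], collapse = ""), "TAA")
}

.random_protein <- function(n_aa) {
  paste(c("M", sample(AA20, n_aa - 1L, replace = TRUE)), collapse = "")
}

#' Simulate a genome with planted regulatory truth
#'
#' Builds a linear genome of alternating intergenic spacers and genes. Genes
#' get random strands; regulon members encode proteins derived from a common
#' ancestor at the spec's divergence rate, and their upstream regions carry a
#' TFBS instance sampled from the spec's matrix (further mutated at the
#' per-site rate). When `plant_promoters` is set, every gene's upstream
#' region carries a canonical TTGACA-N17-TATAAT promoter. The matching
#' source-organism regulon (independently diverged member proteins plus a
#' TFBS library entry built from independently sampled sites) is returned
#' alongside, so the full regulon-transfer pipeline can be scored against
#' the planted truth. The simulation is a pure function of the spec,
#' including its seed.
#'
#' @param spec A [sim_spec()].
#' @return List: `genome` (a [genome_record()]), `regulon` (a
#'   [regulon_definition()]), `truth` (list of data frames: `regulon_members`,
#'   `tfbs_sites`, `promoters`) and `spec`.
#' @export
simulate_genome <- function(spec = sim_spec()) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$rng_seed)

  n <- spec$n_genes
  n_aa <- max(30L, round(spec$mean_gene_len / 3))
  tf_w <- ncol(spec$tfbs_pspm)

  regulon_idx <- sort(sample(n, spec$regulon_size))
  ancestor <- .random_protein(n_aa)
  # initiator stays M so the stored translation matches the encoded CDS
  diverge <- function(p) {
    m <- .mutate_protein(p, spec$homolog_divergence)
    substr(m, 1L, 1L) <- "M"
    m
  }
  target_members <- vapply(seq_len(spec$regulon_size), function(i)
    diverge(ancestor), "")
  source_members <- vapply(seq_len(max(1L, spec$regulon_size)), function(i)
    diverge(ancestor), "")

  strands <- sample(c("+", "-"), n, replace = TRUE)
  # a planted TFBS must belong unambiguously to its regulon gene: the
  # non-regulon neighbour across the planted spacer is made to face away,
  # so no other gene's upstream region covers the site (two adjacent
  # regulon genes may still legitimately share a divergent spacer)
  for (i in regulon_idx) {
    if (strands[i] == "+" && i > 1L && !((i - 1L) %in% regulon_idx) &&
        strands[i - 1L] == "-") strands[i - 1L] <- "+"
    if (strands[i] == "-" && i < n && !((i + 1L) %in% regulon_idx) &&
        strands[i + 1L] == "+") strands[i + 1L] <- "-"
  }
  proteins <- character(n)
  proteins[regulon_idx] <- target_members
  for (i in setdiff(seq_len(n), regulon_idx))
    proteins[i] <- .random_protein(max(30L, round(stats::rnorm(1, n_aa, n_aa / 10))))
  cds <- vapply(proteins, .backtranslate, "", USE.NAMES = FALSE)

  # per-gene planted upstream block, gene-oriented, ending 1 nt before the
  # start codon: [TFBS][20 random][TTGACA][N17][TATAAT][15 random]
  blocks <- character(n)
  tfbs_site <- rep(NA_character_, n)
  tfbs_off_in_block <- integer(n)     # 1-based offset of the site in its block
  prom_off_in_block <- integer(n)     # offset of the -35 box (NA if none)
  for (i in seq_len(n)) {
    block <- ""
    if (spec$plant_promoters)
      block <- paste0("TTGACA", .random_dna(17L), "TATAAT", .random_dna(15L))
    prom_off_in_block[i] <- if (spec$plant_promoters) 1L else NA_integer_
    if (i %in% regulon_idx) {
      site <- .mutate_dna(.sample_site(spec$tfbs_pspm), spec$tfbs_mutation_rate)
      tfbs_site[i] <- site
      block <- paste0(site, .random_dna(20L), block)
      tfbs_off_in_block[i] <- 1L
      if (spec$plant_promoters) prom_off_in_block[i] <- tf_w + 21L
    }
    blocks[i] <- block
  }

  # assemble: spacer_1 gene_1 spacer_2 gene_2 ... gene_n spacer_{n+1}
  # gene i "+" plants its block at the tail of spacer i; gene i "-" plants
  # the reverse complement of its block at the head of spacer i+1.
  mid_min <- max(60L, spec$mean_intergenic_len - 90L)
  mid_max <- spec$mean_intergenic_len + 30L
  spacers <- character(n + 1L)
  head_block <- character(n + 1L)  # rc block of a "-" gene on the left
  tail_block <- character(n + 1L)  # block of a "+" gene on the right
  for (s in seq_len(n + 1L)) {
    left_gene <- s - 1L
    right_gene <- s
    hb <- if (left_gene >= 1L && strands[left_gene] == "-")
      revcomp(blocks[left_gene]) else ""
    tb <- if (right_gene <= n && strands[right_gene] == "+")
      blocks[right_gene] else ""
    head_block[s] <- hb
    tail_block[s] <- tb
    spacers[s] <- paste0(hb, .random_dna(sample(mid_min:mid_max, 1L)), tb)
  }

  seq_parts <- character(2L * n + 1L)
  feats <- vector("list", n)
  pos <- 0L
  truth_tfbs <- list()
  truth_prom <- list()
  for (i in seq_len(n)) {
    spacer <- spacers[i]
    seq_parts[2L * i - 1L] <- spacer
    pos <- pos + nchar(spacer)
    gene_seq <- if (strands[i] == "+") cds[i] else revcomp(cds[i])
    gstart <- pos + 1L
    gend <- pos + nchar(gene_seq)
    seq_parts[2L * i] <- gene_seq
    pos <- gend
    id <- sprintf("gene_%03d", i)
    feats[[i]] <- gene_feature(id, id, gstart, gend, strands[i],
                               translation = sub("\\*?$", "", proteins[i]),
                               source = "synthetic")
    # forward-genome coordinates of the planted elements
    block_len <- nchar(blocks[i])
    if (block_len) {
      if (strands[i] == "+") {
        block_start <- gstart - block_len   # block ends right before gene
        loc <- function(off, w) c(block_start + off - 1L,
                                  block_start + off + w - 2L)
      } else {
        # rc block at head of spacer i+1, which begins at gend + 1
        block_start <- gend + 1L
        loc <- function(off, w) c(block_start + block_len - off - w + 1L,
                                  block_start + block_len - off)
      }
      if (i %in% regulon_idx) {
        p <- loc(tfbs_off_in_block[i], tf_w)
        truth_tfbs[[length(truth_tfbs) + 1L]] <- data.frame(
          feature_id = id, start = p[1L], end = p[2L], strand = strands[i],
          site_seq = tfbs_site[i], stringsAsFactors = FALSE)
      }
      if (!is.na(prom_off_in_block[i])) {
        p35 <- loc(prom_off_in_block[i], 6L)
        p10 <- loc(prom_off_in_block[i] + 23L, 6L)
        truth_prom[[length(truth_prom) + 1L]] <- data.frame(
          feature_id = id, minus35_start = p35[1L], minus35_end = p35[2L],
          minus10_start = p10[1L], minus10_end = p10[2L],
          strand = strands[i], stringsAsFactors = FALSE)
      }
    }
  }
  seq_parts[2L * n + 1L] <- spacers[n + 1L]
  genome <- genome_record("SIMGENOME", paste(seq_parts, collapse = ""),
                          do.call(rbind, feats))

  # source-organism TFBS library entry from independently sampled sites
  tfbs <- NULL
  if (spec$regulon_size > 0L) {
    lib_sites <- vapply(1:10, function(k)
      .mutate_dna(.sample_site(spec$tfbs_pspm), spec$tfbs_mutation_rate), "")
    tfbs <- tfbs_entry("simTF", build_pspm(lib_sites),
                       organism = "source_organism", cutoff_pvalue = 1e-5,
                       pseudocount = 0.25)
  }
  regulon <- if (spec$regulon_size > 0L) {
    regulon_definition("simTF",
                       stats::setNames(source_members,
                                       sprintf("src_member_%02d",
                                               seq_along(source_members))),
                       tfbs = tfbs, source_organism = "source_organism")
  } else NULL

  bind_or_empty <- function(lst, proto) if (length(lst)) do.call(rbind, lst) else proto
  truth <- list(
    regulon_members = data.frame(
      feature_id = sprintf("gene_%03d", regulon_idx),
      protein = proteins[regulon_idx], stringsAsFactors = FALSE),
    tfbs_sites = bind_or_empty(truth_tfbs, data.frame(
      feature_id = character(), start = integer(), end = integer(),
      strand = character(), site_seq = character(), stringsAsFactors = FALSE)),
    promoters = bind_or_empty(truth_prom, data.frame(
      feature_id = character(), minus35_start = integer(),
      minus35_end = integer(), minus10_start = integer(),
      minus10_end = integer(), strand = character(), stringsAsFactors = FALSE)))
  list(genome = genome, regulon = regulon, truth = truth, spec = spec)
}

#' Write a minimal GenBank fixture file
#'
#' Emits a minimal but valid GenBank flat file (LOCUS, FEATURES with CDS
#' locus_tag/translation qualifiers, ORIGIN) for a simulated genome so the
#' GenBank reader can be exercised round-trip. This is a fixture writer, not
#' a general-purpose GenBank exporter.
#'
#' @param genome A [genome_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank_fixture <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  L <- nchar(genome$sequence)
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s   BCT 01-JAN-2000",
                     genome$accession, L, genome$topology), con)
  writeLines(sprintf("DEFINITION  synthetic fixture genome %s.", genome$accession), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", L), con)
  f <- genome$features
  for (i in seq_len(nrow(f))) {
    loc <- sprintf("%d..%d", f$start[i], f$end[i])
    if (f$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     CDS             %s", loc), con)
    writeLines(sprintf("                     /locus_tag=\"%s\"", f$locus_tag[i]), con)
    if (!is.na(f$translation[i])) {
      tr <- sprintf("/translation=\"%s\"", f$translation[i])
      chunks <- substring(tr, seq(1L, nchar(tr), by = 58L),
                          pmin(nchar(tr), seq(1L, nchar(tr), by = 58L) + 57L))
      writeLines(paste0("                     ", chunks), con)
    }
  }
  writeLines("ORIGIN", con)
  for (from in seq(1L, L, by = 60L)) {
    chunk <- substr(genome$sequence, from, min(L, from + 59L))
    groups <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                        pmin(nchar(chunk), seq(1L, nchar(chunk), by = 10L) + 9L))
    writeLines(sprintf("%9d %s", from, tolower(paste(groups, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}
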