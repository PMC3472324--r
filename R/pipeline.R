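# The all-in-one flow: candidate regulon members are collected through two
# independent evidence channels (protein homology to the known regulon;
# presence of the known TFBS upstream), a de-novo motif refinement is run on
# the pooled upstream regions, and the final membership is gated on carrying
# a site of the refined motif.

#' Regulon definition
#'
#' @param tf_name Transcription factor name.
#' @param member_proteins Named character vector of member protein sequences
#'   (at least one).
#' @param tfbs Optional [tfbs_entry()] for the TF's binding site (width 6-18).
#' @param source_organism Label of the organism the regulon is known in.
#' @return A `regulon_definition` list.
#' @export
regulon_definition <- function(tf_name, member_proteins, tfbs = NULL,
                               source_organism = "unknown") {
  stopifnot(length(member_proteins) >= 1L)
  if (!is.null(tfbs)) {
    w <- ncol(tfbs$pspm)
    if (w < 6L || w > 18L) stop("TFBS width must be within 6-18")
  }
  if (is.null(names(member_proteins)))
    names(member_proteins) <- sprintf("%s_member_%d", tf_name,
                                      seq_along(member_proteins))
  structure(list(tf_name = tf_name, source_organism = source_organism,
                 member_proteins = member_proteins, tfbs = tfbs),
            class = "regulon_definition")
}

#' Pipeline configuration
#'
#' @param evalue_cutoff Homology-channel best-hit cutoff (default 1e-20, the
#'   conventional "high similarity" protein-transfer threshold).
#' @param scan_pvalue TFBS-channel scan cutoff (default 1e-5).
#' @param refined_pvalue Refined-motif membership gate (default 1e-5).
#' @param max_upstream_nt,gene_prefix_nt Upstream extraction window
#'   (defaults 300 and 20).
#' @param operon_gap_nt Operon grouping gap (default 50).
#' @param pool_combine `"union"` (default) or `"intersection"` of the two
#'   evidence channels before motif refinement.
#' @param gram Gram stain for the promoter model.
#' @param discovery Optional [discovery_config()]; when NULL the refinement
#'   search uses the known TFBS's width (blind 6-18 sweep if no TFBS).
#' @param scheme A [scoring_scheme()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(evalue_cutoff = 1e-20, scan_pvalue = 1e-5,
                            refined_pvalue = 1e-5, max_upstream_nt = 300L,
                            gene_prefix_nt = 20L, operon_gap_nt = 50L,
                            pool_combine = c("union", "intersection"),
                            gram = c("positive", "negative"),
                            discovery = NULL, scheme = scoring_scheme()) {
  structure(list(evalue_cutoff = evalue_cutoff, scan_pvalue = scan_pvalue,
                 refined_pvalue = refined_pvalue,
                 max_upstream_nt = as.integer(max_upstream_nt),
                 gene_prefix_nt = as.integer(gene_prefix_nt),
                 operon_gap_nt = as.integer(operon_gap_nt),
                 pool_combine = match.arg(pool_combine),
                 gram = match.arg(gram),
                 discovery = discovery, scheme = scheme),
            class = "pipeline_config")
}

.operon_id <- function(op) op$lead_gene

.target_proteome <- function(genome) {
  f <- genome$features
  prot <- f$translation
  ok <- !is.na(prot)
  stats::setNames(prot[ok], f$feature_id[ok])
}

#' Mine a known regulon in a target genome
#'
#' Runs the two-channel regulon transfer: pool Ia holds operons with a
#' best-hit protein match (E <= `evalue_cutoff`) to any regulon member; pool
#' Ib holds operons whose upstream region carries the regulon's known TFBS at
#' its scan cutoff. De-novo motif refinement ([discover_motifs()]) is run on
#' the upstream regions of the combined pool, and the final pool II keeps the
#' operons whose upstream region contains a site of the top refined motif at
#' p <= `refined_pvalue`. Pool-II regions are then annotated with promoter,
#' RBS and terminator calls.
#'
#' @param regulon A [regulon_definition()].
#' @param target A [genome_record()] with translated features (run
#'   [call_orfs()] / [adjust_start()] first for bare DNA).
#' @param cfg A [pipeline_config()].
#' @return A `regulon_prediction`: pools Ia/Ib/II (operon lead-gene ids),
#'   `refined_motif`, per-operon `evidence` data frame, and per-pool-II-gene
#'   `annotations`.
#' @export
mine_regulon <- function(regulon, target, cfg = pipeline_config()) {
  if (nrow(target$features) == 0L)
    stop("target genome has no features; run call_orfs() first")
  operons <- group_operons(target, cfg$operon_gap_nt)
  names(operons) <- vapply(operons, .operon_id, "")
  feature2operon <- stats::setNames(
    rep(names(operons), vapply(operons, function(o) length(o$members), 1L)),
    unlist(lapply(operons, function(o) o$members)))

  # channel Ia: protein homology
  proteome <- .target_proteome(target)
  hits <- if (length(proteome))
    search_proteome(regulon$member_proteins, proteome,
                    cutoff_evalue = cfg$evalue_cutoff, scheme = cfg$scheme)
  else search_proteome(regulon$member_proteins, c(x = "M"), cutoff_evalue = 0)
  pool_Ia <- unique(feature2operon[hits$subject_id])

  if (is.null(regulon$tfbs) && length(pool_Ia) == 0L)
    stop("no evidence channels: regulon has no TFBS and no homology hits")

  regions <- lapply(operons, extract_upstream, genome = target,
                    max_upstream_nt = cfg$max_upstream_nt,
                    gene_prefix_nt = cfg$gene_prefix_nt)

  # channel Ib: known-TFBS scan of upstream regions
  pool_Ib <- character(0)
  tfbs_hits <- list()
  if (!is.null(regulon$tfbs)) {
    entry <- regulon$tfbs
    if (abs(entry$cutoff_pvalue - cfg$scan_pvalue) > 0) {
      entry$cutoff_pvalue <- cfg$scan_pvalue
      entry$cutoff_score <- score_threshold(entry$pwm, cfg$scan_pvalue,
                                            entry$bg, entry$granularity)
    }
    for (id in names(regions)) {
      h <- scan_motif(regions[[id]]$sequence, entry)
      if (nrow(h)) {
        pool_Ib <- c(pool_Ib, id)
        tfbs_hits[[id]] <- h
      }
    }
  }

  pool_cand <- if (cfg$pool_combine == "union") union(pool_Ia, pool_Ib)
  else intersect(pool_Ia, pool_Ib)
  pool_cand <- names(operons)[names(operons) %in% pool_cand]  # genome order

  # de-novo refinement on the pooled upstream regions; with fewer than two
  # candidate regions no motif can be refined and the final pool is empty
  refined <- NULL
  refined_entry <- NULL
  pool_II <- character(0)
  refined_hits <- list()
  if (length(pool_cand) >= 2L) {
    dcfg <- cfg$discovery
    if (is.null(dcfg)) {
      dcfg <- if (!is.null(regulon$tfbs)) {
        w <- ncol(regulon$tfbs$pspm)
        discovery_config(width_min = w, width_max = w)
      } else discovery_config()
    }
    cand_seqs <- vapply(regions[pool_cand], function(r) r$sequence, "")
    bg <- estimate_background(vapply(regions, function(r) r$sequence, ""))
    refined <- discover_motifs(cand_seqs, bg, dcfg)[[1L]]

    refined_entry <- tfbs_entry(paste0(regulon$tf_name, "_refined"),
                                refined$pspm, bg,
                                organism = target$accession,
                                cutoff_pvalue = cfg$refined_pvalue,
                                pseudocount = 0.25)
    for (id in pool_cand) {
      h <- scan_motif(regions[[id]]$sequence, refined_entry)
      if (nrow(h)) {
        pool_II <- c(pool_II, id)
        refined_hits[[id]] <- h
      }
    }
  }

  # annotate pool-II upstream regions
  pmodel <- default_promoter_model(cfg$gram)
  annotations <- lapply(pool_II, function(id) {
    region <- regions[[id]]
    list(region = region,
         tfbs_hits = tfbs_hits[[id]],
         refined_hits = refined_hits[[id]],
         promoters = find_promoters(region, pmodel),
         rbs = find_rbs(region, region$upstream_flank_len + 1L),
         terminators = find_terminators(region$sequence, reduce = TRUE))
  })
  names(annotations) <- pool_II

  evidence <- data.frame(
    operon = names(operons),
    in_pool_Ia = names(operons) %in% pool_Ia,
    in_pool_Ib = names(operons) %in% pool_Ib,
    in_pool_II = names(operons) %in% pool_II,
    best_evalue = NA_real_, best_member = NA_character_,
    tfbs_min_pvalue = NA_real_, refined_min_pvalue = NA_real_,
    stringsAsFactors = FALSE)
  if (nrow(hits)) {
    hit_op <- feature2operon[hits$subject_id]
    for (k in seq_len(nrow(hits))) {
      i <- match(hit_op[k], evidence$operon)
      if (is.na(evidence$best_evalue[i]) || hits$evalue[k] < evidence$best_evalue[i]) {
        evidence$best_evalue[i] <- hits$evalue[k]
        evidence$best_member[i] <- hits$query_id[k]
      }
    }
  }
  for (id in names(tfbs_hits))
    evidence$tfbs_min_pvalue[match(id, evidence$operon)] <-
      min(tfbs_hits[[id]]$pvalue)
  for (id in names(refined_hits))
    evidence$refined_min_pvalue[match(id, evidence$operon)] <-
      min(refined_hits[[id]]$pvalue)

  structure(list(target_genome = target$accession, tf_name = regulon$tf_name,
                 pool_Ia = pool_Ia, pool_Ib = pool_Ib, pool_II = pool_II,
                 refined_motif = refined, refined_entry = refined_entry,
                 evidence = evidence, annotations = annotations,
                 operons = operons, cfg = cfg),
            class = "regulon_prediction")
}

#' @export
print.regulon_prediction <- function(x, ...) {
  cat(sprintf("regulon_prediction %s in %s\n", x$tf_name, x$target_genome))
  cat(sprintf("  pool Ia (homology): %d operons\n", length(x$pool_Ia)))
  cat(sprintf("  pool Ib (known TFBS): %d operons\n", length(x$pool_Ib)))
  cat(sprintf("  pool II (final, refined-motif gated): %d operons\n",
              length(x$pool_II)))
  if (!is.null(x$refined_motif))
    cat(sprintf("  refined motif: %s (width %d, %d sites)\n",
                consensus(x$refined_motif$pspm), x$refined_motif$width,
                nrow(x$refined_motif$sites)))
  if (length(x$pool_II)) cat("  members:", paste(x$pool_II, collapse = ", "), "\n")
  invisible(x)
}

#' Multi-genome regulon mapping
#'
#' [map_regulon()] applied per target genome: the tabular twin of a
#' colour-graded members x genomes conservation grid.
#'
#' @param regulon A [regulon_definition()].
#' @param targets List of [genome_record()] objects (named, or accessions are
#'   used).
#' @param tier_bands,scheme Passed to [map_regulon()].
#' @return List with `tiers` (members x genomes character matrix),
#'   `best_hits` (matrix of best-hit gene ids) and `maps` (the per-genome
#'   [map_regulon()] data frames).
#' @export
mine_multi <- function(regulon, targets,
                       tier_bands = c(strong = 1e-50, moderate = 1e-20,
                                      weak = 1e-5),
                       scheme = scoring_scheme()) {
  stopifnot(length(targets) >= 1L)
  if (is.null(names(targets)))
    names(targets) <- vapply(targets, function(g) g$accession, "")
  maps <- lapply(targets, function(g)
    map_regulon(regulon$member_proteins, .target_proteome(g),
                tier_bands = tier_bands, scheme = scheme))
  members <- names(regulon$member_proteins)
  tiers <- vapply(maps, function(m) as.character(m$tier[match(members, m$member)]),
                  character(length(members)))
  hits <- vapply(maps, function(m) m$subject_id[match(members, m$member)],
                 character(length(members)))
  tiers <- matrix(tiers, nrow = length(members),
                  dimnames = list(members, names(targets)))
  hits <- matrix(hits, nrow = length(members),
                 dimnames = list(members, names(targets)))
  list(tiers = tiers, best_hits = hits, maps = maps)
}

#' Annotate all intergenic regions of a genome
#'
#' For every operon's upstream region: all library TFBS hits, promoter calls,
#' RBS and terminator calls, coordinate-mapped to the forward genome strand.
#'
#' @param genome A [genome_record()] with features.
#' @param library List of [tfbs_entry()] objects (may be empty).
#' @param cfg A [pipeline_config()].
#' @param gff_path Optional path; when given the annotation set is also
#'   written as GFF3.
#' @return Data frame of annotations (GFF-shaped columns plus `region`), or
#'   an empty data frame when the genome has no intergenic nucleotides.
#' @export
annotate_intergenic <- function(genome, library = list(),
                                cfg = pipeline_config(), gff_path = NULL) {
  operons <- tryCatch(group_operons(genome, cfg$operon_gap_nt),
                      error = function(e) list())
  pmodel <- default_promoter_model(cfg$gram)
  rows <- list()
  add <- function(region, type, source, local_start, local_end, score, attrs,
                  local_strand = "+") {
    gc <- region_to_genome(region, local_start, local_end)
    strand <- if (local_strand == "+") gc$strand else
      c("+" = "-", "-" = "+")[[gc$strand]]
    rows[[length(rows) + 1L]] <<- data.frame(
      seqid = genome$accession, source = source, type = type,
      start = gc$start, end = gc$end, score = score, strand = strand,
      attributes = attrs, region = region$anchor_gene,
      stringsAsFactors = FALSE)
  }
  for (op in operons) {
    region <- tryCatch(
      extract_upstream(genome, op, cfg$max_upstream_nt, cfg$gene_prefix_nt),
      error = function(e) NULL)
    if (is.null(region) || region$upstream_flank_len == 0L) next
    for (entry in library) {
      h <- scan_motif(region$sequence, entry)
      for (k in seq_len(nrow(h)))
        add(region, "TF_binding_site", "regumine", h$start[k], h$end[k],
            h$score[k],
            sprintf("tf=%s;pvalue=%s;site=%s", h$tf_name[k],
                    format_pvalue(h$pvalue[k]), h$matched_seq[k]),
            local_strand = h$strand[k])
    }
    pr <- find_promoters(region, pmodel)
    for (k in seq_len(nrow(pr))) {
      if (pr$complete[k]) {
        add(region, "promoter", "regumine",
            pr$minus35_start[k], pr$minus10_end[k], pr$combined_score[k],
            sprintf("spacer=%d;complete=yes;tss=%d", pr$spacer_nt[k],
                    pr$tss[k]))
      } else if (!is.na(pr$minus35_start[k])) {
        add(region, "minus35", "regumine", pr$minus35_start[k],
            pr$minus35_end[k], pr$minus35_score[k], "complete=no")
      } else {
        add(region, "minus10", "regumine", pr$minus10_start[k],
            pr$minus10_end[k], pr$minus10_score[k],
            sprintf("complete=no;tss=%d", pr$tss[k]))
      }
    }
    rbs <- find_rbs(region, region$upstream_flank_len + 1L)
    if (!is.null(rbs))
      add(region, "ribosome_entry_site", "regumine", rbs$start, rbs$end,
          rbs$score, sprintf("spacing=%d;site=%s", rbs$spacing_to_start,
                             rbs$matched_seq))
    term <- find_terminators(region$sequence, reduce = TRUE)
    for (k in seq_len(nrow(term)))
      add(region, "terminator", "simplified-transterm", term$start[k],
          term$end[k], term$total_score[k],
          sprintf("stem=%d;loop=%d;tail_score=%.2f", term$stem_len[k],
                  term$loop_len[k], term$tail_score[k]))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seqid = character(), source = character(), type = character(),
               start = integer(), end = integer(), score = numeric(),
               strand = character(), attributes = character(),
               region = character(), stringsAsFactors = FALSE)
  if (!is.null(gff_path))
    write_gff(out[, setdiff(names(out), "region")], gff_path,
              genome_length = nchar(genome$sequence))
  out
}
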