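# sigma70-type promoter prediction: independent -35/-10 box scans paired
# under a 16-18 nt spacer constraint, TSS placement from the -10 box, plus
# RBS detection and naive-ORF start adjustment.

.read_site_collection <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  heads <- grep("^>", lines)
  out <- list()
  for (i in seq_along(heads)) {
    to <- if (i < length(heads)) heads[i + 1L] - 1L else length(lines)
    out[[sub("^>", "", lines[heads[i]])]] <- lines[(heads[i] + 1L):to]
  }
  out
}

#' Default sigma70 promoter model
#'
#' Both Gram variants ship as rebuildable site collections: the -35 box
#' collection is centred on TTGACA and the -10 (Pribnow) collection on
#' TATAAT; `gram` selects between the two packaged variant mixes. Boxes are
#' width 6 and promoters are accepted only when the -35/-10 spacing is
#' 16-18 nt.
#'
#' @param gram `"positive"` or `"negative"`.
#' @param box_pvalue Per-box scan p-value cutoff (default 1e-3; promoter boxes
#'   are weak motifs, so ranking is driven by combined evidence rather than
#'   single-box significance).
#' @param bg A [background].
#' @param spacer_min,spacer_max Accepted -35/-10 spacer range in nt.
#' @return A `promoter_model`: list with `minus35` and `minus10`
#'   [tfbs_entry()] objects and the spacer window.
#' @export
default_promoter_model <- function(gram = c("positive", "negative"),
                                   box_pvalue = 1e-3,
                                   bg = uniform_background(),
                                   spacer_min = 16L, spacer_max = 18L) {
  gram <- match.arg(gram)
  path <- system.file("extdata",
                      sprintf("promoter_sites_gram%s.txt",
                              if (gram == "positive") "pos" else "neg"),
                      package = "regumine")
  sites <- .read_site_collection(path)
  mk <- function(name) tfbs_entry(name, build_pspm(sites[[name]]), bg,
                                  organism = paste0("gram_", gram),
                                  cutoff_pvalue = box_pvalue,
                                  pseudocount = 0.05)
  structure(list(minus35 = mk("minus35"), minus10 = mk("minus10"),
                 spacer_min = as.integer(spacer_min),
                 spacer_max = as.integer(spacer_max),
                 box_pvalue = box_pvalue, gram = gram),
            class = "promoter_model")
}

#' @export
print.promoter_model <- function(x, ...) {
  cat(sprintf("promoter_model (gram-%s)  -35 %s / -10 %s  spacer %d-%d nt  box p<=%g\n",
              x$gram, consensus(x$minus35$pspm), consensus(x$minus10$pspm),
              x$spacer_min, x$spacer_max, x$box_pvalue))
  invisible(x)
}

.empty_promoter_calls <- function() {
  data.frame(minus35_start = integer(), minus35_end = integer(),
             minus35_score = numeric(), minus10_start = integer(),
             minus10_end = integer(), minus10_score = numeric(),
             spacer_nt = integer(), complete = logical(),
             combined_score = numeric(), tss = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

#' Predict promoters in an upstream region
#'
#' The -35 and -10 boxes are scanned independently on the gene-facing strand
#' at the model's per-box p-value; every (-35, -10) hit pair whose spacer
#' (gap between the end of the -35 hexamer and the start of the -10 hexamer)
#' falls in the model's window becomes a complete promoter call with
#' `combined_score` the sum of the two box scores. Box hits that are part of
#' no complete pair are reported as incomplete calls. Overlapping complete
#' calls are all reported; calls are sorted by `combined_score`.
#'
#' @param region An `intergenic_region` or a plain DNA string oriented
#'   5'->3' toward the gene.
#' @param model A [default_promoter_model()].
#' @return Data frame of promoter calls with region-local 1-based
#'   coordinates; `tss` is 10 nt downstream of the -10 box start (NA for
#'   -35-only calls).
#' @export
find_promoters <- function(region, model = default_promoter_model()) {
  seq <- if (inherits(region, "intergenic_region")) region$sequence else region
  h35 <- scan_motif(seq, model$minus35, both_strands = FALSE)
  h10 <- scan_motif(seq, model$minus10, both_strands = FALSE)
  calls <- list()
  used35 <- logical(nrow(h35))
  used10 <- logical(nrow(h10))
  k <- 0L
  if (nrow(h35) && nrow(h10)) {
    for (i in seq_len(nrow(h35))) for (j in seq_len(nrow(h10))) {
      spacer <- h10$start[j] - h35$end[i] - 1L
      if (spacer >= model$spacer_min && spacer <= model$spacer_max) {
        used35[i] <- TRUE
        used10[j] <- TRUE
        k <- k + 1L
        calls[[k]] <- data.frame(
          minus35_start = h35$start[i], minus35_end = h35$end[i],
          minus35_score = h35$score[i],
          minus10_start = h10$start[j], minus10_end = h10$end[j],
          minus10_score = h10$score[j],
          spacer_nt = spacer, complete = TRUE,
          combined_score = h35$score[i] + h10$score[j],
          tss = h10$start[j] + 10L, strand = "+",
          stringsAsFactors = FALSE)
      }
    }
  }
  for (i in which(!used35)) {
    k <- k + 1L
    calls[[k]] <- data.frame(
      minus35_start = h35$start[i], minus35_end = h35$end[i],
      minus35_score = h35$score[i],
      minus10_start = NA_integer_, minus10_end = NA_integer_,
      minus10_score = NA_real_, spacer_nt = NA_integer_, complete = FALSE,
      combined_score = h35$score[i], tss = NA_integer_, strand = "+",
      stringsAsFactors = FALSE)
  }
  for (j in which(!used10)) {
    k <- k + 1L
    calls[[k]] <- data.frame(
      minus35_start = NA_integer_, minus35_end = NA_integer_,
      minus35_score = NA_real_,
      minus10_start = h10$start[j], minus10_end = h10$end[j],
      minus10_score = h10$score[j], spacer_nt = NA_integer_,
      complete = FALSE, combined_score = h10$score[j],
      tss = h10$start[j] + 10L, strand = "+",
      stringsAsFactors = FALSE)
  }
  if (k == 0L) return(.empty_promoter_calls())
  out <- do.call(rbind, calls)
  out <- out[order(-out$combined_score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Transcription start site of a promoter call
#'
#' The TSS is placed 10 nt downstream of the -10 box start (4 nt past the
#' end of the hexamer), matching the canonical Pribnow-box-to-TSS distance.
#'
#' @param call One row of a [find_promoters()] result.
#' @return Region-local 1-based TSS position.
#' @export
predict_tss <- function(call) {
  if (is.na(call$minus10_start))
    stop("TSS prediction requires a -10 box hit")
  as.integer(call$minus10_start + 10L)
}

# --- ribosome binding sites ---------------------------------------------------

.rbs_model_cache <- new.env(parent = emptyenv())

#' Shine-Dalgarno (RBS) scoring model
#'
#' Width-6 log-odds model rebuilt from the packaged AGGAGG-seeded site
#' collection.
#'
#' @param bg A [background].
#' @return A [tfbs_entry()].
#' @export
rbs_model <- function(bg = uniform_background()) {
  key <- paste(round(as.numeric(bg), 6), collapse = ",")
  if (is.null(.rbs_model_cache[[key]])) {
    sites <- .read_site_collection(
      system.file("extdata", "rbs_sites.txt", package = "regumine"))
    .rbs_model_cache[[key]] <- tfbs_entry("RBS", build_pspm(sites$rbs), bg,
                                          organism = "anti_SD",
                                          cutoff_pvalue = 1e-2,
                                          pseudocount = 0.05)
  }
  .rbs_model_cache[[key]]
}

#' Detect a ribosome binding site upstream of a start codon
#'
#' Scores every width-6 window whose spacing to the start codon (gap between
#' the end of the window and the first base of the start codon) lies in the
#' configured range against the AGGAGG-seeded model and returns the best
#' window, or NULL when nothing reaches `min_score`. Equal-scoring windows
#' are resolved in favour of the one nearer the start codon.
#'
#' @param region An `intergenic_region` or DNA string oriented toward the
#'   gene.
#' @param start_codon_offset Local 1-based position of the first base of the
#'   start codon within the region.
#' @param model RBS scoring model (default [rbs_model()]).
#' @param min_score Minimum reported score in bits (default 5).
#' @param spacing_min,spacing_max Allowed spacing window in nt (default 4-15).
#' @return A list (`start`, `end`, `matched_seq`, `score`,
#'   `spacing_to_start`) or NULL.
#' @export
find_rbs <- function(region, start_codon_offset, model = rbs_model(),
                     min_score = 5, spacing_min = 4L, spacing_max = 15L) {
  seq <- if (inherits(region, "intergenic_region")) region$sequence else region
  w <- ncol(model$pwm)
  # window end e must satisfy spacing = start_codon_offset - e - 1 in range
  ends <- (start_codon_offset - 1L - spacing_max):(start_codon_offset - 1L - spacing_min)
  ends <- ends[ends >= w & ends <= nchar(seq)]
  if (length(ends) == 0L) return(NULL)
  codes <- .dna_codes(seq)
  best <- NULL
  for (e in rev(ends)) {  # nearest-to-start first, so ties keep the near one
    sc <- sum(unclass(model$pwm)[cbind(codes[(e - w + 1L):e], seq_len(w))],
              na.rm = TRUE)
    if (is.null(best) || sc > best$score + 1e-12) {
      best <- list(start = e - w + 1L, end = e,
                   matched_seq = substr(seq, e - w + 1L, e), score = sc,
                   spacing_to_start = start_codon_offset - e - 1L)
    }
  }
  if (best$score < min_score) return(NULL)
  best
}

#' Adjust the start of a naively called ORF to match the RBS prediction
#'
#' Applies only to features produced by [call_orfs()] (`source ==
#' "naive_orf_caller"`); annotated genes are returned unchanged. Among
#' in-frame alternative starts (ATG/GTG/TTG) within `window` nt of the called
#' start, the one with the best [find_rbs()] score at proper spacing is
#' chosen; when no alternative beats the current start's RBS score the
#' feature is returned unchanged.
#'
#' @param gene One feature row.
#' @param genome The [genome_record()] the feature belongs to.
#' @param window Search window around the annotated start in nt (default 30).
#' @param model RBS model.
#' @param flank Upstream context used for RBS scoring, in nt (default 25).
#' @return The (possibly adjusted) feature row.
#' @export
adjust_start <- function(gene, genome, window = 30L, model = rbs_model(),
                         flank = 25L) {
  if (!identical(gene$source, "naive_orf_caller")) return(gene)
  L <- nchar(genome$sequence)
  starts_set <- c("ATG", "GTG", "TTG")
  stops_set <- c("TAA", "TAG", "TGA")
  # work in gene orientation: position of start codon's first base
  if (gene$strand == "+") {
    cur <- gene$start
    cand <- seq(cur - window, cur + window, by = 3L)
    cand <- cand[cand >= 1L & cand + 2L <= gene$end - 3L]
    codon_at <- function(p) substr(genome$sequence, p, p + 2L)
  } else {
    cur <- gene$end
    cand <- seq(cur - window, cur + window, by = 3L)
    cand <- cand[cand <= L & cand - 2L >= gene$start + 3L]
    codon_at <- function(p) revcomp(substr(genome$sequence, p - 2L, p))
  }
  cand <- cand[vapply(cand, function(p) codon_at(p) %in% starts_set, logical(1))]
  # upstream extensions must not introduce an in-frame stop before the old start
  ok_ext <- vapply(cand, function(p) {
    if (gene$strand == "+") {
      if (p >= cur) return(TRUE)
      ps <- seq(p, cur - 3L, by = 3L)
      !any(vapply(ps, function(q) codon_at(q) %in% stops_set, logical(1)))
    } else {
      if (p <= cur) return(TRUE)
      ps <- seq(p, cur + 3L, by = -3L)
      !any(vapply(ps, function(q) codon_at(q) %in% stops_set, logical(1)))
    }
  }, logical(1))
  cand <- cand[ok_ext]
  if (length(cand) == 0L) return(gene)

  rbs_score_at <- function(p) {
    if (gene$strand == "+") {
      from <- max(1L, p - flank)
      ctx <- substr(genome$sequence, from, p + 2L)
      off <- p - from + 1L
    } else {
      to <- min(L, p + flank)
      ctx <- revcomp(substr(genome$sequence, p - 2L, to))
      off <- to - p + 1L
    }
    r <- find_rbs(ctx, off, model = model, min_score = -Inf)
    if (is.null(r)) -Inf else r$score
  }
  scores <- vapply(cand, rbs_score_at, numeric(1))
  cur_score <- rbs_score_at(cur)
  best <- cand[which.max(scores)]
  if (max(scores) <= cur_score || best == cur) return(gene)
  if (gene$strand == "+") gene$start <- as.integer(best) else gene$end <- as.integer(best)
  cds <- substr(genome$sequence, gene$start, gene$end)
  if (gene$strand == "-") cds <- revcomp(cds)
  gene$translation <- .translate_cds(cds)
  gene
}

# --- rho-independent terminators ---------------------------------------------

.PAIR_SCORE <- c(GC = 3, CG = 3, AT = 2, TA = 2, GT = 1, TG = 1)
.TAIL_WEIGHTS <- seq(1.5, 0.8, by = -0.1)  # 8 positions 3' of the stem

#' Detect rho-independent transcription terminators (simplified)
#'
#' A simplified stem-loop + U-tail scorer: stems of 4-12 bp (Watson-Crick
#' pairs GC=3 and AT=2; GU wobble allowed but penalised at 1; mismatches
#' forbidden), loops of 3-9 nt, `hairpin_score` = sum of pair scores minus a
#' 1-point-per-nt loop penalty, and `tail_score` = position-weighted T count
#' over the 8 nt 3' of the stem. All stem-loops with
#' `total_score = hairpin_score + tail_score >= threshold` are reported.
#'
#' @param seq DNA string (forward genome strand).
#' @param strand `"+"` scans `seq` as given; `"-"` scans its reverse
#'   complement and reports mirrored forward-strand intervals.
#' @param threshold Minimum total score (default 12).
#' @param reduce Keep only the best call among mutually overlapping calls
#'   (default FALSE: all calls are reported).
#' @return Data frame: `start`, `end` (hairpin extent, 1-based forward
#'   coordinates), `strand`, `stem_len`, `loop_len`, `hairpin_score`,
#'   `tail_score`, `total_score`.
#' @export
find_terminators <- function(seq, strand = "+", threshold = 12, reduce = FALSE) {
  seq <- toupper(seq)
  L <- nchar(seq)
  s <- if (strand == "+") seq else revcomp(seq)
  ch <- strsplit(s, "")[[1L]]
  rows <- list()
  n <- 0L
  for (stem in 4:12) {
    for (loop in 3:9) {
      span <- 2L * stem + loop
      if (span > L) next
      for (i in seq_len(L - span + 1L)) {
        left <- ch[i:(i + stem - 1L)]
        right <- ch[(i + stem + loop):(i + span - 1L)]
        pairs <- paste0(left, rev(right))
        sc <- .PAIR_SCORE[pairs]
        if (anyNA(sc)) next
        hairpin <- sum(sc) - loop
        tail_from <- i + span
        tail_to <- min(L, tail_from + 7L)
        tail <- 0
        if (tail_from <= L) {
          tl <- ch[tail_from:tail_to]
          tail <- sum(.TAIL_WEIGHTS[seq_along(tl)][tl == "T"])
        }
        total <- hairpin + tail
        if (total >= threshold) {
          n <- n + 1L
          start_l <- i
          end_l <- i + span - 1L
          if (strand == "-") {
            tmp <- L - end_l + 1L
            end_l <- L - start_l + 1L
            start_l <- tmp
          }
          rows[[n]] <- data.frame(start = start_l, end = end_l,
                                  strand = strand, stem_len = stem,
                                  loop_len = loop, hairpin_score = hairpin,
                                  tail_score = tail, total_score = total,
                                  stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (n == 0L)
    return(data.frame(start = integer(), end = integer(), strand = character(),
                      stem_len = integer(), loop_len = integer(),
                      hairpin_score = numeric(), tail_score = numeric(),
                      total_score = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(-out$total_score, out$start), , drop = FALSE]
  if (reduce && nrow(out) > 1L) {
    keep <- logical(nrow(out))
    for (i in seq_len(nrow(out))) {
      kept <- which(keep)
      overlaps <- length(kept) &&
        any(out$start[i] <= out$end[kept] & out$end[i] >= out$start[kept])
      keep[i] <- !overlaps
    }
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
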