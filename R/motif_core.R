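#' @useDynLib regumine, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Nucleotide background model
#'
#' A background model is the zero-order base composition against which motif
#' matches are scored, typically estimated from all intergenic regions of the
#' organism under study.
#'
#' @param freqs Numeric vector of 4 probabilities for A, C, G, T (in that
#'   order). Must be strictly positive and sum to 1.
#' @return An object of class `background`: a named numeric vector.
#' @examples
#' uniform_background()
#' background(c(0.3, 0.2, 0.2, 0.3))
#' @export
background <- function(freqs) {
  freqs <- as.numeric(freqs)
  if (length(freqs) != 4L) stop("background requires exactly 4 frequencies (A,C,G,T)")
  if (any(freqs <= 0)) stop("background frequencies must be strictly positive")
  if (abs(sum(freqs) - 1) > 1e-9) stop("background frequencies must sum to 1")
  structure(stats::setNames(freqs, DNA_BASES), class = "background")
}

#' @rdname background
#' @export
uniform_background <- function() background(rep(0.25, 4))

#' Estimate a background model from DNA sequences
#'
#' @param seqs Character vector of DNA sequences; N and other ambiguity codes
#'   are ignored in the counts.
#' @param pseudocount Count added to each base before normalisation.
#' @return A [background] object.
#' @export
estimate_background <- function(seqs, pseudocount = 1) {
  counts <- stats::setNames(rep(pseudocount, 4), DNA_BASES)
  tab <- table(strsplit(paste(toupper(seqs), collapse = ""), "")[[1]])
  keep <- intersect(names(tab), DNA_BASES)
  counts[keep] <- counts[keep] + as.numeric(tab[keep])
  background(counts / sum(counts))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_dna <- function(x, what = "sequence") {
  bad <- regmatches(x, gregexpr("[^ACGT]", x))[[1]]
  if (length(bad)) stop(sprintf("%s contains non-ACGT characters: %s",
                                what, paste(unique(bad), collapse = ",")))
  invisible(x)
}

# DNA string -> integer codes 1..4 (A,C,G,T); N and other codes -> NA
.dna_codes <- function(seq) {
  match(strsplit(toupper(seq), "")[[1]], DNA_BASES)
}

#' Reverse complement of a DNA string
#'
#' @param seq DNA string (A,C,G,T,N accepted).
#' @return The reverse complement string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Build a position-specific probability matrix (PSPM) from aligned sites
#'
#' Each column holds the base probabilities at one motif position, estimated
#' from the site counts with an additive per-base pseudocount:
#' `p(j, b) = (count(j, b) + pseudocount) / (n_sites + 4 * pseudocount)`.
#'
#' @param sites Character vector of equal-length DNA strings (A,C,G,T only).
#' @param pseudocount Per-base additive pseudocount (default 0).
#' @return A `pspm`: a 4 x width numeric matrix (rows A,C,G,T) with attributes
#'   `site_count` and `width`.
#' @examples
#' build_pspm(c("ACGT", "ACGT"))
#' @export
build_pspm <- function(sites, pseudocount = 0) {
  if (length(sites) == 0L) stop("at least one site is required")
  sites <- toupper(sites)
  w <- unique(nchar(sites))
  if (length(w) != 1L) stop("sites have ragged lengths: ", paste(sort(w), collapse = ","))
  if (w == 0L) stop("sites must be non-empty")
  for (s in sites) .check_dna(s, "site")
  chars <- matrix(unlist(strsplit(sites, "")), nrow = length(sites), byrow = TRUE)
  counts <- vapply(seq_len(w), function(j) {
    tabulate(match(chars[, j], DNA_BASES), nbins = 4L)
  }, numeric(4))
  counts <- matrix(counts, nrow = 4L)
  prob <- (counts + pseudocount) / (length(sites) + 4 * pseudocount)
  new_pspm(prob, site_count = length(sites))
}

#' Construct a PSPM from a probability matrix
#'
#' @param matrix 4 x width matrix of column-stochastic base probabilities
#'   (rows A,C,G,T).
#' @param site_count Number of sites the matrix was estimated from.
#' @return A `pspm` object.
#' @export
new_pspm <- function(matrix, site_count = 0L) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != 4L) stop("PSPM must have 4 rows (A,C,G,T)")
  if (any(matrix < 0)) stop("PSPM entries must be non-negative")
  sums <- colSums(matrix)
  if (any(abs(sums - 1) > 1e-9)) stop("every PSPM column must sum to 1")
  rownames(matrix) <- DNA_BASES
  structure(matrix, site_count = as.integer(site_count),
            width = ncol(matrix), class = "pspm")
}

#' @export
print.pspm <- function(x, ...) {
  cat(sprintf("PSPM  width=%d  sites=%d  consensus=%s\n",
              ncol(x), attr(x, "site_count"), consensus(x)))
  print(round(unclass(x), 4))
  invisible(x)
}

#' Consensus string of a PSPM
#'
#' The most probable base per column; ties resolved in A,C,G,T order.
#'
#' @param pspm A `pspm`.
#' @return A character string of length `width`.
#' @export
consensus <- function(pspm) {
  paste(DNA_BASES[apply(unclass(pspm), 2, which.max)], collapse = "")
}

#' Convert a PSPM to a log-odds position weight matrix (PWM)
#'
#' Entries are base-2 log-odds of the (regularised) motif probability against
#' the background: `log2(p' / bg)` with the background-weighted regularisation
#' `p' = (p + pseudocount * bg_b) / (1 + pseudocount)`. Scores are therefore
#' in bits.
#'
#' @param pspm A `pspm`.
#' @param bg A [background].
#' @param pseudocount Total regularisation mass spread over the background
#'   (default 0). Must be > 0 if the PSPM contains zero probabilities.
#' @return A `pwm`: 4 x width matrix with attributes `min_score` and
#'   `max_score` (sums of column minima / maxima).
#' @export
pspm_to_pwm <- function(pspm, bg = uniform_background(), pseudocount = 0) {
  p <- unclass(pspm)
  if (pseudocount == 0 && any(p == 0))
    stop("PSPM has zero entries; a positive pseudocount is required")
  preg <- sweep(p, 1, as.numeric(bg) * pseudocount, "+") / (1 + pseudocount)
  m <- log2(sweep(preg, 1, as.numeric(bg), "/"))
  rownames(m) <- DNA_BASES
  structure(m,
            min_score = sum(apply(m, 2, min)),
            max_score = sum(apply(m, 2, max)),
            width = ncol(m), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM (bits)  width=%d  score range [%.3f, %.3f]\n",
              ncol(x), attr(x, "min_score"), attr(x, "max_score")))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Per-column information content of a PSPM
#'
#' Relative entropy of each column against the background,
#' `IC_j = sum_b p(j,b) log2(p(j,b)/bg_b)` (0 log 0 = 0), in bits.
#'
#' @param pspm A `pspm`.
#' @param bg A [background].
#' @return List with `per_column` (numeric vector) and `total`.
#' @export
information_content <- function(pspm, bg = uniform_background()) {
  p <- unclass(pspm)
  lr <- log2(sweep(p, 1, as.numeric(bg), "/"))
  term <- p * lr
  term[p == 0] <- 0
  per_column <- colSums(term)
  list(per_column = per_column, total = sum(per_column))
}

# --- exact score distribution -------------------------------------------------

# Discretised distribution of the PWM score of a random background word.
# Returns integer-lattice representation: list(probs, offset, granularity) where
# probs[k] = P(score_int == offset + k - 1), score = score_int * granularity.
.score_distribution <- function(pwm, bg, granularity = 1e-3) {
  s_int <- round(unclass(pwm) / granularity)
  bgv <- as.numeric(bg)
  lo <- sum(apply(s_int, 2, min))
  hi <- sum(apply(s_int, 2, max))
  probs <- numeric(hi - lo + 1L)
  # DP over columns; maintain running support [cur_lo, cur_hi]
  cur <- 1
  cur_lo <- 0L
  for (j in seq_len(ncol(s_int))) {
    col <- s_int[, j]
    new_lo <- cur_lo + min(col)
    new_hi <- cur_lo + length(cur) - 1L + max(col)
    new <- numeric(new_hi - new_lo + 1L)
    for (b in 1:4) {
      sh <- cur_lo + col[b] - new_lo
      idx <- seq_along(cur) + sh
      new[idx] <- new[idx] + bgv[b] * cur
    }
    cur <- new
    cur_lo <- new_lo
  }
  list(probs = cur, offset = cur_lo, granularity = granularity)
}

# Upper-tail lookup: P(score >= s) on the discretised lattice.
.score_dist_tail <- function(dist, score) {
  tail_cum <- rev(cumsum(rev(dist$probs)))
  k <- ceiling(round(score / dist$granularity, 6)) - dist$offset + 1L
  if (k <= 1L) return(1)
  if (k > length(tail_cum)) return(0)
  tail_cum[k]
}

#' Score threshold for a target p-value
#'
#' Computes, by exact dynamic programming over the discretised score
#' distribution of a random background word, the smallest score `t` such that
#' `P_bg(score >= t) <= pvalue`. The returned threshold is conservative: at
#' the stated granularity it never admits more probability mass than `pvalue`.
#'
#' @param pwm A `pwm`.
#' @param pvalue Target p-value in (0, 1].
#' @param bg A [background].
#' @param granularity Score discretisation bin width in bits (default 1/1000).
#' @return The score threshold (bits), on the discretisation lattice.
#' @export
score_threshold <- function(pwm, pvalue, bg = uniform_background(),
                            granularity = 1e-3) {
  if (pvalue <= 0) stop("pvalue must be positive")
  if (pvalue > 1) stop("pvalue must be <= 1")
  dist <- .score_distribution(pwm, bg, granularity)
  .threshold_from_dist(dist, pvalue)
}

.threshold_from_dist <- function(dist, pvalue) {
  tail_cum <- rev(cumsum(rev(dist$probs)))
  # smallest achievable score whose upper tail is within pvalue
  ok <- which(dist$probs > 0 & tail_cum <= pvalue)
  if (length(ok) == 0L) {
    # even the top achievable score exceeds the mass budget; nothing passes
    return((dist$offset + length(dist$probs)) * dist$granularity)
  }
  (dist$offset + ok[1L] - 1L) * dist$granularity
}

#' TFBS library entry
#'
#' Bundles a named motif with its probability matrix, log-odds matrix and the
#' p-value-derived score cutoff used for genome scanning.
#'
#' @param tf_name Transcription factor name (unique within a library).
#' @param pspm A `pspm` for the binding site.
#' @param bg A [background]; stored and used for cutoff computation.
#' @param organism Source organism label.
#' @param cutoff_pvalue Per-motif scan p-value cutoff (default 1e-5).
#' @param pseudocount Regularisation used in [pspm_to_pwm()] (default 0.01).
#' @param granularity Score discretisation for the cutoff (default 1/1000 bit).
#' @return An object of class `tfbs_entry`.
#' @export
tfbs_entry <- function(tf_name, pspm, bg = uniform_background(),
                       organism = "unknown", cutoff_pvalue = 1e-5,
                       pseudocount = 0.01, granularity = 1e-3) {
  w <- ncol(pspm)
  pwm <- pspm_to_pwm(pspm, bg, pseudocount)
  dist <- .score_distribution(pwm, bg, granularity)
  structure(list(
    tf_name = tf_name,
    organism = organism,
    pspm = pspm,
    pwm = pwm,
    bg = bg,
    cutoff_pvalue = cutoff_pvalue,
    cutoff_score = .threshold_from_dist(dist, cutoff_pvalue),
    pseudocount = pseudocount,
    granularity = granularity,
    score_dist = dist
  ), class = "tfbs_entry")
}

#' @export
print.tfbs_entry <- function(x, ...) {
  cat(sprintf("TFBS entry %s [%s]  width=%d  consensus=%s  cutoff p<=%g (score %.3f bits)\n",
              x$tf_name, x$organism, ncol(x$pspm), consensus(x$pspm),
              x$cutoff_pvalue, x$cutoff_score))
  invisible(x)
}

# Window scores of a PWM along an encoded sequence (codes 1..4, NA for N).
# N positions score 0 (background behaviour). Returns numeric vector of
# length len - w + 1 (or length 0).
.window_scores <- function(codes, pwm) {
  w <- ncol(pwm)
  L <- length(codes)
  if (L < w) return(numeric(0))
  n_win <- L - w + 1L
  scores <- numeric(n_win)
  m <- unclass(pwm)
  for (j in seq_len(w)) {
    v <- m[, j][codes[j:(j + n_win - 1L)]]
    v[is.na(v)] <- 0
    scores <- scores + v
  }
  scores
}

#' Scan a sequence for motif matches
#'
#' Reports every window (on both strands when requested) whose log-odds score
#' reaches the entry's cutoff, together with the exact background p-value of
#' the observed score (same dynamic-programming table as [score_threshold()]).
#' Overlapping hits are all reported; ambiguous bases (N) score as background
#' (0 bits).
#'
#' @param seq DNA string (may be shorter than the motif; then no hits).
#' @param entry A [tfbs_entry()].
#' @param both_strands Scan the reverse strand too (default TRUE).
#' @return A data frame of hits sorted by position: `tf_name`, `start`, `end`
#'   (1-based inclusive, forward coordinates), `strand`, `score` (bits),
#'   `pvalue`, `matched_seq` (motif-strand sequence).
#' @export
scan_motif <- function(seq, entry, both_strands = TRUE) {
  stopifnot(inherits(entry, "tfbs_entry"))
  w <- ncol(entry$pwm)
  seq <- toupper(seq)
  L <- nchar(seq)
  empty <- data.frame(tf_name = character(), start = integer(), end = integer(),
                      strand = character(), score = numeric(), pvalue = numeric(),
                      matched_seq = character(), stringsAsFactors = FALSE)
  if (L < w) return(empty)
  dist <- entry$score_dist %||%
    .score_distribution(entry$pwm, entry$bg, entry$granularity)
  tail_cum <- rev(cumsum(rev(dist$probs)))
  # p-values are looked up at the window's score on the same discretisation
  # lattice the threshold DP uses, so they agree with word enumeration
  lattice <- structure(round(unclass(entry$pwm) / entry$granularity),
                       width = w, class = "pwm")
  pval_of <- function(lat_scores) {
    k <- lat_scores - dist$offset + 1L
    k[k < 1L] <- 1L
    out <- numeric(length(k))
    inside <- k <= length(tail_cum)
    out[inside] <- tail_cum[k[inside]]
    out[!inside] <- 0
    out
  }
  hits <- list()
  strands <- if (both_strands) c("+", "-") else "+"
  for (st in strands) {
    s <- if (st == "+") seq else revcomp(seq)
    codes <- .dna_codes(s)
    scores <- .window_scores(codes, entry$pwm)
    lat_scores <- .window_scores(codes, lattice)
    pass <- which(scores >= entry$cutoff_score)
    if (length(pass)) {
      if (st == "+") {
        start <- pass
      } else {
        # window at position i of the reverse complement maps to forward
        # interval [L - i - w + 2, L - i + 1]
        start <- L - pass - w + 2L
      }
      hits[[st]] <- data.frame(
        tf_name = entry$tf_name,
        start = start, end = start + w - 1L, strand = st,
        score = scores[pass], pvalue = pval_of(lat_scores[pass]),
        matched_seq = vapply(pass, function(i) substr(s, i, i + w - 1L), ""),
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) return(empty)
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- MEME-minimal motif library I/O ------------------------------------------

#' Write a motif library in MEME-minimal text format
#'
#' One file holds many motifs; probabilities are written with 6 decimals and
#' each motif's scan p-value cutoff is carried on a comment-line extension
#' (`# cutoff_pvalue= ...`) so the round trip is lossless for name, width,
#' site count, probabilities and cutoff.
#'
#' @param entries List of [tfbs_entry()] objects.
#' @param path Output file path.
#' @param bg A [background] written to the header (defaults to the first
#'   entry's background).
#' @return `path`, invisibly.
#' @export
write_motif_library <- function(entries, path, bg = NULL) {
  if (length(entries) && is.null(bg)) bg <- entries[[1L]]$bg
  if (is.null(bg)) bg <- uniform_background()
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.6f", DNA_BASES, as.numeric(bg)), collapse = " "),
               ""), con)
  for (e in entries) {
    p <- unclass(e$pspm)
    writeLines(sprintf("MOTIF %s %s", e$tf_name, e$organism), con)
    writeLines(sprintf("# cutoff_pvalue= %g", e$cutoff_pvalue), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       ncol(p), attr(e$pspm, "site_count")), con)
    for (j in seq_len(ncol(p)))
      writeLines(paste(sprintf("%.6f", p[, j]), collapse = "  "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a motif library in MEME-minimal text format
#'
#' @param path File path.
#' @param cutoff_pvalue Default scan cutoff for motifs whose file entry does
#'   not carry a `# cutoff_pvalue=` extension line.
#' @param pseudocount Regularisation used when rebuilding the log-odds
#'   matrices.
#' @return List of [tfbs_entry()] objects. Columns whose probabilities sum to
#'   1 within 1e-3 are renormalised with a warning; larger deviations are an
#'   error naming the offending line.
#' @export
read_motif_library <- function(path, cutoff_pvalue = 1e-5, pseudocount = 0.01) {
  lines <- readLines(path)
  bg <- uniform_background()
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at) && bg_at[1L] < length(lines)) {
    toks <- strsplit(trimws(lines[bg_at[1L] + 1L]), "\\s+")[[1L]]
    if (length(toks) == 8L) bg <- background(as.numeric(toks[c(2, 4, 6, 8)]))
  }
  motif_at <- grep("^MOTIF\\b", lines)
  entries <- vector("list", length(motif_at))
  for (k in seq_along(motif_at)) {
    i <- motif_at[k]
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    tf_name <- toks[2L]
    organism <- if (length(toks) >= 3L) toks[3L] else "unknown"
    cutoff <- cutoff_pvalue
    j <- i + 1L
    hdr <- NA_integer_
    while (j <= length(lines) && (k == length(motif_at) || j < motif_at[k + 1L])) {
      if (grepl("^#\\s*cutoff_pvalue=", lines[j]))
        cutoff <- as.numeric(sub("^#\\s*cutoff_pvalue=\\s*", "", lines[j]))
      if (grepl("^letter-probability matrix:", lines[j])) { hdr <- j; break }
      j <- j + 1L
    }
    if (is.na(hdr)) stop("motif ", tf_name, " has no letter-probability matrix")
    w <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", lines[hdr]))
    nsites <- if (grepl("nsites=", lines[hdr]))
      as.integer(sub(".*nsites=\\s*(\\d+).*", "\\1", lines[hdr])) else 0L
    rows <- lines[(hdr + 1L):(hdr + w)]
    mat <- matrix(0, nrow = 4L, ncol = w)
    for (r in seq_len(w)) {
      vals <- suppressWarnings(as.numeric(strsplit(trimws(rows[r]), "\\s+")[[1L]]))
      if (length(vals) != 4L || anyNA(vals))
        stop(sprintf("malformed matrix row at line %d of %s", hdr + r, path))
      s <- sum(vals)
      if (abs(s - 1) > 1e-3)
        stop(sprintf("matrix row at line %d does not sum to 1 (sum=%.4f)", hdr + r, s))
      if (abs(s - 1) > 1e-5)
        warning(sprintf("renormalising matrix row at line %d (sum=%.6f)", hdr + r, s))
      if (abs(s - 1) > 1e-12) vals <- vals / s
      mat[, r] <- vals
    }
    entries[[k]] <- tfbs_entry(tf_name, new_pspm(mat, nsites), bg,
                               organism = organism, cutoff_pvalue = cutoff,
                               pseudocount = pseudocount)
  }
  entries
}
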