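# Protein similarity layer: exact Smith-Waterman local alignment with affine
# gaps plus an analytic Karlin-Altschul E-value, used to transfer regulon
# membership between organisms by best-hit homology.

.blosum62_cache <- new.env(parent = emptyenv())

.blosum62 <- function() {
  if (is.null(.blosum62_cache$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum62_cache$m <- e$BLOSUM62
  }
  .blosum62_cache$m
}

#' Protein alignment scoring scheme
#'
#' BLOSUM62 with affine gap penalties (a gap of length L costs
#' `gap_open + L * gap_extend`) and Karlin-Altschul parameters for the
#' analytic E-value. The defaults approximate the classic gapped protein
#' BLAST parameterisation (BLOSUM62, 11/1, lambda = 0.267, K = 0.041);
#' reproduction of BLAST's composition-based statistics is explicitly out of
#' scope, so E-values are approximate.
#'
#' @param gap_open,gap_extend Positive gap penalties.
#' @param karlin_lambda,karlin_K Karlin-Altschul parameters.
#' @param matrix Substitution matrix (default: BLOSUM62 from Biostrings).
#' @return A `scoring_scheme` list.
#' @export
scoring_scheme <- function(gap_open = 11, gap_extend = 1,
                           karlin_lambda = 0.267, karlin_K = 0.041,
                           matrix = NULL) {
  if (is.null(matrix)) matrix <- .blosum62()
  stopifnot(gap_open > 0, gap_extend > 0,
            identical(rownames(matrix), colnames(matrix)),
            isTRUE(all.equal(matrix, t(matrix))))
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, karlin_lambda = karlin_lambda,
                 karlin_K = karlin_K),
            class = "scoring_scheme")
}

.aa_codes <- function(x, alphabet) {
  codes <- match(strsplit(x, "")[[1L]], alphabet)
  if (anyNA(codes))
    stop("illegal residue(s) in protein sequence: ",
         paste(unique(strsplit(x, "")[[1L]][is.na(codes)]), collapse = ","))
  codes
}

#' Optimal local protein alignment
#'
#' Exact Smith-Waterman with affine gaps under the given scheme; the
#' traceback yields the aligned spans and the identity fraction (identical
#' columns / alignment columns). Completely dissimilar sequences floor at
#' score 0 with empty spans.
#'
#' @param query,subject Protein strings (20 amino-acid letters plus X).
#' @param scheme A [scoring_scheme()].
#' @return An `alignment_hit` list: `raw_score`, `bit_score`, `qstart`,
#'   `qend`, `sstart`, `send`, `identity_fraction`, `align_len`.
#' @export
local_align <- function(query, subject, scheme = scoring_scheme()) {
  if (nchar(query) == 0L || nchar(subject) == 0L)
    stop("sequences must be non-empty")
  alphabet <- rownames(scheme$matrix)
  r <- .sw_align_cpp(.aa_codes(toupper(query), alphabet),
                     .aa_codes(toupper(subject), alphabet),
                     scheme$matrix, scheme$gap_open, scheme$gap_extend)
  structure(list(
    raw_score = r$score,
    bit_score = (scheme$karlin_lambda * r$score - log(scheme$karlin_K)) / log(2),
    qstart = r$qstart, qend = r$qend, sstart = r$sstart, send = r$send,
    identity_fraction = if (r$align_len > 0) r$n_ident / r$align_len else 0,
    align_len = r$align_len
  ), class = "alignment_hit")
}

#' Analytic Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * raw_score)`: the expected number of chance
#' local alignments at or above `raw_score` in a search of a length-`m` query
#' against `n` database residues.
#'
#' @param raw_score Non-negative alignment raw score.
#' @param m Query length (residues).
#' @param n Database length (total residues).
#' @param scheme A [scoring_scheme()].
#' @return The E-value.
#' @export
evalue_ka <- function(raw_score, m, n, scheme = scoring_scheme()) {
  stopifnot(raw_score >= 0)
  scheme$karlin_K * m * n * exp(-scheme$karlin_lambda * raw_score)
}

#' Best-hit protein search
#'
#' Exact all-vs-all Smith-Waterman of every query against the proteome; per
#' query the minimum-E hit with `E <= cutoff_evalue` is reported. The database
#' size `n` in the E-value is the total residue count of the proteome. Ties
#' are broken by higher raw score, then lexicographic subject id, so results
#' do not depend on proteome input order.
#'
#' @param queries,proteome Named character vectors of protein sequences.
#' @param cutoff_evalue Reporting cutoff (default 1e-5).
#' @param scheme A [scoring_scheme()].
#' @return Data frame with one row per query that has a hit: `query_id`,
#'   `subject_id`, `raw_score`, `bit_score`, `evalue`, `identity_fraction`,
#'   `qstart`, `qend`, `sstart`, `send`.
#' @export
search_proteome <- function(queries, proteome, cutoff_evalue = 1e-5,
                            scheme = scoring_scheme()) {
  if (length(proteome) == 0L) stop("proteome must be non-empty")
  if (is.null(names(queries))) names(queries) <- sprintf("query_%d", seq_along(queries))
  if (is.null(names(proteome))) names(proteome) <- sprintf("subject_%d", seq_along(proteome))
  n_db <- sum(nchar(proteome))
  rows <- list()
  for (qi in seq_along(queries)) {
    best <- NULL
    for (si in order(names(proteome))) {
      h <- local_align(queries[[qi]], proteome[[si]], scheme)
      e <- evalue_ka(h$raw_score, nchar(queries[[qi]]), n_db, scheme)
      if (e > cutoff_evalue) next
      if (is.null(best) || e < best$evalue ||
          (e == best$evalue && h$raw_score > best$raw_score)) {
        best <- list(query_id = names(queries)[qi],
                     subject_id = names(proteome)[si],
                     raw_score = h$raw_score, bit_score = h$bit_score,
                     evalue = e, identity_fraction = h$identity_fraction,
                     qstart = h$qstart, qend = h$qend,
                     sstart = h$sstart, send = h$send)
      }
    }
    if (!is.null(best)) rows[[length(rows) + 1L]] <- as.data.frame(best)
  }
  if (length(rows) == 0L)
    return(data.frame(query_id = character(), subject_id = character(),
                      raw_score = numeric(), bit_score = numeric(),
                      evalue = numeric(), identity_fraction = numeric(),
                      qstart = integer(), qend = integer(),
                      sstart = integer(), send = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Map a regulon onto a target proteome by homology tiers
#'
#' Every regulon member is searched against the target proteome; its best hit
#' is assigned a similarity tier by E-value band (defaults: strong <= 1e-50 <
#' moderate <= 1e-20 < weak <= 1e-5 < absent), the tabular twin of a
#' colour-graded regulon conservation overview.
#'
#' @param regulon_members Named character vector of member protein sequences.
#' @param target_proteome Named character vector of target proteins.
#' @param tier_bands Named numeric vector of ascending band edges
#'   `c(strong=, moderate=, weak=)`; E-values above the last edge are
#'   `absent`.
#' @param scheme A [scoring_scheme()].
#' @return Data frame: `member`, `subject_id`, `evalue`, `raw_score`,
#'   `identity_fraction`, `tier` (factor absent < weak < moderate < strong).
#' @export
map_regulon <- function(regulon_members, target_proteome,
                        tier_bands = c(strong = 1e-50, moderate = 1e-20,
                                       weak = 1e-5),
                        scheme = scoring_scheme()) {
  stopifnot(!is.unsorted(tier_bands))
  if (is.null(names(regulon_members)))
    names(regulon_members) <- sprintf("member_%d", seq_along(regulon_members))
  if (length(regulon_members) == 0L)
    return(data.frame(member = character(), subject_id = character(),
                      evalue = numeric(), raw_score = numeric(),
                      identity_fraction = numeric(),
                      tier = factor(character(),
                                    levels = c("absent", names(rev(tier_bands)))),
                      stringsAsFactors = FALSE))
  hits <- search_proteome(regulon_members, target_proteome,
                          cutoff_evalue = tier_bands[length(tier_bands)],
                          scheme = scheme)
  idx <- match(names(regulon_members), hits$query_id)
  ev <- hits$evalue[idx]
  tier <- rep("absent", length(regulon_members))
  for (k in seq_along(tier_bands)) {
    band <- names(tier_bands)[k]
    sel <- !is.na(ev) & ev <= tier_bands[k] &
      (k == 1L | ev > c(0, tier_bands)[k])
    tier[sel] <- band
  }
  data.frame(member = names(regulon_members),
             subject_id = hits$subject_id[idx],
             evalue = ev,
             raw_score = hits$raw_score[idx],
             identity_fraction = hits$identity_fraction[idx],
             tier = factor(tier, levels = c("absent", rev(names(tier_bands)))),
             stringsAsFactors = FALSE)
}
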