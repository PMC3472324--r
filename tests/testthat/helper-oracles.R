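# Independent oracles and fixture builders shared across the test files.
# Every oracle deliberately re-derives its quantity by a different route than
# the implementation (brute-force enumeration, per-window loops, closed
# forms) so agreement is informative.

BASES <- c("A", "C", "G", "T")

random_dna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(BASES, n, replace = TRUE, prob = prob), collapse = "")
}

random_pspm <- function(width, alpha = 0.8) {
  m <- matrix(stats::rgamma(4 * width, shape = alpha), nrow = 4)
  m <- sweep(m, 2, colSums(m), "/")
  new_pspm(m, site_count = 10L)
}

# brute-force per-window log-odds scorer: plain loop, no vectorised reuse
naive_window_scores <- function(seq, pwm) {
  w <- ncol(pwm)
  L <- nchar(seq)
  if (L < w) return(numeric(0))
  m <- unclass(pwm)
  sapply(seq_len(L - w + 1L), function(i) {
    word <- strsplit(substr(seq, i, i + w - 1L), "")[[1L]]
    idx <- match(word, BASES)
    s <- 0
    for (j in seq_len(w)) s <- s + if (is.na(idx[j])) 0 else m[idx[j], j]
    s
  })
}

# enumerate all 4^w words on the discretisation lattice; returns the smallest
# achievable lattice score whose upper tail probability is <= pvalue
enumerate_threshold <- function(pwm, pvalue, bg = uniform_background(),
                                granularity = 1e-3) {
  w <- ncol(pwm)
  s_int <- round(unclass(pwm) / granularity)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- numeric(nrow(words))
  probs <- numeric(nrow(words))
  bgv <- as.numeric(bg)
  for (j in seq_len(w)) {
    scores <- scores + s_int[cbind(words[, j], j)]
    probs <- if (j == 1L) bgv[words[, j]] else probs * bgv[words[, j]]
  }
  lev <- sort(unique(scores))
  tails <- vapply(lev, function(t) sum(probs[scores >= t]), numeric(1))
  ok <- lev[tails <= pvalue]
  if (length(ok) == 0L) return((max(lev) + 1L) * granularity)
  ok[1L] * granularity
}

# exact word-level upper-tail p-value of a score (same lattice)
enumerate_pvalue <- function(pwm, score, bg = uniform_background(),
                             granularity = 1e-3) {
  w <- ncol(pwm)
  s_int <- round(unclass(pwm) / granularity)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- numeric(nrow(words))
  probs <- rep(1, nrow(words))
  bgv <- as.numeric(bg)
  for (j in seq_len(w)) {
    scores <- scores + s_int[cbind(words[, j], j)]
    probs <- probs * bgv[words[, j]]
  }
  sum(probs[scores * granularity >= score - granularity / 2])
}

# brute-force 6-frame ORF enumeration (start ATG/GTG/TTG, stop TAA/TAG/TGA,
# first start after each stop, stop codon included in the interval)
brute_force_orfs <- function(seq, min_aa) {
  L <- nchar(seq)
  out <- list()
  starts_set <- c("ATG", "GTG", "TTG")
  stops_set <- c("TAA", "TAG", "TGA")
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else regumine::revcomp(seq)
    for (frame in 0:2) {
      i <- frame + 1L
      open_at <- NA_integer_
      while (i + 2L <= L) {
        codon <- substr(s, i, i + 2L)
        if (is.na(open_at) && codon %in% starts_set) open_at <- i
        if (codon %in% stops_set) {
          if (!is.na(open_at)) {
            n_codons <- (i - open_at) / 3L
            if (n_codons >= min_aa) {
              from <- open_at; to <- i + 2L
              if (strand == "-") { tmp <- L - to + 1L; to <- L - from + 1L; from <- tmp }
              out[[length(out) + 1L]] <- c(start = from, end = to,
                                           strand = if (strand == "+") 1L else -1L)
            }
          }
          open_at <- NA_integer_
        }
        i <- i + 3L
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(), end = integer(), strand = character()))
  df <- as.data.frame(do.call(rbind, out))
  df$strand <- ifelse(df$strand == 1L, "+", "-")
  df[order(df$start, df$end), c("start", "end", "strand")]
}

# brute-force promoter oracle: enumerate every (-35 position, -10 position)
# box-pair placement directly against the PWMs and the spacer window
brute_force_promoters <- function(seq, model) {
  w <- 6L
  L <- nchar(seq)
  if (L < w) return(data.frame())
  s35 <- naive_window_scores(seq, model$minus35$pwm)
  s10 <- naive_window_scores(seq, model$minus10$pwm)
  pass35 <- which(s35 >= model$minus35$cutoff_score)
  pass10 <- which(s10 >= model$minus10$cutoff_score)
  pairs <- list()
  for (i in pass35) for (j in pass10) {
    spacer <- j - (i + w - 1L) - 1L
    if (spacer >= model$spacer_min && spacer <= model$spacer_max)
      pairs[[length(pairs) + 1L]] <- c(m35 = i, m10 = j, spacer = spacer)
  }
  if (length(pairs) == 0L)
    return(data.frame(m35 = integer(), m10 = integer(), spacer = integer()))
  as.data.frame(do.call(rbind, pairs))
}

# exhaustive local alignment for tiny sequences: max over all substring pairs
# of an independently written affine-gap global DP (gap cost open + L*extend)
exhaustive_local_score <- function(a, b, scheme) {
  mat <- scheme$matrix
  go <- scheme$gap_open; ge <- scheme$gap_extend
  global_affine <- function(x, y) {
    nx <- nchar(x); ny <- nchar(y)
    xs <- strsplit(x, "")[[1L]]; ys <- strsplit(y, "")[[1L]]
    NEG <- -1e9
    M <- matrix(NEG, nx + 1L, ny + 1L)  # ends in match state
    X <- matrix(NEG, nx + 1L, ny + 1L)  # gap in y (consumes x)
    Y <- matrix(NEG, nx + 1L, ny + 1L)  # gap in x (consumes y)
    M[1, 1] <- 0
    for (i in 2:(nx + 1L)) X[i, 1] <- -go - (i - 1L) * ge
    for (j in 2:(ny + 1L)) Y[1, j] <- -go - (j - 1L) * ge
    for (i in seq_len(nx + 1L)[-1L]) {
      for (j in seq_len(ny + 1L)[-1L]) {
        sc <- mat[xs[i - 1L], ys[j - 1L]]
        M[i, j] <- max(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L]) + sc
        X[i, j] <- max(M[i - 1L, j] - go - ge, X[i - 1L, j] - ge)
        Y[i, j] <- max(M[i, j - 1L] - go - ge, Y[i, j - 1L] - ge)
      }
    }
    max(M[nx + 1L, ny + 1L], X[nx + 1L, ny + 1L], Y[nx + 1L, ny + 1L])
  }
  best <- 0
  na <- nchar(a); nb <- nchar(b)
  for (i1 in seq_len(na)) for (i2 in i1:na)
    for (j1 in seq_len(nb)) for (j2 in j1:nb) {
      sc <- global_affine(substr(a, i1, i2), substr(b, j1, j2))
      if (sc > best) best <- sc
    }
  best
}

random_protein <- function(n) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y"),
               n, replace = TRUE), collapse = "")
}

# simple Levenshtein distance for consensus comparisons
edit_distance <- function(a, b) {
  as.integer(adist(a, b))
}

# one-gene GenBank text fixture
minimal_genbank <- function(path, cds_from = 101L, cds_to = 250L,
                            complement = FALSE, len = 400L, seed = 42L) {
  set.seed(seed)
  seqc <- sample(BASES, len, replace = TRUE)
  loc <- sprintf("%d..%d", cds_from, cds_to)
  if (complement) loc <- sprintf("complement(%s)", loc)
  lines <- c(
    sprintf("LOCUS       TEST01 %d bp    DNA     linear   BCT 01-JAN-2000", len),
    "DEFINITION  test record.",
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", len),
    sprintf("     CDS             %s", loc),
    "                     /locus_tag=\"tag001\"",
    "                     /gene=\"abc\"",
    "ORIGIN")
  for (from in seq(1L, len, by = 60L)) {
    chunk <- seqc[from:min(len, from + 59L)]
    groups <- tapply(chunk, (seq_along(chunk) - 1L) %/% 10L, paste, collapse = "")
    lines <- c(lines, sprintf("%9d %s", from, tolower(paste(groups, collapse = " "))))
  }
  writeLines(c(lines, "//"), path)
  paste(seqc, collapse = "")
}
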