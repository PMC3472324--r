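# sigma70 promoter pairing under the spacer constraint, TSS placement, RBS
# detection, naive-ORF start adjustment, and terminator scoring.

test_that("packaged promoter models carry the canonical consensus", {
  for (gram in c("positive", "negative")) {
    m <- default_promoter_model(gram)
    expect_equal(consensus(m$minus10$pspm), "TATAAT")
    expect_equal(consensus(m$minus35$pspm), "TTGACA")
    expect_equal(ncol(m$minus35$pwm), 6L)
    expect_equal(ncol(m$minus10$pwm), 6L)
    expect_true(all(abs(colSums(unclass(m$minus35$pspm)) - 1) < 1e-9))
    expect_true(all(abs(colSums(unclass(m$minus10$pspm)) - 1) < 1e-9))
    expect_equal(m$spacer_min, 16L)
    expect_equal(m$spacer_max, 18L)
  }
})

test_that("find_promoters pairs boxes only at 16-18 nt spacing", {
  model <- default_promoter_model()
  set.seed(55)
  region17 <- paste0(random_dna(40), "TTGACA", random_dna(17), "TATAAT",
                     random_dna(40))
  calls <- find_promoters(region17, model)
  complete <- calls[calls$complete, ]
  expect_gte(nrow(complete), 1L)
  top <- complete[1L, ]
  expect_equal(top$minus35_start, 41L)
  expect_equal(top$minus10_start, 41L + 6L + 17L)
  expect_equal(top$spacer_nt, 17L)
  expect_equal(top$combined_score, top$minus35_score + top$minus10_score)

  # spacer 25: no complete call, but both boxes appear as incomplete calls
  region25 <- paste0(random_dna(40), "TTGACA", random_dna(25), "TATAAT",
                     random_dna(40))
  calls25 <- find_promoters(region25, model)
  expect_equal(sum(calls25$complete), 0L)
  expect_true(any(!is.na(calls25$minus35_start) & calls25$minus35_start == 41L))
  expect_true(any(!is.na(calls25$minus10_start) & calls25$minus10_start == 72L))

  # every complete call ever produced satisfies the spacer window
  expect_true(all(calls$spacer_nt[calls$complete] >= 16L &
                  calls$spacer_nt[calls$complete] <= 18L))
})

test_that("find_promoters equals the brute-force box-pair oracle", {
  model <- default_promoter_model()
  set.seed(56)
  for (rep in 1:6) {
    seq <- if (rep <= 3) random_dna(500) else
      paste0(random_dna(150), "TTGACA", random_dna(sample(16:18, 1)),
             "TATAAT", random_dna(320))
    calls <- find_promoters(seq, model)
    oracle <- brute_force_promoters(seq, model)
    got <- calls[calls$complete, c("minus35_start", "minus10_start", "spacer_nt")]
    got <- got[order(got$minus35_start, got$minus10_start), ]
    exp <- oracle[order(oracle$m35, oracle$m10), ]
    expect_equal(nrow(got), nrow(exp))
    if (nrow(got)) {
      expect_equal(got$minus35_start, exp$m35)
      expect_equal(got$minus10_start, exp$m10)
      expect_equal(got$spacer_nt, exp$spacer)
    }
  }
})

test_that("random regions rarely yield complete promoter calls", {
  model <- default_promoter_model(box_pvalue = 1e-4)
  set.seed(57)
  n_complete <- sum(vapply(1:100, function(i) {
    any(find_promoters(random_dna(60), model)$complete)
  }, logical(1)))
  expect_lte(n_complete, 5L)
})

test_that("the TSS sits 10 nt downstream of the -10 box start", {
  model <- default_promoter_model()
  set.seed(58)
  region <- paste0(random_dna(44), "TATAAT", random_dna(30))
  calls <- find_promoters(region, model)
  m10 <- calls[!is.na(calls$minus10_start) & calls$minus10_start == 45L, ]
  expect_gte(nrow(m10), 1L)
  expect_equal(predict_tss(m10[1L, ]), 55L)
  expect_equal(m10$tss[1L], 55L)
  no10 <- calls[1L, ]
  no10$minus10_start <- NA_integer_
  expect_error(predict_tss(no10), "-10")

  # minus-strand genomic mapping checked against the simulator's truth
  sim <- simulate_genome(sim_spec(n_genes = 10L, regulon_size = 2L,
                                  rng_seed = 21L))
  f <- sim$genome$features
  minus_gene <- sim$truth$promoters$feature_id[sim$truth$promoters$strand == "-"][1L]
  skip_if(is.na(minus_gene))
  region <- extract_upstream(sim$genome, minus_gene)
  calls <- find_promoters(region, default_promoter_model())
  truth <- sim$truth$promoters[sim$truth$promoters$feature_id == minus_gene, ]
  found <- FALSE
  for (k in which(calls$complete)) {
    gc <- region_to_genome(region, calls$minus10_start[k], calls$minus10_end[k])
    if (gc$start == truth$minus10_start && gc$end == truth$minus10_end &&
        gc$strand == "-") found <- TRUE
  }
  expect_true(found)
})

test_that("find_rbs scores the anti-SD window with the near-start tie rule", {
  set.seed(59)
  region <- paste0(random_dna(40), "AGGAGG", random_dna(7), "ATGAAA")
  r <- find_rbs(region, start_codon_offset = 54L)
  expect_equal(r$matched_seq, "AGGAGG")
  expect_equal(r$spacing_to_start, 7L)
  expect_equal(r$start, 41L)

  # nothing above threshold: empty result
  expect_null(find_rbs(strrep("C", 60), start_codon_offset = 50L))

  # two perfect windows at different spacings: the nearer one wins
  region2 <- paste0(random_dna(20), "AGGAGG", "CC", "AGGAGG", random_dna(5),
                    "ATGAAA")
  r2 <- find_rbs(region2, start_codon_offset = 40L)
  expect_equal(r2$spacing_to_start, 5L)
  expect_equal(r2$start, 29L)
})

test_that("adjust_start moves naive ORF starts to the best RBS", {
  set.seed(60)
  # true start with a perfect RBS at spacing 8; caller picked an internal
  # ATG 12 nt downstream
  inner <- paste(sample(c("GCT", "GAA", "TGC", "CTG", "AAA"), 40, TRUE),
                 collapse = "")
  gene <- paste0("ATG", "GCAGCAGCA", "ATG", inner, "TAA")
  seq <- paste0(random_dna(60), "AGGAGG", random_dna(8), gene, random_dna(50))
  true_start <- 75L
  wrong_start <- true_start + 12L
  g <- genome_record("t", seq)
  feat <- gene_feature("orf", "orf", wrong_start, 74L + nchar(gene), "+",
                       source = "naive_orf_caller")
  adj <- adjust_start(feat, g)
  expect_equal(adj$start, true_start)
  expect_equal(adj$end, feat$end)
  expect_match(adj$translation, "^M")

  # annotated genes are never adjusted
  feat_gb <- feat
  feat_gb$source <- "genbank"
  expect_identical(adjust_start(feat_gb, g), feat_gb)

  # no alternative start present: unchanged
  no_alt <- paste0(strrep("C", 40), "ATG", inner, "TAA", strrep("C", 40))
  g2 <- genome_record("t2", no_alt)
  feat2 <- gene_feature("orf", "orf", 41L, 43L + nchar(inner) + 3L, "+",
                        source = "naive_orf_caller")
  expect_equal(adjust_start(feat2, g2)$start, 41L)
})

test_that("terminator scoring is exact on planted hairpins", {
  stem <- "GCGCGCGC"
  hp <- paste0(stem, "AAAA", revcomp(stem))
  seq <- paste0(strrep("C", 20), hp, "TTTTTTTT", strrep("C", 20))
  calls <- find_terminators(seq)
  planted <- calls[calls$start == 21L & calls$stem_len == 8L &
                   calls$loop_len == 4L, ]
  expect_equal(nrow(planted), 1L)
  expect_equal(planted$hairpin_score, 8 * 3 - 4)
  expect_equal(planted$tail_score, sum(seq(1.5, 0.8, by = -0.1)))
  expect_equal(planted$total_score,
               planted$hairpin_score + planted$tail_score)

  # removing the tail drops the total by exactly the tail component
  seq_no_tail <- paste0(strrep("C", 20), hp, "AAAAAAAA", strrep("C", 20))
  calls2 <- find_terminators(seq_no_tail)
  planted2 <- calls2[calls2$start == 21L & calls2$stem_len == 8L &
                     calls2$loop_len == 4L, ]
  expect_equal(planted2$total_score,
               planted$total_score - planted$tail_score)

  # poly-A sequence has no stems at all
  expect_equal(nrow(find_terminators(strrep("A", 120))), 0L)
})

test_that("terminator calls mirror under reverse complement", {
  set.seed(61)
  for (rep in 1:5) {
    stem_len <- sample(4:8, 1)
    stem <- random_dna(stem_len, prob = c(.1, .4, .4, .1))
    loop <- sample(3:9, 1)
    seq <- paste0(random_dna(25), stem, random_dna(loop), revcomp(stem),
                  "TTTTTTTT", random_dna(25))
    fwd <- find_terminators(seq, "+", threshold = 8)
    rev <- find_terminators(revcomp(seq), "-", threshold = 8)
    expect_equal(nrow(rev), nrow(fwd))
    expect_equal(sort(rev$total_score), sort(fwd$total_score))
    L <- nchar(seq)
    expect_equal(sort(rev$start), sort(L - fwd$end + 1L))
    expect_equal(sort(rev$end), sort(L - fwd$start + 1L))
  }
})

test_that("terminator scores equal independent pair/tail recomputation", {
  set.seed(62)
  pair_score <- c(GC = 3, CG = 3, AT = 2, TA = 2, GT = 1, TG = 1)
  weights <- seq(1.5, 0.8, by = -0.1)
  for (rep in 1:50) {
    stem_len <- sample(4:10, 1)
    left <- random_dna(stem_len, prob = c(.15, .35, .35, .15))
    loop_len <- sample(3:9, 1)
    # right arm: complement with occasional GU wobble
    lchars <- strsplit(left, "")[[1]]
    comp <- c(A = "T", C = "G", G = "C", T = "A")[lchars]
    wob <- runif(stem_len) < 0.2
    comp[wob & lchars == "G"] <- "T"   # G:T pair
    comp[wob & lchars == "T"] <- "G"   # T:G pair
    right <- paste(rev(comp), collapse = "")
    tail <- paste(sample(c("T", "A", "C"), 8, TRUE, prob = c(.7, .2, .1)),
                  collapse = "")
    seq <- paste0(strrep("C", 12), left, strrep("A", loop_len), right, tail,
                  strrep("C", 12))
    calls <- find_terminators(seq, threshold = -20)
    row <- calls[calls$start == 13L & calls$stem_len == stem_len &
                 calls$loop_len == loop_len, ]
    expect_equal(nrow(row), 1L)
    pairs <- paste0(lchars, rev(strsplit(right, "")[[1]]))
    exp_hairpin <- sum(pair_score[pairs]) - loop_len
    tl <- strsplit(tail, "")[[1]]
    exp_tail <- sum(weights[tl == "T"])
    expect_equal(row$hairpin_score, exp_hairpin)
    expect_equal(row$tail_score, exp_tail)
    expect_equal(row$total_score, exp_hairpin + exp_tail)
  }
})
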