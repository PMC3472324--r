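# Genome reading, ORF calling, operon grouping, upstream extraction and GFF3.

test_that("read_genbank parses coordinates, strand and translation", {
  path <- withr::local_tempfile(fileext = ".gbk")
  seqc <- minimal_genbank(path, cds_from = 101L, cds_to = 250L)
  g <- read_genbank(path)
  expect_s3_class(g, "genome_record")
  expect_equal(nchar(g$sequence), 400L)
  f <- g$features
  expect_equal(nrow(f), 1L)
  expect_equal(f$start, 101L)
  expect_equal(f$end, 250L)
  expect_equal(f$strand, "+")
  expect_equal(f$locus_tag, "tag001")
  expect_equal(f$gene_name, "abc")

  # complement CDS: strand "-" and translation equals an independent codon
  # walk over the reverse complement (bacterial code, initiator forced to M)
  seqc2 <- minimal_genbank(path, cds_from = 101L, cds_to = 250L,
                           complement = TRUE, seed = 43L)
  g2 <- read_genbank(path)
  expect_equal(g2$features$strand, "-")
  code <- Biostrings::getGeneticCode("11")
  rc <- revcomp(substr(seqc2, 101L, 250L))
  codons <- substring(rc, seq(1L, 148L, 3L), seq(3L, 150L, 3L))
  walked <- paste(code[codons], collapse = "")
  walked <- sub("\\*$", "", walked)
  substr(walked, 1L, 1L) <- "M"
  expect_equal(g2$features$translation, walked)
})

test_that("read_genbank errors on missing ORIGIN and origin-spanning joins", {
  path <- withr::local_tempfile(fileext = ".gbk")
  writeLines(c("LOCUS       X 10 bp DNA linear", "FEATURES", "//"), path)
  expect_error(read_genbank(path), "ORIGIN")
  writeLines(c(
    "LOCUS       X 30 bp    DNA     linear   BCT 01-JAN-2000",
    "FEATURES             Location/Qualifiers",
    "     CDS             join(25..30,1..6)",
    "ORIGIN",
    "        1 acgtacgtac gtacgtacgt acgtacgtac", "//"), path)
  expect_error(read_genbank(path), "origin")
})

test_that("simulated genomes round-trip through the GenBank fixture writer", {
  sim <- simulate_genome(sim_spec(n_genes = 10L, regulon_size = 2L,
                                  rng_seed = 5L))
  path <- withr::local_tempfile(fileext = ".gbk")
  write_genbank_fixture(sim$genome, path)
  back <- read_genbank(path)
  expect_equal(back$sequence, sim$genome$sequence)
  expect_equal(nrow(back$features), nrow(sim$genome$features))
  expect_equal(back$features$start, sim$genome$features$start)
  expect_equal(back$features$end, sim$genome$features$end)
  expect_equal(back$features$strand, sim$genome$features$strand)
  expect_equal(back$features$translation, sim$genome$features$translation)
})

test_that("read_fasta handles single, multi-record and lowercase input", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s", "ACGT"), path)
  g <- read_fasta(path)
  expect_equal(nchar(g$sequence), 4L)
  expect_equal(nrow(g$features), 0L)

  writeLines(c(">c1", "ACGTACGT", ">c2", "GGGG", ">c3", "TTTTTT"), path)
  gs <- read_fasta(path)
  expect_length(gs, 3L)
  expect_equal(vapply(gs, function(x) x$accession, ""), c("c1", "c2", "c3"))

  writeLines(c(">lc", "acgtn"), path)
  g3 <- read_fasta(path)
  expect_equal(g3$sequence, "ACGTN")

  # non-IUPAC-core characters are rejected with positions
  expect_error(genome_record("x", "ACGTXACGT"), "position")
})

test_that("call_orfs finds planted ORFs and matches 6-frame enumeration", {
  set.seed(11)
  # planted ATG + 89 random non-stop codons + TAA on the forward strand
  codons <- c("GCT", "GAA", "TGC", "CTG", "AAA", "TCT", "GGC", "CAT")
  body <- paste(sample(codons, 89, replace = TRUE), collapse = "")
  orf <- paste0("ATG", body, "TAA")
  seq <- paste0(random_dna(153), orf, random_dna(151))
  g <- genome_record("t", seq)
  found <- call_orfs(g, min_aa = 50L)
  # the stop side is pinned; a maximal ORF may extend in-frame into the flank
  hit <- found[found$strand == "+" & found$end == 154L + nchar(orf) - 1L, ]
  expect_equal(nrow(hit), 1L)
  expect_lte(hit$start, 154L)
  expect_equal((154L - hit$start) %% 3L, 0)
  expect_equal(hit$source, "naive_orf_caller")

  # all-N sequence has no ORFs
  expect_equal(nrow(call_orfs(genome_record("n", strrep("N", 300)), 20L)), 0L)

  # minus-strand planted ORF is reported on "-" with forward coordinates
  seq2 <- paste0(random_dna(97), revcomp(orf), random_dna(100))
  found2 <- call_orfs(genome_record("t2", seq2), min_aa = 50L)
  hit2 <- found2[found2$strand == "-" & found2$start == 98L, ]
  expect_equal(nrow(hit2), 1L)
  expect_gte(hit2$end, 98L + nchar(orf) - 1L)
  expect_equal((hit2$end - (98L + nchar(orf) - 1L)) %% 3L, 0)

  # property: equality with a brute-force 6-frame oracle on random sequence
  for (rep in 1:3) {
    rs <- random_dna(1500)
    mine <- call_orfs(genome_record("r", rs), min_aa = 25L)
    oracle <- brute_force_orfs(rs, 25L)
    expect_equal(mine$start, oracle$start)
    expect_equal(mine$end, oracle$end)
    expect_equal(mine$strand, oracle$strand)
  }
})

test_that("group_operons merges same-strand neighbours within the gap", {
  mk <- function(strands, starts, ends) {
    feats <- do.call(rbind, lapply(seq_along(starts), function(i)
      gene_feature(sprintf("g%d", i), sprintf("g%d", i), starts[i], ends[i],
                   strands[i])))
    genome_record("t", strrep("A", 2000L), feats)
  }
  # 30 nt gap, max 50: one operon of two
  ops <- group_operons(mk(c("+", "+"), c(101L, 331L), c(300L, 500L)), 50L)
  expect_length(ops, 1L)
  expect_equal(ops[[1]]$members, c("g1", "g2"))
  expect_equal(ops[[1]]$lead_gene, "g1")
  # 200 nt gap: two singletons
  ops2 <- group_operons(mk(c("+", "+"), c(101L, 501L), c(300L, 700L)), 50L)
  expect_length(ops2, 2L)
  # strand switch always splits
  ops3 <- group_operons(mk(c("+", "-"), c(101L, 311L), c(300L, 500L)), 50L)
  expect_length(ops3, 2L)
  # "-" operon: lead gene is the 3'-most forward member (5' in transcription)
  ops4 <- group_operons(mk(c("-", "-"), c(101L, 331L), c(300L, 500L)), 50L)
  expect_length(ops4, 1L)
  expect_equal(ops4[[1]]$lead_gene, "g2")
  expect_equal(ops4[[1]]$members, c("g2", "g1"))
})

test_that("extract_upstream obeys flank, prefix, truncation and strand", {
  set.seed(13)
  seq <- random_dna(1200)
  feats <- rbind(
    gene_feature("prev", "prev", 101L, 200L, "+"),
    gene_feature("g", "g", 501L, 700L, "+"))
  g <- genome_record("t", seq, feats)
  r <- extract_upstream(g, "g", max_upstream_nt = 300L, gene_prefix_nt = 20L)
  expect_equal(nchar(r$sequence), 320L)
  expect_equal(r$upstream_flank_len, 300L)
  expect_equal(r$gene_prefix_len, 20L)
  expect_equal(r$sequence, substr(seq, 201L, 520L))
  # flank truncates at the nearest feature boundary
  feats2 <- rbind(
    gene_feature("prev", "prev", 101L, 490L, "+"),
    gene_feature("g", "g", 501L, 700L, "+"))
  r2 <- extract_upstream(genome_record("t", seq, feats2), "g", 300L, 20L)
  expect_equal(r2$upstream_flank_len, 10L)
  expect_equal(nchar(r2$sequence), 30L)

  # "-" target: sequence is the reverse complement of the downstream slice
  feats3 <- rbind(
    gene_feature("g", "g", 301L, 500L, "-"),
    gene_feature("nxt", "nxt", 901L, 1000L, "-"))
  r3 <- extract_upstream(genome_record("t", seq, feats3), "g", 300L, 20L)
  expect_equal(r3$sequence, revcomp(substr(seq, 481L, 800L)))
  expect_equal(r3$upstream_flank_len, 300L)
  expect_equal(r3$strand, "-")

  # region-local to genome mapping round-trips for both strands
  gc <- region_to_genome(r, 1L, 10L)
  expect_equal(gc$start, 201L)
  gc3 <- region_to_genome(r3, 1L, 10L)
  expect_equal(gc3$end, 800L)
  expect_equal(gc3$start, 791L)
  expect_equal(gc3$strand, "-")
})

test_that("extract_upstream wraps circular genomes and rejects empty regions", {
  set.seed(14)
  seq <- random_dna(600)
  feats <- rbind(
    gene_feature("g", "g", 51L, 250L, "+"),
    gene_feature("other", "other", 451L, 550L, "+"))
  gc <- genome_record("t", seq, feats, topology = "circular")
  r <- extract_upstream(gc, "g", max_upstream_nt = 80L, gene_prefix_nt = 0L)
  # 50 nt before the gene plus 30 wrapped from the end of the sequence
  expect_equal(r$upstream_flank_len, 80L)
  expect_equal(r$sequence, paste0(substr(seq, 571L, 600L), substr(seq, 1L, 50L)))

  glin <- genome_record("t", seq, feats[1, , drop = FALSE])
  g0 <- genome_record("t", seq,
                      gene_feature("at0", "at0", 1L, 200L, "+"))
  expect_error(extract_upstream(g0, "at0", 300L, 0L), "empty upstream")

  # the upstream region never covers another feature beyond the gene prefix
  sim <- simulate_genome(sim_spec(n_genes = 12L, regulon_size = 3L,
                                  rng_seed = 8L))
  ops <- group_operons(sim$genome, 50L)
  f <- sim$genome$features
  for (op in ops) {
    r <- extract_upstream(sim$genome, op, 300L, 20L)
    others <- f[!(f$feature_id %in% op$members), ]
    overlap <- pmin(r$genome_end, others$end) - pmax(r$genome_start, others$start) + 1L
    expect_true(all(overlap <= 0L))
  }
})

test_that("GFF3 writing round-trips and formats attributes", {
  ann <- data.frame(
    seqid = "chr", source = "regumine", type = c("TF_binding_site", "promoter"),
    start = c(101L, 350L), end = c(116L, 378L), score = c(12.5, 9.25),
    strand = c("+", "-"),
    attributes = c(sprintf("tf=WalR;pvalue=%s", format_pvalue(1e-6)),
                   "spacer=17;complete=yes"),
    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff(ann, path, genome_length = 1000L)
  lines <- readLines(path)
  expect_equal(lines[1], "##gff-version 3")
  cols <- strsplit(lines[3], "\t")[[1]]
  expect_equal(cols[4], "101")
  expect_equal(cols[5], "116")
  expect_match(cols[9], "pvalue=1.0e-06", fixed = TRUE)

  back <- read_gff(path)
  expect_equal(back$start, ann$start)
  expect_equal(back$end, ann$end)
  expect_equal(back$strand, ann$strand)
  expect_equal(back$attributes, ann$attributes)

  # an independent GFF3 reader agrees on intervals and strands
  skip_if_not_installed("rtracklayer")
  gr <- rtracklayer::import(path)
  expect_equal(BiocGenerics::start(gr), ann$start)
  expect_equal(BiocGenerics::end(gr), ann$end)
  expect_equal(as.character(BiocGenerics::strand(gr)), ann$strand)

  # empty annotation set: header-only valid file
  write_gff(ann[0, ], path)
  expect_equal(readLines(path), "##gff-version 3")
  expect_equal(nrow(read_gff(path)), 0L)

  # coordinates outside the genome are rejected
  bad <- ann; bad$end[1] <- 2000L
  expect_error(write_gff(bad, path, genome_length = 1000L), "outside")
})
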