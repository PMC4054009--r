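test_that("seed index postings match exhaustive k-mer scan", {
  idx <- build_seed_index(c(t1 = "ACGTACGT"), k = 8)
  hit <- seed_lookup(idx, "ACGTACGT")
  # ACGTACGT is its own reverse complement: both strands at the same locus
  expect_equal(hit$pos, c(1, 1))
  expect_setequal(hit$strand, c("+", "-"))

  idx4 <- build_seed_index(c(t1 = "ACGTACGTAA"), k = 8)
  expect_error(build_seed_index(c(t1 = "ACGT"), k = 8), "shorter")

  set.seed(21)
  target <- random_dna(1000)
  idx1k <- build_seed_index(c(t = target), k = 12)
  for (p in sample(1:(1000 - 11), 40)) {
    kmer <- substr(target, p, p + 11)
    hits <- seed_lookup(idx1k, kmer)
    expect_true(p %in% hits$pos[hits$strand == "+"])
    # oracle: every forward posting is a true occurrence
    for (q in hits$pos[hits$strand == "+"])
      expect_equal(substr(target, q, q + 11), kmer)
  }
})

test_that("align_end reports exactly the brute-force Hamming placements", {
  set.seed(31)
  target <- random_dna(2000)
  idx <- build_seed_index(c(t = target), k = 21)

  exact <- substr(target, 301, 390)
  h <- align_end(c(r = exact), idx)
  expect_equal(nrow(h), 1)
  expect_equal(h$pos, 301)
  expect_equal(h$mismatches, 0)

  # more substitutions than allowed: unmapped
  bad <- exact
  for (p in c(10, 40, 70)) substr(bad, p, p) <- "N"
  expect_equal(nrow(align_end(c(r = bad), idx, max_mismatch = 2)), 0)

  # 50 random sampled reads with 0-2 substitutions, either strand
  for (i in 1:50) {
    p <- sample(1:(2000 - 89), 1)
    rd <- substr(target, p, p + 89)
    n_sub <- sample(0:2, 1)
    for (sp in sample(90, n_sub)) {
      cur <- substr(rd, sp, sp)
      substr(rd, sp, sp) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
    }
    if (runif(1) < 0.5) rd <- dna_revcomp(rd)
    got <- align_end(c(r = rd), idx, max_mismatch = 2, max_hits = 50) |>
      dplyr::select(target, pos, strand, mismatches) |>
      dplyr::arrange(mismatches, target, pos)
    oracle <- brute_hamming_scan(rd, c(t = target), max_mm = 2)
    expect_equal(as.data.frame(got), as.data.frame(oracle))
  }
})

test_that("short reads are still found via the small-k fallback", {
  set.seed(32)
  target <- random_dna(2000)
  idx <- build_seed_index(c(t = target), k = 21)
  rd <- substr(target, 501, 530)              # 30 nt < 3k
  substr(rd, 3, 3) <- "N"; substr(rd, 28, 28) <- "N"
  got <- align_end(c(r = rd), idx, max_mismatch = 2)
  expect_equal(got$pos, 501)
  expect_equal(got$mismatches, 2)
})

test_that("pair classification follows orientation and insert rules", {
  set.seed(41)
  chrom <- random_dna(15000)
  idx <- build_seed_index(c(chr1 = chrom), k = 21)
  mk <- function(p1, p2, flip2 = TRUE) {
    e1 <- substr(chrom, p1, p1 + 89)
    e2 <- substr(chrom, p2, p2 + 89)
    if (flip2) e2 <- dna_revcomp(e2)
    list(e1 = e1, e2 = e2)
  }
  a <- mk(1001, 1211)          # head-to-head, fragment 300
  b <- mk(2001, 2211, flip2 = FALSE)  # same strand: abnormal orientation
  c <- mk(3001, 14911)         # implied fragment 12,000
  pairs <- tibble::tibble(pair_id = c("a", "b", "c"),
                          end1 = c(a$e1, b$e1, c$e1),
                          end2 = c(a$e2, b$e2, c$e2))
  h1 <- align_end(setNames(pairs$end1, pairs$pair_id), idx)
  h2 <- align_end(setNames(pairs$end2, pairs$pair_id), idx)
  st <- classify_pairs(pairs, h1, h2)
  expect_equal(st$stage[st$pair_id == "a"], "PE-S01")
  expect_equal(st$fragment[st$pair_id == "a"], 300)
  expect_equal(st$stage[st$pair_id == "b"], "SE-S01")
  expect_equal(st$stage[st$pair_id == "c"], "SE-S01")
})

test_that("insert-size statistics match closed forms and recover the truth", {
  expect_equal(estimate_insert_size(c(200, 200, 200))[c("INS", "SD")],
               list(INS = 200, SD = 0))
  est <- estimate_insert_size(c(190, 210))
  expect_equal(est$INS, 200)
  expect_equal(est$SD, sd(c(190, 210)))       # 14.142...
  expect_equal(est$SD, 14.1421356, tolerance = 1e-6)
  expect_error(estimate_insert_size(c(200)), "configuration")

  # simulator reads at INS 200, SD 20: genome-space estimate within 2 bp
  # (single-exon genes, so genomic and transcript fragment lengths agree)
  sim <- simulate_reference(n_chrom = 1, n_genes = 10,
                            exons_per_gene = c(1, 1),
                            exon_length = c(1500, 2500), seed = 13)
  ref <- sim$reference
  no_fusions <- simulate_fusions(ref, select_fusion_pairs(ref, 0, seed = 13),
                                 seed = 13)
  rd <- simulate_reads(ref, no_fusions, INS = 200, SD = 20, error_rate = 0,
                       background_depth = 50, seed = 13)
  expect_gt(nrow(rd$reads), 5000)
  gidx <- build_seed_index(ref$genome, k = 21)
  h1 <- align_end(setNames(rd$reads$end1, rd$reads$pair_id), gidx)
  h2 <- align_end(setNames(rd$reads$end2, rd$reads$pair_id), gidx)
  st <- classify_pairs(rd$reads, h1, h2)
  est <- estimate_insert_size(st$fragment[st$stage == "PE-S01"],
                              robust = TRUE)
  expect_lt(abs(est$INS - 200), 2)
  expect_lt(abs(est$SD - 20), 2)
})

test_that("transcript realignment stages splice reads and conserves counts", {
  ref <- tiny_reference()
  nrt_seqs <- vapply(ref$nrt, function(n) n$sequence, character(1))
  tidx <- build_seed_index(nrt_seqs, k = 21)

  # a read spanning an exon-exon boundary of gA maps only in transcript space
  splice <- substr(nrt_seqs[["gA"]], 160, 249)   # exon1 ends at tpos 200
  gidx <- build_seed_index(ref$genome, k = 21)
  expect_equal(nrow(align_end(c(s = splice), gidx)), 0)
  res <- align_to_transcripts(c(`p1/1` = splice), tidx)
  expect_equal(res$hits$target, "gA")
  expect_equal(res$hits$pos, 160)

  # intergenic sequence maps nowhere in transcript space
  intergenic <- substr(ref$genome[["chrA"]], 1500, 1589)
  res2 <- align_to_transcripts(c(`p2/1` = intergenic), tidx)
  expect_equal(nrow(res2$hits), 0)

  # staging is a partition of the unmapped input
  reads <- c(`a/1` = splice, `b/1` = intergenic,
             `c/1` = substr(nrt_seqs[["gB"]], 250, 339))
  res3 <- align_to_transcripts(reads, tidx)
  mapped <- unique(res3$mapped_reads)
  expect_equal(length(mapped) + sum(!names(reads) %in% mapped),
               length(reads))
})

test_that("one-gap rescue removes indel artifacts but keeps junction reads", {
  ref <- tiny_reference()
  nrt_seqs <- vapply(ref$nrt, function(n) n$sequence, character(1))
  tidx <- build_seed_index(nrt_seqs, k = 21)
  tA <- nrt_seqs[["gA"]]; tB <- nrt_seqs[["gB"]]

  del3 <- paste0(substr(tA, 50, 99), substr(tA, 103, 142))   # 3-base deletion
  gap6 <- paste0(substr(tA, 200, 249), substr(tA, 256, 295)) # 6-base gap
  junc <- paste0(substr(tA, 356, 400), substr(tB, 1, 45))    # fusion junction
  fum <- collect_fum(c(d = del3, g = gap6, j = junc), tidx,
                     max_gap = 5, max_mismatch = 2)
  expect_false("d" %in% names(fum))
  expect_true("g" %in% names(fum))
  expect_true("j" %in% names(fum))

  # boundary agrees with a brute-force gapped scan on the source window
  expect_true(brute_gap_fit(del3, substr(tA, 1, 200), max_mm = 2, max_gap = 5))
  expect_false(brute_gap_fit(gap6, substr(tA, 150, 350), max_mm = 2,
                             max_gap = 5))
})
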