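test_that("bisection produces isometric halves that reconstruct the read", {
  r90 <- random_dna(90)
  h <- bisect_read(r90)
  expect_equal(nchar(h$left), 45)
  expect_equal(nchar(h$right), 45)
  expect_equal(paste0(h$left, h$right), r90)

  r91 <- random_dna(91)
  h91 <- bisect_read(r91)
  expect_equal(h91$half_len, 45)
  expect_equal(paste0(h91$left, substr(r91, 46, 46), h91$right), r91)

  expect_null(bisect_read(random_dna(30), min_half = 20))
})

test_that("half-read regions extend one half-length toward the junction", {
  # left half (45 nt) mapped plus at 101: junction window to the right
  r <- fused_region_from_hum(list(pos = 101, strand = "+"), 45, "left",
                             "upstream", transcript_len = 1000)
  expect_equal(c(r$start, r$end), c(146, 190))
  # right half mapped plus at 200: window to the left
  r2 <- fused_region_from_hum(list(pos = 200, strand = "+"), 45, "right",
                              "downstream", transcript_len = 1000)
  expect_equal(c(r2$start, r2$end), c(155, 199))
  # clipping at the transcript start
  r3 <- fused_region_from_hum(list(pos = 10, strand = "+"), 45, "right",
                              "downstream", transcript_len = 1000)
  expect_equal(c(r3$start, r3$end), c(1, 9))
  # a minus-strand hit mirrors the side of the unmapped half
  r4 <- fused_region_from_hum(list(pos = 101, strand = "-"), 45, "left",
                              "upstream", transcript_len = 1000)
  expect_equal(c(r4$start, r4$end), c(56, 100))
})

test_that("span-read intervals follow the printed insert-size formulas", {
  p <- list(MP1 = 100, MP2 = 500, RL1 = 90, RL2 = 90, INS = 200, SD = 20,
            FLB = 5)
  fr <- fused_region_from_span(p)
  # oracle: direct evaluation of the interval formulas
  up_expect <- c(p$MP1 + p$RL1 - p$FLB,
                 p$MP1 + p$INS + 3 * p$SD - p$RL2 + p$FLB - 1)
  dn_expect <- c(p$MP2 + p$RL2 - p$INS - 3 * p$SD + p$RL1 - p$FLB,
                 p$MP2 + p$FLB - 1)
  expect_equal(c(fr$upstream$start, fr$upstream$end), up_expect)
  expect_equal(c(fr$upstream$start, fr$upstream$end), c(185, 274))
  expect_equal(c(fr$downstream$start, fr$downstream$end), dn_expect)
  expect_equal(c(fr$downstream$start, fr$downstream$end), c(415, 504))

  # degenerate geometry: SD = 0, FLB = 0 leaves the unsequenced middle
  p0 <- list(MP1 = 100, MP2 = 500, RL1 = 90, RL2 = 90, INS = 300, SD = 0,
             FLB = 0)
  fr0 <- fused_region_from_span(p0)
  expect_equal(fr0$upstream$end - fr0$upstream$start + 1,
               p0$INS - 2 * p0$RL1)

  # clipping to transcript bounds; empty intervals disappear
  fr_clip <- fused_region_from_span(p, up_len = 200, down_len = 1000)
  expect_equal(fr_clip$upstream$end, 200)
  fr_empty <- fused_region_from_span(list(MP1 = 100, MP2 = 1, RL1 = 90,
                                          RL2 = 90, INS = 500, SD = 0,
                                          FLB = 0))
  expect_equal(nrow(fr_empty$downstream), 0)
})

test_that("credible/potential classification partitions region 2 exactly", {
  r2 <- tibble::tibble(start = 100L, end = 200L)
  r1 <- tibble::tibble(start = 150L, end = 170L)
  cls <- classify_subregions(r1, r2)
  expect_equal(cls$start, c(100L, 150L, 171L))
  expect_equal(cls$end, c(149L, 170L, 200L))
  expect_equal(cls$class, c("potential", "credible", "potential"))

  expect_equal(classify_subregions(r1[0, ], r2)$class, "potential")
  all_cred <- classify_subregions(tibble::tibble(start = 50L, end = 400L), r2)
  expect_equal(all_cred$class, "credible")

  # base-level partition property against brute-force sets
  set.seed(73)
  for (i in 1:25) {
    r2i <- tibble::tibble(start = sample(1:500, 2), width = sample(5:80, 2))
    r2i$end <- r2i$start + r2i$width
    r1i <- tibble::tibble(start = sample(1:500, 3), width = sample(3:60, 3))
    r1i$end <- r1i$start + r1i$width
    cls <- classify_subregions(r1i, r2i)
    bases2 <- exon_base_set(r2i$start, r2i$end)
    bases1 <- exon_base_set(r1i$start, r1i$end)
    got_cred <- exon_base_set(cls$start[cls$class == "credible"],
                              cls$end[cls$class == "credible"])
    got_pot <- exon_base_set(cls$start[cls$class == "potential"],
                             cls$end[cls$class == "potential"])
    if (length(got_cred) == 0) got_cred <- integer(0)
    expect_equal(got_cred, intersect(bases2, bases1))
    expect_equal(got_pot, setdiff(bases2, bases1))
    expect_equal(sort(c(got_cred, got_pot)), bases2)  # exact partition
  }
})

test_that("span-derived regions contain the true junction site", {
  # geometry-level check of the 3 SD bound: fragments sampled the way the
  # simulator sequences them, junction at U on the fused transcript
  set.seed(81)
  INS <- 200; SD <- 20; RL <- 90; FLB <- 5; U <- 1000
  n <- 4000
  hit <- logical(0)
  for (i in seq_len(n)) {
    F <- max(RL + 10, round(rnorm(1, INS, SD)))
    s <- sample(seq(U - F + 1, U), 1)        # fragment overlapping U
    e <- s + F - 1
    # span read: neither end crosses the junction
    if (s + RL - 1 > U || e - RL + 1 <= U) next
    MP1 <- s
    MP2 <- 1 + (e - RL + 1) - (U + 1)        # leftmost coord on downstream
    fr <- fused_region_from_span(list(MP1 = MP1, MP2 = MP2, RL1 = RL,
                                      RL2 = RL, INS = INS, SD = SD,
                                      FLB = FLB))
    D <- 1
    hit <- c(hit,
             U >= fr$upstream$start && U <= fr$upstream$end &&
               D >= fr$downstream$start && D <= fr$downstream$end)
  }
  expect_gt(length(hit), 300)
  expect_gte(mean(hit), 0.99)
})
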