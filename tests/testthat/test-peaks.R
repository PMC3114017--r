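score_track1 <- function(v) as_track(chr1 = v, kind = "score")

test_that("candidate regions are maximal super-cutoff runs with max-score statistics", {
  t <- numeric(40)
  t[12:20] <- 3
  t[15] <- 7
  r <- call_candidate_regions(score_track1(t), cutoff = 2)
  expect_equal(r$start, 12L)
  expect_equal(r$end, 20L)
  expect_equal(r$t_max, 7)
  expect_equal(r$pos_max, 15L)

  # ties at the cutoff are excluded (strictly greater than)
  t2 <- c(0, 2, 2, 3, 2, 0)
  r2 <- call_candidate_regions(score_track1(t2), cutoff = 2)
  expect_equal(r2$start, 4L)
  expect_equal(r2$end, 4L)

  # leftmost position wins score ties
  t3 <- numeric(10); t3[c(3, 7)] <- 5
  r3 <- call_candidate_regions(score_track1(t3), cutoff = 1,
                               merge_distance = 100)
  expect_equal(r3$pos_max, 3L)
})

test_that("runs separated by less than the merge distance are merged", {
  t <- numeric(400)
  t[10:20] <- 5
  t[71:80] <- 4      # gap of 50 bp
  t[231:240] <- 3    # gap of 150 bp
  r <- call_candidate_regions(score_track1(t), cutoff = 2,
                              merge_distance = 100)
  expect_equal(nrow(r), 2L)
  expect_equal(r$start, c(10L, 231L))
  expect_equal(r$end, c(80L, 240L))
  expect_equal(r$t_max, c(5, 3))

  # a gap of exactly merge_distance does not merge
  t4 <- numeric(100); t4[10] <- 5; t4[10 + 100 - 60] <- 5  # gap 39
  r4 <- call_candidate_regions(score_track1(t4), cutoff = 1,
                               merge_distance = 39)
  expect_equal(nrow(r4), 2L)
  r5 <- call_candidate_regions(score_track1(t4), cutoff = 1,
                               merge_distance = 40)
  expect_equal(nrow(r5), 1L)
})

test_that("every super-cutoff position is covered and regions are well separated", {
  set.seed(41)
  for (i in 1:10) {
    t <- pmax(0, cumsum(rnorm(500)))  # wandering score with runs
    cutoff <- quantile(t, 0.8)
    md <- sample(c(0, 10, 50), 1)
    r <- call_candidate_regions(score_track1(t), cutoff, md)
    covered <- logical(500)
    for (j in seq_len(nrow(r))) covered[r$start[j]:r$end[j]] <- TRUE
    expect_true(all(covered[t > cutoff]))
    expect_true(all(r$t_max > cutoff))
    if (nrow(r) > 1)
      expect_true(all(r$start[-1] - r$end[-nrow(r)] - 1 >= md))
  }
})

test_that("raising the cutoff shrinks the covered position set", {
  set.seed(43)
  t <- pmax(0, rnorm(800, 1))
  cov_at <- function(cut) {
    r <- call_candidate_regions(score_track1(t), cut, 20)
    sum(r$end - r$start + 1)
  }
  covs <- vapply(c(0.5, 1, 1.5, 2, 2.5), cov_at, numeric(1))
  expect_true(all(diff(covs) <= 0))
})

test_that("an empty or all-sub-cutoff track yields an empty region table", {
  r <- call_candidate_regions(score_track1(rep(0.5, 50)), cutoff = 2)
  expect_equal(nrow(r), 0L)
  expect_named(r, c("chrom", "start", "end", "t_max", "pos_max"))
})

test_that("region matching measures exclusive edge gaps with overlap as zero", {
  a <- data.frame(chrom = "chr1", start = 50L, end = 100L)
  b1 <- data.frame(chrom = "chr1", start = 349L, end = 400L)  # gap 248
  b2 <- data.frame(chrom = "chr1", start = 352L, end = 400L)  # gap 251
  expect_true(region_overlap(a, b1, within = 250))
  expect_false(region_overlap(a, b2, within = 250))

  # identical lists match; disjoint chromosomes never match
  expect_true(all(region_overlap(b1, b1)))
  b3 <- b1; b3$chrom <- "chr2"
  expect_false(region_overlap(a, b3, within = 1e6))

  # overlapping regions are at distance zero
  expect_true(region_overlap(a, data.frame(chrom = "chr1", start = 90L,
                                           end = 95L), within = 0))
})

test_that("region matching agrees with the all-pairs oracle", {
  set.seed(44)
  for (i in 1:20) {
    rand_regions <- function(n) {
      s <- sample.int(2000, n)
      data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                 start = s, end = s + sample.int(100, n))
    }
    a <- rand_regions(8)
    b <- rand_regions(6)
    w <- sample(c(0, 50, 250), 1)
    expect_equal(region_overlap(a, b, w), oracle_overlap(a, b, w))
  }
})
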