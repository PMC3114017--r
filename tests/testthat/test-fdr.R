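test_that("label permutation preserves sizes and the pooled multiset", {
  set.seed(51)
  control <- random_read_set(3, label = "control")
  ip <- random_read_set(5, label = "IP")
  perm <- permute_labels(control, ip, seed = 99)
  expect_equal(total_mapped(perm$control), 3L)
  expect_equal(total_mapped(perm$ip), 5L)
  key <- function(...) sort(unlist(lapply(list(...), permpeaks:::read_key)))
  expect_equal(key(perm$control, perm$ip), key(control, ip))

  # deterministic under the seed, different across seeds (w.h.p.)
  perm2 <- permute_labels(control, ip, seed = 99)
  expect_identical(perm$control$pos, perm2$control$pos)
  big_c <- random_read_set(20); big_i <- random_read_set(20)
  pA <- permute_labels(big_c, big_i, seed = 1)
  pB <- permute_labels(big_c, big_i, seed = 2)
  expect_false(identical(pA$control$pos, pB$control$pos))

  expect_error(permute_labels(read_set(), ip), "non-empty")
})

test_that("the FDR threshold reproduces the hand-enumerated example", {
  null <- structure(list(n_perm = 2L,
                         null_scores = list(c(5, 3), c(7, 1))),
                    class = "permutation_null")
  res <- fdr_threshold(c(10, 8, 6, 4), null, fdr_level = 0.05)
  # FDR(8) = 0/2 = 0; FDR(6) = 0.5/3 fails; so threshold 8, two significant
  expect_equal(res$threshold, 8)
  expect_equal(res$n_significant, 2L)
  expect_equal(res$fdr_curve$fdr[res$fdr_curve$threshold == 6], 0.5 / 3)
})

test_that("threshold edge cases: clean separation, level 1, hopeless nulls", {
  null_lo <- structure(list(n_perm = 3L,
                            null_scores = list(c(1, 2), c(0.5), numeric(0))),
                       class = "permutation_null")
  obs <- c(9, 5, 4)
  res <- fdr_threshold(obs, null_lo, 0.05)
  expect_equal(res$threshold, 4)          # all null below min(observed)
  expect_equal(res$n_significant, 3L)

  null_hi <- structure(list(n_perm = 2L,
                            null_scores = list(rep(100, 5), rep(90, 5))),
                       class = "permutation_null")
  res_hi <- fdr_threshold(obs, null_hi, 0.05)
  expect_equal(res_hi$threshold, Inf)
  expect_equal(res_hi$n_significant, 0L)

  res_1 <- fdr_threshold(obs, null_hi, fdr_level = 1)
  expect_equal(res_1$threshold, min(obs))

  expect_error(fdr_threshold(numeric(0), null_lo), "no observed")
})

test_that("the monotonized FDR curve is non-increasing in the threshold", {
  set.seed(52)
  null <- structure(list(n_perm = 5L,
                         null_scores = replicate(5, runif(30, 0, 10),
                                                 simplify = FALSE)),
                    class = "permutation_null")
  res <- fdr_threshold(runif(40, 0, 12), null, 0.1)
  expect_true(all(diff(res$fdr_curve$fdr) <= 0 + 1e-12) ||
              all(diff(rev(res$fdr_curve$fdr)) >= -1e-12))
  # ascending thresholds: monotonized FDR must not increase
  expect_true(all(diff(res$fdr_curve$fdr) <= 1e-12))
})

test_that("fdr_threshold agrees with the double-loop oracle", {
  set.seed(53)
  for (i in 1:30) {
    obs <- round(runif(sample(3:50, 1), 0, 10), 2)
    nulls <- replicate(sample(2:6, 1),
                       round(runif(sample(0:50, 1), 0, 10), 2),
                       simplify = FALSE)
    null <- structure(list(n_perm = length(nulls), null_scores = nulls),
                      class = "permutation_null")
    lev <- sample(c(0.01, 0.05, 0.2, 1), 1)
    got <- fdr_threshold(obs, null, lev)
    want <- oracle_fdr_threshold(obs, nulls, lev)
    expect_equal(got$threshold, want$threshold)
    expect_equal(got$n_significant, as.integer(want$n_significant))
  }
})

test_that("fewer regions pass at stricter FDR levels", {
  set.seed(54)
  null <- structure(list(n_perm = 4L,
                         null_scores = replicate(4, runif(25, 0, 10),
                                                 simplify = FALSE)),
                    class = "permutation_null")
  obs <- runif(30, 0, 12)
  ns <- vapply(c(0.01, 0.05, 0.1, 0.5, 1),
               function(a) fdr_threshold(obs, null, a)$n_significant,
               integer(1))
  expect_true(all(diff(ns) >= 0))
})

test_that("permutation nulls are reproducible and respect the cutoff", {
  set.seed(55)
  g <- tiny_genome(c(chr1 = 3000L))
  control <- random_read_set(300, L = 3000L, read_length = c(20L, 20L),
                             label = "control")
  ip <- random_read_set(300, L = 3000L, read_length = c(20L, 20L),
                        label = "IP")
  n1 <- permutation_null(control, ip, g, fragment_length = 60,
                         cutoff = 1.2, n_perm = 3, seed = 7)
  n2 <- permutation_null(control, ip, g, fragment_length = 60,
                         cutoff = 1.2, n_perm = 3, seed = 7)
  expect_identical(n1$null_scores, n2$null_scores)
  expect_equal(n1$n_perm, 3L)

  # a cutoff above every permuted score leaves the null lists empty
  hi <- permutation_null(control, ip, g, fragment_length = 60,
                         cutoff = 1e6, n_perm = 2, seed = 7)
  expect_true(all(lengths(hi$null_scores) == 0L))
})
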