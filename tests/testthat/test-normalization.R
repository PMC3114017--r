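test_that("depth scaling multiplies by theta * 1e6 / total_mapped", {
  tr <- as_track(chr1 = c(0L, 3L, 1L), kind = "coverage")
  expect_equal(scale_counts(tr, 1e6)$chr1, c(0, 3, 1))        # factor 1
  expect_equal(scale_counts(tr, 2e6)$chr1, c(0, 1.5, 0.5))
  expect_equal(scale_counts(tr, 5e5, theta = 2)$chr1, c(0, 12, 4))
  zero <- as_track(chr1 = integer(5), kind = "coverage")
  expect_true(all(scale_counts(zero, 1000)$chr1 == 0))
  expect_error(scale_counts(tr, 0), "total_mapped")
})

test_that("doubling every read leaves scaled values unchanged", {
  tr <- as_track(chr1 = c(2L, 4L, 0L, 6L), kind = "coverage")
  doubled <- as_track(chr1 = c(4L, 8L, 0L, 12L), kind = "coverage")
  expect_equal(scale_counts(tr, 1000)$chr1,
               scale_counts(doubled, 2000)$chr1)
})

test_that("moment matching reproduces the hand-computed affine transform", {
  control <- as_track(chr1 = c(0, 0, 2, 2))   # mean 1, population sd 1
  ip <- as_track(chr1 = c(0, 0, 0, 4))        # mean 1, population sd sqrt(3)
  mm <- moment_match(ip, control)
  expect_equal(mm$params$mean_control, 1)
  expect_equal(mm$params$sd_ip, sqrt(3))
  s3 <- 1 / sqrt(3)
  expect_equal(mm$track$chr1, c(1 - s3, 1 - s3, 1 - s3, 1 + 3 * s3),
               tolerance = 1e-12)
})

test_that("moment matching is a fixed point on identical tracks and errors on constants", {
  tr <- as_track(chr1 = c(1, 5, 2, 0), chr2 = c(3, 3, 0, 1))
  mm <- moment_match(tr, tr)
  expect_equal(mm$track$chr1, tr$chr1)
  expect_equal(mm$track$chr2, tr$chr2)

  flat <- as_track(chr1 = rep(2, 4), chr2 = rep(2, 4))
  expect_error(moment_match(flat, tr), "IP")
  expect_error(moment_match(tr, flat), "control")
  other <- as_track(chrX = c(1, 2))
  expect_error(moment_match(tr, other), "chromosome")
})

test_that("matched moments agree with the control to near machine precision", {
  set.seed(21)
  for (i in 1:20) {
    control <- as_track(chr1 = rpois(300, 4) * 1.7, chr2 = rpois(200, 2) * 1.7)
    ip <- as_track(chr1 = rpois(300, 9) * 0.4, chr2 = rpois(200, 1) * 0.4)
    mm <- moment_match(ip, control)
    mo <- permpeaks:::track_moments(mm$track)
    scale <- max(1, abs(mm$params$mean_control))
    expect_lt(abs(mo$mean - mm$params$mean_control), 1e-9 * scale)
    expect_lt(abs(mo$sd - mm$params$sd_control), 1e-9 * scale)
  }
})

test_that("moment matching is affine and order-preserving", {
  set.seed(22)
  control <- as_track(chr1 = runif(100, 0, 5))
  ip <- as_track(chr1 = runif(100, 0, 9))
  mm <- moment_match(ip, control)
  expect_equal(order(mm$track$chr1), order(ip$chr1))
})

test_that("background level defaults to the mean over nonzero IP positions", {
  ip_raw <- as_track(chr1 = c(0L, 0L, 2L, 4L), kind = "coverage")
  params <- list(mean_control = 1, sd_control = 1, mean_ip = 1, sd_ip = 1)
  bg <- compute_background(ip_raw, total_mapped = 1e6, params = params)
  expect_equal(bg$n0, 2L)
  expect_equal(bg$c, 3)

  # user-supplied c bypasses the estimate
  bg5 <- compute_background(ip_raw, 1e6, params, c_user = 5)
  expect_equal(bg5$c, 5)

  # identity transforms: beta equals c
  expect_equal(bg$beta, 3)

  zero <- as_track(chr1 = integer(4), kind = "coverage")
  expect_error(compute_background(zero, 1e6, params), "all zero")
})

test_that("beta is c carried through scaling and moment matching", {
  ip_raw <- as_track(chr1 = c(0L, 6L, 3L), kind = "coverage")
  params <- list(mean_control = 10, sd_control = 2, mean_ip = 30, sd_ip = 8)
  bg <- compute_background(ip_raw, total_mapped = 2e5, params = params,
                           theta = 1)
  c_scaled <- 4.5 * 1e6 / 2e5
  expect_equal(bg$beta, (c_scaled - 30) * (2 / 8) + 10)
})

test_that("flooring the control is a pointwise max and idempotent", {
  control <- as_track(chr1 = c(0, 1, 5))
  floored <- floor_control(control, 2)
  expect_equal(floored$chr1, c(2, 2, 5))
  expect_equal(floor_control(floored, 2)$chr1, floored$chr1)
  # beta below the minimum: identity
  expect_equal(floor_control(control, -1)$chr1, control$chr1)
  # never decreases, never below beta
  set.seed(5)
  v <- runif(50, 0, 4)
  f <- floor_control(as_track(chr1 = v), 1.5)$chr1
  expect_true(all(f >= v) && all(f >= 1.5))
})
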