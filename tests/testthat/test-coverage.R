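test_that("extension intervals follow the 5' anchoring convention", {
  g <- tiny_genome(c(chr1 = 60L))
  # one + read with no - strand support: minimum-mode coverage is zero
  plus <- read_set("chr1", 10L, "+", 5L)
  expect_true(all(extend_and_count(plus, g, 20)$chr1 == 0L))
  fwd <- extend_and_count(plus, g, 20, strand_mode = "forward")$chr1
  expect_equal(which(fwd == 1L), 10:29)

  # a +/- pair from the same 20 bp fragment reconstructs it on both strands
  pair <- read_set(c("chr1", "chr1"), c(10L, 25L), c("+", "-"), c(5L, 5L))
  x <- extend_and_count(pair, g, 20)$chr1
  expect_equal(which(x == 1L), 10:29)
  expect_true(all(x[-(10:29)] == 0L))

  # empty read set: all-zero track
  empty <- extend_and_count(read_set(), g, 20)
  expect_true(all(empty$chr1 == 0L))
  expect_length(empty$chr1, 60L)
})

test_that("identical reads stack additively on their strand", {
  g <- tiny_genome(c(chr1 = 100L))
  k <- 7L
  rs <- read_set(rep("chr1", k), rep(30L, k), rep("+", k), rep(10L, k))
  sc <- strand_counts(rs, g, 25)
  expect_equal(unique(sc$forward$chr1[30:54]), k)
  expect_true(all(sc$reverse$chr1 == 0L))
})

test_that("coverage matches the interval-stabbing oracle and is clipped at edges", {
  set.seed(42)
  g <- tiny_genome(c(chr1 = 1000L))
  for (rep in 1:5) {
    rs <- random_read_set(50, L = 1000L)
    for (mode in c("minimum", "forward", "reverse", "sum")) {
      expect_equal(extend_and_count(rs, g, 30, strand_mode = mode)$chr1,
                   as.integer(oracle_coverage(rs, 1000L, 30, mode)),
                   label = mode)
    }
  }
  # reads whose extension would cross the chromosome ends are clipped
  edge <- read_set(c("chr1", "chr1"), c(1L, 995L), c("-", "+"),
                   c(5L, 5L))
  gS <- tiny_genome(c(chr1 = 1000L))
  sc <- strand_counts(edge, gS, 50)
  expect_equal(which(sc$reverse$chr1 == 1L), 1:5)       # clipped left
  expect_equal(which(sc$forward$chr1 == 1L), 995:1000)  # clipped right
})

test_that("single-strand mass is conserved as clipped extension length", {
  set.seed(9)
  g <- tiny_genome(c(chr1 = 300L))
  rs <- random_read_set(30, L = 300L)
  fl <- 40
  sc <- strand_counts(rs, g, fl)
  ext <- pmax(fl, rs$read_length)
  fwd <- rs$strand == "+"
  s <- ifelse(fwd, rs$pos, rs$pos + rs$read_length - ext)
  e <- pmin(s + ext - 1, 300)
  s <- pmax(s, 1)
  expect_equal(sum(sc$forward$chr1), sum((e - s + 1)[fwd]))
  expect_equal(sum(sc$reverse$chr1), sum((e - s + 1)[!fwd]))
})

test_that("strand-combination modes are pointwise ordered", {
  set.seed(10)
  g <- tiny_genome(c(chr1 = 500L))
  rs <- random_read_set(80, L = 500L)
  mn <- extend_and_count(rs, g, 25)$chr1
  f <- extend_and_count(rs, g, 25, "forward")$chr1
  r <- extend_and_count(rs, g, 25, "reverse")$chr1
  sm <- extend_and_count(rs, g, 25, "sum")$chr1
  expect_true(all(mn <= f) && all(mn <= r))
  expect_true(all(f <= sm) && all(r <= sm))
  expect_equal(sm, f + r)
})

test_that("translating all reads translates the track", {
  set.seed(12)
  g <- tiny_genome(c(chr1 = 600L))
  rs <- random_read_set(40, L = 400L)
  delta <- 100L
  shifted <- rs
  shifted$pos <- shifted$pos + delta
  x0 <- extend_and_count(rs, g, 30)$chr1
  x1 <- extend_and_count(shifted, g, 30)$chr1
  expect_equal(x1[(1 + delta):600], x0[1:(600 - delta)])
})

test_that("one-strand duplicate stacks cannot create minimum-mode coverage", {
  g <- tiny_genome(c(chr1 = 400L))
  rs <- read_set("chr1", 300L, "-", 10L)   # lone - read elsewhere
  stacked <- inject_onesided_stack(rs, "chr1", 100L, "+", copies = 1000,
                                   read_length = 10L)
  x <- extend_and_count(stacked, g, 30)$chr1
  expect_true(all(x[1:250] == 0L))  # opposite strand empty under the stack
  smode <- extend_and_count(stacked, g, 30, "sum")$chr1
  expect_equal(max(smode[100:129]), 1000L)
})

test_that("reads longer than the fragment length keep their footprint, with a warning", {
  g <- tiny_genome(c(chr1 = 100L))
  rs <- read_set("chr1", 10L, "+", 50L)
  expect_warning(sc <- strand_counts(rs, g, 20), "footprint")
  expect_equal(which(sc$forward$chr1 == 1L), 10:59)
})

test_that("reads on chromosomes missing from the genome are an error", {
  g <- tiny_genome(c(chr1 = 100L))
  rs <- read_set("chrZ", 10L, "+", 5L)
  expect_error(extend_and_count(rs, g, 20), "chrZ")
})
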