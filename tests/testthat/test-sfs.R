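test_that("folding collapses mirror classes and conserves sites", {
  x4 <- sfs(c(100, 7, 4, 2), n = 4)
  f4 <- fold_sfs(x4)
  expect_equal(f4$counts, c(100, 9, 4))

  x5 <- sfs(c(50, 3, 2, 1, 4), n = 5)
  expect_equal(fold_sfs(x5)$counts, c(50, 7, 3))

  # even n: the n/2 class maps to itself and is not doubled
  x6 <- sfs(c(100, 1, 2, 3, 4, 5), n = 6)
  expect_equal(fold_sfs(x6)$counts, c(100, 6, 6, 3))

  # all-zero polymorphic classes stay all-zero
  expect_equal(fold_sfs(sfs(c(10, 0, 0, 0), n = 4))$counts, c(10, 0, 0))

  expect_error(fold_sfs(fold_sfs(x4)), "already folded")

  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(3:40, 1)
    x <- sfs(c(1000, rpois(n - 1, 5)), n = n)
    expect_identical(sum(fold_sfs(x)$counts), sum(x$counts))
  }
})

test_that("a supplied fixed-derived class is absorbed into monomorphic", {
  x <- sfs(c(100, 5, 3, 2, 9), n = 4)   # class n = 4 present
  expect_equal(x$counts, c(109, 5, 3, 2))
  expect_equal(length(x$counts), 4L)
})

test_that("spectrum validation rejects malformed input", {
  expect_error(sfs(c(10, 1, 2), n = 4), "requires 4 classes")
  expect_error(sfs(c(10, 1), n = 4, folded = TRUE), "requires 3 classes")
  expect_error(sfs(c(10, -1, 2, 1), n = 4), "non-negative")
  expect_error(sfs(c(10, 1.5, 2, 1), n = 4), "non-negative")
  expect_error(sfs(c(0, 0, 0, 0), n = 4), "positive")
  expect_error(sfs(c(10, 1, 2, 3), n = 1), ">= 2")
})

test_that("masking flags classes and rejects invalid bins", {
  x <- sfs(c(100, 9, 4), n = 4, folded = TRUE)
  expect_equal(mask_sfs(x, 1)$masked_bins, 1L)
  expect_error(mask_sfs(x, 0), "1..2")
  expect_error(mask_sfs(x, 3), "1..2")
  expect_error(mask_sfs(x, 1:2), "no information")
  # empty mask behaves as unmasked
  expect_identical(sfs(c(100, 9, 4), n = 4, folded = TRUE)$masked_bins,
                   integer())
  # masked bins map through folding (class n - i collapses onto class i)
  xu <- sfs(c(100, 5, 4, 3, 2, 1), n = 6, masked_bins = 5)
  expect_equal(fold_sfs(xu)$masked_bins, 1L)
})

test_that("subsample split draws the exact training size and conserves counts", {
  x <- sfs(c(200, 60, 40), n = 4, folded = TRUE)
  set.seed(42)
  sp <- split_sfs(x, 2 / 3)
  expect_equal(sum(sp$training$counts), 200)   # round(2/3 * 300)
  expect_equal(sum(sp$testing$counts), 100)
  expect_equal(sp$training$counts + sp$testing$counts, x$counts)
  expect_identical(sp$training$folded, TRUE)
  expect_identical(sp$training$n, x$n)

  set.seed(7); a <- split_sfs(x, 0.5)
  set.seed(7); b <- split_sfs(x, 0.5)
  expect_identical(a$training$counts, b$training$counts)

  expect_error(split_sfs(x, 0), "strictly between")
  expect_error(split_sfs(x, 1), "strictly between")
})

test_that("per-class training counts have the hypergeometric mean", {
  x <- sfs(c(600, 300, 100), n = 4, folded = TRUE)
  N <- 1000; k <- 500
  R <- 1000
  set.seed(99)
  acc <- matrix(0, R, 3)
  for (r in seq_len(R)) acc[r, ] <- split_sfs(x, 0.5)$training$counts
  for (j in 1:3) {
    p <- x$counts[j] / N
    mu <- k * p
    v <- k * p * (1 - p) * (N - k) / (N - 1)
    expect_lt(abs(mean(acc[, j]) - mu), 3 * sqrt(v / R))
  }
})

test_that("blueprint files round-trip exactly", {
  x <- sfs(c(993000, 4000, 2000, 1000), n = 6, folded = TRUE,
           masked_bins = 1)
  cfg <- inference_config(B = 25, training_fraction = 2 / 3,
                          candidate_m = c(1L, 2L, 4L), mu = 1.2e-8,
                          year_per_generation = 24, seed = 77)
  path <- tempfile(fileext = ".blueprint")
  write_blueprint(x, cfg, path, popid = "toy", output_prefix = "out/toy")
  bp <- read_blueprint(path)
  expect_identical(bp$sfs$counts, x$counts)
  expect_identical(bp$sfs$n, x$n)
  expect_identical(bp$sfs$folded, TRUE)
  expect_identical(bp$sfs$masked_bins, 1L)
  expect_equal(bp$config$training_fraction, 2 / 3)
  expect_equal(bp$config$mu, 1.2e-8)
  expect_identical(bp$config$B, 25L)
  expect_identical(bp$config$candidate_m, c(1L, 2L, 4L))
  expect_identical(bp$popid, "toy")
})

test_that("blueprint parsing reports offending keys and defaults", {
  path <- tempfile()
  writeLines(c("popid: p", "nseq: 6", "total_sites: 1000",
               "folded: true", "sfs: 4 2 1", "mu: 1.2e-8"), path)
  bp <- read_blueprint(path)
  expect_equal(bp$config$training_fraction, 2 / 3)   # default when absent
  expect_identical(bp$config$B, 200L)
  expect_equal(bp$sfs$counts, c(993, 4, 2, 1))

  writeLines(c("popid: p", "nseq: 6", "total_sites: 1000",
               "folded: true", "sfs: 4 2 1 9 9", "mu: 1.2e-8"), path)
  expect_error(read_blueprint(path), "expected 3 folded class counts")

  writeLines(c("popid: p", "nseq: 6", "total_sites: 1000",
               "folded: true", "sfs: 4 2 1"), path)
  expect_error(read_blueprint(path), "'mu'")
})
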