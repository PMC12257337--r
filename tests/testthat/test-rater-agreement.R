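test_that("squared-weight kappa matches hand-computed tables", {
  # identical non-constant ratings: perfect agreement
  expect_equal(weighted_kappa(c(0, 3, 7, 2), c(0, 3, 7, 2)), 1)
  # chance-level 2x2 table with uniform marginals: kappa 0
  expect_equal(weighted_kappa(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  # reversed ordinal ratings: brute-force formula gives a negative value
  x <- c(0, 1, 2); y <- c(2, 1, 0)
  k <- length(0:2)
  O <- table(factor(x, levels = 0:2), factor(y, levels = 0:2)) / 3
  E <- outer(rowSums(O), colSums(O))
  w <- outer(1:k, 1:k, function(i, j) (i - j)^2)
  oracle <- 1 - sum(w * O) / sum(w * E)
  expect_equal(weighted_kappa(x, y), oracle, tolerance = 1e-12)
  expect_lt(weighted_kappa(x, y), 0)
  # degenerate: both raters constant and equal
  expect_warning(val <- weighted_kappa(c(2, 2, 2), c(2, 2, 2)), "kappa")
  expect_equal(val, 1)
})

test_that("kappa respects the declared category range and item order", {
  x <- c(0, 5, 10, 3)
  y <- c(1, 5, 9, 3)
  full <- weighted_kappa(x, y, categories = 0:40)
  perm <- sample(seq_along(x))
  expect_equal(weighted_kappa(x[perm], y[perm], categories = 0:40), full)
  expect_error(weighted_kappa(c(0, 50), c(0, 1), categories = 0:40),
               "outside")
})

test_that("Krippendorff alpha matches a direct pairwise-difference oracle", {
  tbl <- rbind(c(1, 1), c(2, 2), c(3, 3), c(3, 4))
  # oracle: enumerate within-item and overall pairs directly
  d_o <- mean(apply(tbl, 1, function(v) (v[1] - v[2])^2))
  pooled <- as.vector(tbl)
  n <- length(pooled)
  d_e <- sum(outer(pooled, pooled, "-")^2) / (n * (n - 1))
  oracle <- 1 - d_o / d_e
  expect_equal(krippendorff_alpha(tbl), oracle, tolerance = 1e-10)
  # identical columns: perfect agreement
  expect_equal(krippendorff_alpha(cbind(1:5, 1:5)), 1)
})

test_that("alpha handles missing ratings and degenerate inputs", {
  tbl <- rbind(c(1, 1, NA), c(2, NA, 2), c(3, 3, 3), c(NA, 4, 4))
  expect_true(is.finite(krippendorff_alpha(tbl)))
  expect_gt(krippendorff_alpha(tbl), 0.9)
  # rows with a single rating carry no pairable information
  expect_error(krippendorff_alpha(rbind(c(1, NA), c(NA, 2))),
               "pairable")
  expect_warning(val <- krippendorff_alpha(cbind(c(2, 2), c(2, 2))),
                 "alpha")
  expect_equal(val, 1)
})

test_that("alpha of a constant rater against noise stays near zero", {
  set.seed(23)
  vals <- vapply(1:100, function(i) {
    krippendorff_alpha(cbind(rep(5, 12), sample(0:10, 12, replace = TRUE)))
  }, numeric(1))
  expect_lte(mean(vals > 0.05), 0.05)
})

test_that("one-way ICC matches an explicit ANOVA oracle and stats::aov", {
  set.seed(3)
  m <- matrix(rpois(18, 20), nrow = 6, ncol = 3)
  res <- icc_oneway(m)
  # sums-of-squares oracle
  n <- 6; k <- 3
  msb <- k * sum((rowMeans(m) - mean(m))^2) / (n - 1)
  msw <- sum((m - rowMeans(m))^2) / (n * (k - 1))
  icc_oracle <- (msb - msw) / (msb + (k - 1) * msw)
  expect_equal(res$icc, icc_oracle, tolerance = 1e-10)
  # cross-check the ANOVA decomposition against stats::aov
  df <- data.frame(score = as.vector(m),
                   item = factor(rep(seq_len(n), k)))
  tab <- summary(stats::aov(score ~ item, data = df))[[1]]
  expect_equal(res$f_statistic, tab["item", "F value"], tolerance = 1e-10)
  expect_equal(res$p_value, tab["item", "Pr(>F)"], tolerance = 1e-10)
  expect_true(res$conf_low < res$icc && res$icc < res$conf_high)
})

test_that("ICC is 1 for rater-identical items and ~0 for pure rater noise", {
  m <- cbind(c(1, 5, 9, 14), c(1, 5, 9, 14), c(1, 5, 9, 14))
  expect_warning(res <- icc_oneway(m), "ICC is 1")
  expect_equal(res$icc, 1)
  set.seed(8)
  vals <- vapply(1:100, function(i) {
    icc_oneway(matrix(rnorm(30), nrow = 10, ncol = 3))$icc
  }, numeric(1))
  expect_lt(mean(vals), 0.1)
})

test_that("Bland-Altman reproduces closed-form toy summaries", {
  ba <- bland_altman(c(1, 2, 3), c(2, 3, 4))
  expect_equal(ba$mean_diff, -1)
  expect_equal(ba$sd_diff, 0)
  expect_equal(c(ba$lower_limit, ba$upper_limit), c(-1, -1))

  same <- bland_altman(c(4, 7), c(4, 7))
  expect_equal(unlist(same[1, ]), c(mean_diff = 0, sd_diff = 0,
                                    lower_limit = 0, upper_limit = 0))

  two <- bland_altman(c(0, 4), c(0, 0))
  expect_equal(two$mean_diff, 2)
  expect_equal(two$sd_diff, sqrt(8))
  expect_equal(two$upper_limit, 2 + 1.96 * sqrt(8))
  expect_equal(two$lower_limit, 2 - 1.96 * sqrt(8))
})
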