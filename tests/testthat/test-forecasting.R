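test_that("composites are unweighted item means with bounds checking", {
  expect_equal(composite_interest(c(7, 7, 7, 7, 7)), 7)
  expect_equal(composite_interest(c(1, 2, 3, 4, 5)), 3)
  expect_equal(composite_dc(rep(4, 14)), 4)
  # permutation invariance
  items <- c(2, 5, 3, 7, 1, 4, 6, 2, 5, 3, 7, 1, 4, 6)
  expect_equal(composite_dc(items), composite_dc(rev(items)))
  expect_error(composite_interest(c(1, 2, 3, 4, 9)), "\\[1, 7\\]")
  expect_error(composite_interest(c(1, 2, 3, 4)), "5 items")
  expect_message(out <- composite_interest(c(1, NA, 3, 5, 7)), "missing")
  expect_equal(out, 4)
  expect_error(composite_interest(c(1, NA, 3, 5, 7), missing = "error"),
               "missing")
})

test_that("Cronbach's alpha recovers the generating reliability", {
  # parallel items: truth variance 1, item noise tuned for alpha = 0.9
  k <- 5
  rho <- 0.9 / (k - (k - 1) * 0.9)
  set.seed(22)
  truth <- rnorm(500)
  items <- vapply(1:k, function(i) truth + rnorm(500, 0, sqrt((1 - rho) / rho)),
                  numeric(500))
  expect_lt(abs(cronbach_alpha(items) - 0.9), 0.05)
  expect_error(cronbach_alpha(matrix(1, 5, 1)), "2 items")
})

test_that("moment-wise forecasting matches closed-form correlations", {
  w <- make_windows(10, 5, 1, 10)
  # metric proportional to outcome at every window: r = 1
  outcome <- c(2, 4, 6, 9)
  metric <- matrix(rep(outcome * 3 + 1, each = nrow(w)), nrow(w))
  fc <- momentwise_forecast(metric, outcome, w)
  expect_true(all(abs(fc$r - 1) < 1e-12))
  # point-biserial on the hand-computable fixture equals Pearson on 0/1
  m <- matrix(c(1, 2, 3, 4), 1)
  fb <- momentwise_forecast(m, c(0, 0, 1, 1))
  expect_equal(fb$method, "point-biserial")
  expect_equal(fb$r, 2 / sqrt(5), tolerance = 1e-12)   # brute-force Pearson
  expect_equal(fb$r, cor(c(1, 2, 3, 4), c(0, 0, 1, 1)), tolerance = 1e-12)
  # Spearman is invariant under monotone transforms of the metric
  set.seed(23)
  m2 <- matrix(rnorm(5 * 8), 5)
  y <- rnorm(8)
  fs1 <- momentwise_forecast(m2, y, method = "spearman")
  fs2 <- momentwise_forecast(exp(3 * m2), y, method = "spearman")
  expect_equal(fs1$r, fs2$r, tolerance = 1e-12)
  # constant metric flagged, not propagated as a number
  fc3 <- momentwise_forecast(matrix(1, 2, 5), rnorm(5))
  expect_true(all(fc3$flagged))
  expect_true(all(is.na(fc3$r)))
  expect_error(momentwise_forecast(matrix(1, 2, 3), 1:3), ">= 4 videos")
})

test_that("null forecasts reject at the nominal rate", {
  set.seed(24)
  hits <- 0L
  total <- 0L
  for (s in 1:200) {
    metric <- matrix(rnorm(10 * 14), 10)
    outcome <- rnorm(14)
    fc <- momentwise_forecast(metric, outcome)
    hits <- hits + length(significance_mask(fc))
    total <- total + nrow(fc)
  }
  rate <- hits / total
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.08)
})

test_that("bootstrap CIs are seeded, degenerate-safe, and well calibrated", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  y <- 2 * x + 3
  ci <- bootstrap_ci(x, y, n_boot = 200, seed = 1)
  expect_equal(as.numeric(ci), c(1, 1))             # perfect correlation
  # determinism
  set.seed(25)
  x2 <- rnorm(14); y2 <- rnorm(14)
  expect_identical(bootstrap_ci(x2, y2, n_boot = 300, seed = 9),
                   bootstrap_ci(x2, y2, n_boot = 300, seed = 9))
  # binary outcome: degenerate resamples are redrawn, not propagated
  yb <- c(rep(0, 12), 1, 1)
  cib <- bootstrap_ci(x2, yb, n_boot = 300, seed = 10)
  expect_gt(attr(cib, "n_redrawn"), 0)
  expect_true(all(is.finite(cib)))
  # null coverage: CI straddles 0 in about 95% of draws
  set.seed(26)
  covered <- vapply(1:60, function(i) {
    a <- rnorm(14); b <- rnorm(14)
    ci <- bootstrap_ci(a, b, n_boot = 400, seed = i)
    ci[1] < 0 && ci[2] > 0
  }, logical(1))
  expect_gte(mean(covered), 0.85)
  expect_error(bootstrap_ci(x, y, n_boot = 50), "n_boot")
  expect_error(bootstrap_ci(1:3, 1:3), ">= 4 videos")
})

test_that("bootstrap CIs tighten as the video count grows", {
  set.seed(27)
  width <- vapply(c(14, 56), function(n) {
    mean(vapply(1:10, function(i) {
      x <- rnorm(n)
      y <- 0.6 * x + rnorm(n, 0, 0.8)       # fixed effect size
      ci <- bootstrap_ci(x, y, n_boot = 400, seed = i)
      ci[2] - ci[1]
    }, numeric(1)))
  }, numeric(1))
  expect_lt(width[2], width[1])
})

test_that("significance masks honor the level and the FDR variant", {
  fc <- momentwise_forecast(matrix(rnorm(6 * 10), 6), rnorm(10))
  fc$p <- c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5)
  expect_length(significance_mask(fc), 0)
  fc$p <- rep(0.001, 6)
  expect_identical(significance_mask(fc), 1:6)
  fc$p <- c(0.001, 0.04, 0.04, 0.04, 0.5, 0.5)
  expect_true(length(significance_mask(fc, adjust = "fdr")) <=
                length(significance_mask(fc)))
})
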