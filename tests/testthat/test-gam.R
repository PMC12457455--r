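test_that("a noise-free linear signal is recovered exactly", {
  x <- seq(0, 1, length.out = 120)
  y <- 2 * x
  fit <- suppressWarnings(fit_smooth(x, y))
  su <- summarize_fit(fit)
  ols <- unname(coef(lm(y ~ x))[2])
  expect_equal(su$mean_rate, ols, tolerance = 1e-6)
  expect_equal(su$mean_abs_rate, ols, tolerance = 1e-6)
  expect_gt(fit$null_dev_prop, 1 - 1e-6)
  expect_identical(su$argmax_x, max(x))   # monotone increasing
  expect_identical(su$argmin_x, min(x))
})

test_that("a constant response yields a flat fit explaining nothing", {
  x <- seq(0, 1, length.out = 50)
  fit <- fit_smooth(x, rep(0.3, 50))
  expect_equal(fit$null_dev_prop, 0)
  su <- summarize_fit(fit)
  expect_equal(su$mean_rate, 0)
  expect_equal(su$mean_abs_rate, 0)
})

test_that("effective degrees of freedom respect the basis cap", {
  set.seed(707)
  x <- runif(300)
  y <- sin(2 * pi * x) + rnorm(300, 0, 0.2)
  fit <- fit_smooth(x, y, basis_dim = 4)
  expect_lte(fit$edf, 4)
  expect_gte(fit$null_dev_prop, 0)
  expect_lte(fit$null_dev_prop, 1)
})

test_that("summaries obey mean_abs_rate >= |mean_rate|", {
  set.seed(808)
  for (i in 1:10) {
    x <- runif(100)
    y <- rnorm(100, sin(3 * x), 0.3)
    su <- summarize_fit(fit_smooth(x, y))
    expect_gte(su$mean_abs_rate, abs(su$mean_rate) - 1e-12)
  }
})

test_that("a hump-shaped effect places argmax near the true peak", {
  set.seed(909)
  hits <- 0L
  n_sim <- 25L
  for (i in seq_len(n_sim)) {
    x <- runif(400)
    y <- exp(-((x - 0.45) / 0.18)^2) + rnorm(400, 0, 0.15)
    su <- summarize_fit(fit_smooth(x, y))
    if (abs(su$argmax_x - 0.45) <= 0.1) hits <- hits + 1L
  }
  expect_gte(hits / n_sim, 0.9)
})

test_that("the uncertainty band covers a known truth pointwise", {
  set.seed(1010)
  x <- seq(0, 1, length.out = 400)
  truth <- function(x) 0.5 + 0.3 * x - 0.2 * x^2
  cover <- numeric(20)
  for (i in 1:20) {
    y <- truth(x) + rnorm(400, 0, 0.1)
    ev <- evaluate_smooth(fit_smooth(x, y), grid_n = 100)
    cover[i] <- mean(truth(ev$x) >= ev$lower & truth(ev$x) <= ev$upper)
  }
  expect_gte(mean(cover), 0.9)
})

test_that("degenerate predictors are rejected", {
  expect_error(fit_smooth(rep(1, 50), rnorm(50)), "distinct")
  expect_error(fit_smooth(1:5, 1:5), "at least 10")
})
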