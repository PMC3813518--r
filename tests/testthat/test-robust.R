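test_that("confidence ranks map linearly to case weights", {
  expect_equal(acid_to_weight(6), 1)
  expect_equal(acid_to_weight(1), 1 / 6)
  expect_equal(acid_to_weight(c(2, 3)), c(2, 3) / 6)
  expect_error(acid_to_weight(0), "1..6")
  expect_error(acid_to_weight(7), "1..6")
  expect_error(acid_to_weight(2.5), "1..6")
})

test_that("standardize centers to mean 0 and sample SD 1, and is idempotent", {
  expect_equal(as.numeric(standardize(c(1, 2, 3))), c(-1, 0, 1))
  expect_error(standardize(c(5, 5, 5)), "constant")
  set.seed(7)
  x <- stats::rnorm(20, 50, 9)
  z <- as.numeric(standardize(x))
  expect_equal(mean(z), 0)
  expect_equal(stats::sd(z), 1)
  expect_equal(as.numeric(standardize(z)), z)
})

test_that("an exact linear relationship is fit exactly with a zero-width CI", {
  x <- 2000:2010
  f <- fit_robust(x, 2 * x + 1, rep(1, 11))
  expect_equal(f$slope, 2)
  expect_equal(f$ci[2] - f$ci[1], 0)
  expect_equal(f$r_squared, 1)
  expect_true(f$exact_fit)
})

test_that("one gross outlier cannot move the robust slope (OLS breaks, LTS agrees)", {
  x <- 1:11
  y <- 2 * x + 1
  y[11] <- y[11] * 100
  f <- fit_robust(x, y, rep(1, 11))
  expect_lt(abs(f$slope - 2), 1e-3)
  expect_gt(abs(ols_slope(x, y) - 2), 0.5)
  expect_lt(abs(lts_slope(x, y) - 2), 1e-8)
})

test_that("breakdown: 20% arbitrarily large contamination barely moves the slope", {
  set.seed(5)
  n <- 20
  x <- seq_len(n)
  y_clean <- as.numeric(standardize(0.1 * x + stats::rnorm(n, sd = 0.05)))
  f_clean <- fit_robust(x, y_clean, rep(1, n))
  for (magnitude in c(1e3, 1e6)) {
    for (n_bad in 1:4) {
      y <- y_clean
      y[seq_len(n_bad)] <- magnitude
      f <- fit_robust(x, y, rep(1, n))
      expect_lt(abs(f$slope - f_clean$slope), 0.05)
      expect_lt(abs(lts_slope(x, y) - f_clean$slope), 0.05)
    }
  }
})

test_that("clean Gaussian data: robust slope tracks OLS with near-full efficiency", {
  set.seed(9)
  n <- 100
  reps <- 150
  slope_r <- slope_o <- numeric(reps)
  for (i in seq_len(reps)) {
    x <- seq_len(n)
    y <- 0.02 * x + stats::rnorm(n)
    slope_r[i] <- fit_robust(x, y, rep(1, n))$slope
    slope_o[i] <- ols_slope(x, y)
  }
  diff <- slope_r - slope_o
  # centred on the OLS slope within Monte-Carlo error
  expect_lt(abs(mean(diff)), 3 * stats::sd(diff) / sqrt(reps) + 1e-12)
  # variance within 1.3x the OLS variance (95% Gaussian efficiency target)
  expect_lt(stats::var(slope_r) / stats::var(slope_o), 1.3)
})

test_that("robust fit agrees with an independent MM implementation on clean data", {
  skip_if_not_installed("MASS")
  set.seed(31)
  for (i in 1:5) {
    n <- 40
    x <- seq_len(n)
    y <- 0.05 * x + stats::rnorm(n, sd = 0.5)
    ours <- fit_robust(x, y, rep(1, n))$slope
    theirs <- unname(stats::coef(MASS::rlm(y ~ x, method = "MM"))[2])
    expect_equal(ours, theirs, tolerance = 0.02)
  }
})

test_that("case weights are scale invariant and downweight low-confidence points", {
  set.seed(13)
  x <- 1:15
  y <- 0.3 * x + stats::rnorm(15, sd = 0.2)
  w <- acid_to_weight(sample(1:6, 15, replace = TRUE))
  f1 <- fit_robust(x, y, w)
  f2 <- fit_robust(x, y, 2 * w)
  expect_equal(f1$slope, f2$slope, tolerance = 1e-10)
  expect_equal(f1$se, f2$se, tolerance = 1e-10)
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-10)
})

test_that("slope sign and t-value are invariant to affine response rescaling", {
  set.seed(17)
  x <- 1:20
  y <- 0.4 * x + stats::rnorm(20)
  f <- fit_robust(x, y, rep(1, 20))
  g <- fit_robust(x, 5 * y + 100, rep(1, 20))
  expect_equal(g$slope, 5 * f$slope, tolerance = 1e-6)
  expect_equal(g$t_value, f$t_value, tolerance = 1e-6)
  expect_equal(g$r_squared, f$r_squared, tolerance = 1e-6)
})

test_that("fit_trend recovers a noise-free exponential growth rate to 1e-8", {
  r <- 0.05
  s <- make_exp_series(seq(1980, 2008, by = 1), r = r, n0 = 2000)
  w <- windowed_from(s, generation_time = 10)
  f <- fit_trend(w, "loglinear")
  expect_identical(f$model_form, "loglinear")
  expect_gt(f$slope, 0)
  expect_lt(abs(growth_rate(f) - r), 1e-8)

  s_dec <- make_exp_series(seq(1980, 2008, by = 1), r = -0.03, n0 = 2000)
  f_dec <- fit_trend(windowed_from(s_dec, 10), "loglinear")
  expect_lt(abs(growth_rate(f_dec) + 0.03), 1e-8)

  # noise-free linear series: linear model has R^2 = 1
  s_lin <- make_series(2000:2010, 100 + 5 * (0:10))
  f_lin <- fit_trend(windowed_from(s_lin, 3.5), "linear")
  expect_equal(f_lin$r_squared, 1)
})

test_that("fit_trend handles zeros, ineligibility and degenerate responses", {
  # zero abundance under loglinear: offset of 1, population retained
  s0 <- make_series(1990:2008, c(0, seq(5, 90, length.out = 18)))
  f0 <- fit_trend(windowed_from(s0, 6), "loglinear")
  expect_s3_class(f0, "trend_fit")
  expect_equal(f0$log_offset, 1)

  # ineligible window yields the unknown sentinel
  s_short <- make_exp_series(c(2000, 2004, 2008), r = 0.02)
  f_short <- fit_trend(windowed_from(s_short, 10), "loglinear")
  expect_s3_class(f_short, "unknown_fit")
  expect_identical(classify_trend(f_short), "UNKNOWN")

  # constant response cannot be standardized: unknown with reason
  s_const <- make_series(1990:2008, rep(500, 19))
  f_const <- fit_trend(windowed_from(s_const, 6), "linear")
  expect_s3_class(f_const, "unknown_fit")
  expect_match(f_const$reason, "constant")
})

test_that("model comparison prefers the larger robust R-squared with a 0.01 tie band", {
  mk <- function(r2) {
    structure(
      list(model_form = "linear", r_squared = r2, converged = TRUE),
      class = "trend_fit"
    )
  }
  bad <- unknown_fit <- structure(
    list(model_form = "linear", converged = FALSE),
    class = "unknown_fit"
  )
  expect_identical(compare_models(mk(0.6), mk(0.8)), "loglinear_better")
  expect_identical(compare_models(mk(0.8), mk(0.6)), "linear_better")
  expect_identical(compare_models(mk(0.700), mk(0.705)), "similar")
  expect_identical(compare_models(bad, mk(0.2)), "loglinear_better")
  expect_identical(compare_models(mk(0.2), bad), "linear_better")
  expect_identical(compare_models(bad, bad), "unknown")
})
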