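test_that("noise-free simulation reproduces the latent exponential exactly", {
  cfg <- sim_config(
    n_populations = 1, year_range = c(2000, 2010),
    growth_rate = 0.05, initial_abundance = 1000,
    survey_gap_mean = 1, cv_by_rank = rep(0, 6), seed = 3
  )
  out <- simulate_trajectory(cfg)
  expect_equal(out$series$year, 2000:2010)
  expect_equal(
    out$series$abundance,
    1000 * exp(0.05 * (2000:2010 - 2000))
  )
  # downstream fit recovers r essentially exactly
  f <- fit_trend(select_window(out$series, 3.5), "loglinear")
  expect_lt(abs(growth_rate(f) - 0.05), 1e-8)
})

test_that("simulation is deterministic under a fixed seed and varies with it", {
  cfg <- sim_config(n_populations = 2, seed = 11)
  a <- simulate_nested_dataset(cfg)
  b <- simulate_nested_dataset(cfg)
  expect_identical(a, b)
  c <- simulate_nested_dataset(sim_config(n_populations = 2, seed = 12))
  expect_false(identical(a$abundance$year, c$abundance$year))
  expect_identical(a$truth$r, c$truth$r)
})

test_that("lognormal observation error is mean-unbiased on the natural scale", {
  # E[log obs] = log N - sigma^2/2 with sigma^2 = log(1 + CV^2)
  cv <- 0.2
  sigma2 <- log(1 + cv^2)
  logs <- numeric(1000)
  for (i in 1:1000) {
    cfg <- sim_config(
      n_populations = 1, year_range = c(2000, 2029),
      growth_rate = 0, initial_abundance = 1000,
      survey_gap_mean = 1, cv_by_rank = rep(cv, 6), seed = 20000 + i
    )
    logs[i] <- mean(log(simulate_trajectory(cfg)$series$abundance))
  }
  expected <- log(1000) - sigma2 / 2
  mc_se <- stats::sd(logs) / sqrt(length(logs))
  expect_lt(abs(mean(logs) - expected), 4 * mc_se)
})

test_that("sub-population latent abundances sum to the parent's", {
  cfg <- sim_config(
    n_populations = 2, year_range = c(1990, 2008),
    survey_gap_mean = 1, cv_by_rank = rep(0, 6), seed = 5
  )
  sim <- simulate_nested_dataset(cfg)
  # pop_02 is split into pop_02a (0.3) and pop_02b (0.7); with zero CV the
  # observed series equal the latent ones, surveyed yearly at common years
  parent <- sim$abundance[sim$abundance$population_id == "pop_02", ]
  a <- sim$abundance[sim$abundance$population_id == "pop_02a", ]
  b <- sim$abundance[sim$abundance$population_id == "pop_02b", ]
  years <- intersect(parent$year, intersect(a$year, b$year))
  expect_gt(length(years), 10)
  expect_equal(
    a$abundance[match(years, a$year)] + b$abundance[match(years, b$year)],
    parent$abundance[match(years, parent$year)]
  )
  expect_identical(
    population_contains(sim$populations)$pop_02, c("pop_02a", "pop_02b")
  )
})

test_that("depletion-recovery truth matches its construction", {
  cfg <- sim_config(
    n_populations = 1, year_range = c(1950, 2008),
    depletion = list(K = 10000, depletion_fraction = 0.1, recovery_rate = 0.4),
    seed = 9
  )
  out <- simulate_trajectory(cfg)
  tr <- out$truth
  expect_equal(tr$historical, 10000)
  expect_equal(decline_pct(tr$historical, tr$n_min), 90, tolerance = 0.01)
  # rebound at 0.4/yr over ~35 years reaches carrying capacity
  expect_gt(recovery_pct(tr$historical, tr$n_recent), 99)
  expect_lte(recovery_pct(tr$historical, tr$n_recent), 100)
})

test_that("growth-rate estimation error stays small at survey-like noise", {
  # CV = 0.15, 40 yearly surveys, r = 0.04: median absolute error of the
  # fitted growth rate stays below 0.01/yr
  reps <- 60
  err <- numeric(reps)
  for (i in seq_len(reps)) {
    cfg <- sim_config(
      n_populations = 1, year_range = c(1969, 2008),
      growth_rate = 0.04, initial_abundance = 2000,
      survey_gap_mean = 1, cv_by_rank = rep(0.15, 6),
      generation_time = 13, seed = 5000 + i
    )
    out <- simulate_trajectory(cfg)
    f <- fit_trend(select_window(out$series, 13), "loglinear")
    err[i] <- abs(growth_rate(f) - 0.04)
  }
  expect_lt(stats::median(err), 0.01)
})

test_that("simulator rejects inconsistent configurations", {
  expect_error(
    sim_config(cv_by_rank = c(0.1, 0.2, 0.2, 0.2, 0.2, 0.2)),
    "non-increasing"
  )
  expect_error(sim_config(depletion = list(
    K = 1000, depletion_fraction = 1.5, recovery_rate = 0.1
  )))
  expect_error(sim_config(n_populations = 0))
})
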