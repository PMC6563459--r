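# Gibbs orchestration: series variance, burn-in arithmetic,
# reproducibility, and recovery on synthetic areas.

test_that("series_variance is the (n-1)-denominator sample variance", {
  expect_equal(series_variance(c(2, 4, 6)), 4.0)
  expect_equal(series_variance(c(7, 7, 7, 7)), 0)
  expect_error(series_variance(5), "at least 2")

  # independent two-pass oracle on random series
  two_pass <- function(x) {
    m <- sum(x) / length(x)
    acc <- 0
    for (v in x) acc <- acc + (v - m)^2
    acc / (length(x) - 1)
  }
  set.seed(21)
  for (rep in 1:1000) {
    x <- rnorm(sample(2:30, 1), sd = runif(1, 0.1, 100))
    expect_equal(series_variance(x), two_pass(x), tolerance = 1e-10)
  }
})

test_that("burn-in arithmetic and draw shapes are exact", {
  syn <- generate_panel(synthetic_config(n_areas = 1), seed = 3)
  obs <- syn$panel[!syn$panel$is_projected, ]
  fit <- fit_model(obs$admissions, panel_X(obs),
                   fit_config(n_iterations = 200, burn_in_fraction = 0.1,
                              seed = 1), years = obs$year)
  expect_equal(nrow(fit$level_paths), 180L)
  expect_equal(ncol(fit$level_paths), 13L)
  expect_equal(dim(fit$inclusions), c(180L, 9L))
  # coefficient zero-pattern matches inclusions row-wise, bitwise
  expect_true(all((fit$coefficients != 0) == (fit$inclusions == 1L)))
})

test_that("fits are bitwise reproducible under a fixed seed", {
  syn <- generate_panel(synthetic_config(n_areas = 1), seed = 5)
  obs <- syn$panel[!syn$panel$is_projected, ]
  cfg <- fit_config(n_iterations = 300, seed = 42)
  f1 <- fit_model(obs$admissions, panel_X(obs), cfg, years = obs$year)
  f2 <- fit_model(obs$admissions, panel_X(obs), cfg, years = obs$year)
  expect_identical(f1$level_paths, f2$level_paths)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$obs_variances, f2$obs_variances)
  expect_identical(f1$inclusions, f2$inclusions)
})

test_that("fit_model validates its inputs", {
  syn <- generate_panel(synthetic_config(n_areas = 1), seed = 6)
  obs <- syn$panel[!syn$panel$is_projected, ]
  X <- panel_X(obs)
  expect_error(fit_model(obs$admissions[1:5], X[1:5, ]),
               "insufficient data")
  bad <- obs$admissions
  bad[3] <- NA
  expect_error(fit_model(bad, X), "missing")
  expect_error(fit_model(obs$admissions, X, years = obs$year + c(0, 2,
               rep(0, 11))), "contiguity")
  Xz <- X
  Xz[, 2] <- 1
  expect_error(fit_model(obs$admissions, Xz), "pop_0_15")
})

test_that("strong covariate signal is recovered on one synthetic area", {
  cfg <- synthetic_config(n_areas = 1,
                          true_coefficients = c(0, 0, 30, 0, 0, 0, 0,
                                                -30, 0),
                          obs_noise_sd = 30, level_innovation_sd = 10,
                          population_wiggle_sd = 5000,
                          population_trend_range = c(-500, 1000))
  syn <- generate_panel(cfg, seed = 2)
  obs <- syn$panel[!syn$panel$is_projected, ]
  X <- panel_X(obs)
  y <- obs$admissions
  er2 <- min(summary(stats::lm(y ~ X))$r.squared, 0.95)
  fit <- fit_model(y, X, fit_config(n_iterations = 2500, seed = 1,
                                    expected_rsq = er2),
                   years = obs$year)
  ip <- inclusion_probabilities(fit)
  bm <- colMeans(fit$coefficients)
  expect_gt(ip[3], 0.9)
  expect_gt(ip[8], 0.9)
  expect_lt(abs(bm[3] - 30) / 30, 0.2)
  expect_lt(abs(bm[8] + 30) / 30, 0.2)
})

test_that("null (pure random walk) data does not promote covariates", {
  cfg <- synthetic_config(n_areas = 1,
                          true_coefficients = rep(0, 9),
                          obs_noise_sd = 30, level_innovation_sd = 15)
  syn <- generate_panel(cfg, seed = 31)
  obs <- syn$panel[!syn$panel$is_projected, ]
  fit <- fit_model(obs$admissions, panel_X(obs),
                   fit_config(n_iterations = 2000, seed = 2),
                   years = obs$year)
  expect_lt(median(inclusion_probabilities(fit)), 5 / 9)
})

test_that("level-innovation SD respects the 150% truncation", {
  syn <- generate_panel(synthetic_config(n_areas = 1), seed = 8)
  obs <- syn$panel[!syn$panel$is_projected, ]
  fit <- fit_model(obs$admissions, panel_X(obs),
                   fit_config(n_iterations = 500, seed = 3),
                   years = obs$year)
  cap <- 1.5 * sqrt(series_variance(obs$admissions))
  expect_true(all(sqrt(fit$level_variances) <= cap + 1e-9))
})

test_that("posterior variance intervals and loglik traces behave on-model", {
  # prior-consistent world (regression explains ~2/3 of variance, as the
  # production expected-R^2 prior assumes); reduced replicate count and
  # chain length to fit the test budget
  n_rep <- 20L
  cover <- 0L
  gew_pass <- 0L
  for (r in seq_len(n_rep)) {
    cfg <- synthetic_config(n_areas = 1,
                            true_coefficients = c(0, 0, 6, 0, 0, 0, 0,
                                                  -6, 0),
                            obs_noise_sd = 30, level_innovation_sd = 10,
                            population_wiggle_sd = 5000,
                            population_trend_range = c(-500, 1000))
    syn <- generate_panel(cfg, seed = 700 + r)
    obs <- syn$panel[!syn$panel$is_projected, ]
    fit <- fit_model(obs$admissions, panel_X(obs),
                     fit_config(n_iterations = 2500, seed = r),
                     years = obs$year)
    ci <- quantile(fit$obs_variances, c(0.025, 0.975))
    cover <- cover + (30^2 >= ci[1] && 30^2 <= ci[2])
    gew_pass <- gew_pass + (abs(geweke_z(fit$log_likelihoods)) <= 1.96)
  }
  # binomial(20, 0.95) alpha = 0.01 lower bound
  expect_gte(cover, qbinom(0.005, n_rep, 0.95))
  expect_gte(gew_pass, ceiling(0.9 * n_rep))
})
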