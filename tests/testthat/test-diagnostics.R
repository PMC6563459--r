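# MCMC diagnostic gates: null behaviour, gross-failure behaviour, and
# second-implementation oracles.

# Independent spectral-density-at-zero implementation: same Yule-Walker /
# AIC estimator, but solving the normal equations densely via a Toeplitz
# solve instead of the Levinson-Durbin recursion.
oracle_spectrum0 <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  p_max <- min(n - 1L, floor(10 * log10(n)))
  r <- vapply(0:p_max, function(k) {
    sum(xc[1:(n - k)] * xc[(1 + k):n]) / n
  }, numeric(1))
  best_aic <- n * log(r[1])
  best_s0 <- r[1]
  for (p in seq_len(p_max)) {
    phi <- solve(stats::toeplitz(r[1:p]), r[2:(p + 1)])
    v <- r[1] - sum(phi * r[2:(p + 1)])
    if (v <= 0) break
    aic <- n * log(v) + 2 * p
    if (aic < best_aic) {
      best_aic <- aic
      best_s0 <- v / (1 - sum(phi))^2
    }
  }
  best_s0
}

oracle_geweke <- function(chain, f1 = 0.1, f2 = 0.5) {
  n <- length(chain)
  x1 <- chain[seq_len(floor(f1 * n))]
  x2 <- chain[(n - floor(f2 * n) + 1L):n]
  (mean(x1) - mean(x2)) /
    sqrt(oracle_spectrum0(x1) / length(x1) +
           oracle_spectrum0(x2) / length(x2))
}

test_that("geweke_z matches an independent spectral implementation", {
  set.seed(61)
  chain <- as.numeric(stats::filter(rnorm(5000), 0.6, "recursive"))
  expect_equal(geweke_z(chain), oracle_geweke(chain), tolerance = 1e-6)
})

test_that("geweke_z null rate and gross nonstationarity", {
  set.seed(62)
  zs <- replicate(500, geweke_z(rnorm(10000)))
  inside <- sum(abs(zs) <= 1.96)
  # binomial(500, 0.95), alpha = 0.01 band
  expect_true(inside >= 475 - 2.576 * sqrt(500 * 0.05 * 0.95) &&
                inside <= 500)

  split <- c(rep(0, 500), rep(10, 500)) + rnorm(1000, 0, 1e-3)
  expect_gt(abs(geweke_z(split)), 10)
})

test_that("geweke_z is antisymmetric under reversal with swapped windows", {
  set.seed(63)
  chain <- cumsum(rnorm(2000, 0, 0.05)) + rnorm(2000)
  expect_equal(geweke_z(rev(chain), 0.5, 0.1),
               -geweke_z(chain, 0.1, 0.5), tolerance = 1e-10)
})

test_that("geweke_z rejects degenerate input", {
  expect_error(geweke_z(rep(1, 1000)), "degenerate")
  expect_error(geweke_z(rnorm(50)), "length")
})

test_that("raftery_lewis_I is near 1 for iid chains and large for sticky ones", {
  set.seed(64)
  Is <- replicate(10, raftery_lewis_I(rnorm(5000)))
  expect_true(all(Is > 0.8 & Is < 1.3))

  ar <- as.numeric(stats::filter(rnorm(20000), 0.95, "recursive"))
  expect_gt(raftery_lewis_I(ar), 5)

  expect_error(raftery_lewis_I(rnorm(1000)), "insufficient length")
})

test_that("the dependence-factor gate uses a strict threshold at 5", {
  expect_true(diagnostic_gate(4.99, 0, TRUE))
  expect_false(diagnostic_gate(5.0, 0, TRUE))
  expect_false(diagnostic_gate(1, 2.5, TRUE))
  expect_false(diagnostic_gate(1, 0, FALSE))
  expect_false(diagnostic_gate(1, 0, TRUE, durbin_watson = 3.1))
  expect_true(diagnostic_gate(1, 0, TRUE, durbin_watson = 2.0))
})

test_that("heidelberger_welch passes iid chains and fails nonstationary ones", {
  set.seed(65)
  res <- replicate(200, {
    h <- heidelberger_welch(rnorm(1000))
    c(h$pass, h$discarded)
  })
  n_pass_clean <- sum(res[1, ] == 1 & res[2, ] == 0)
  expect_gt(n_pass_clean,
            190 - 2.576 * sqrt(200 * 0.05 * 0.95))

  set.seed(68)
  trend <- seq(0, 10, length.out = 1000) + rnorm(1000, 0, 0.1)
  expect_false(heidelberger_welch(trend)$pass)
  # stationary-but-autocorrelated chains should still pass mostly
  set.seed(69)
  ar_pass <- mean(replicate(30, heidelberger_welch(
    as.numeric(stats::filter(rnorm(2000), 0.9, "recursive")))$pass))
  expect_gt(ar_pass, 0.8)
  expect_error(heidelberger_welch(rep(2, 500)), "degenerate")
})

test_that("heidelberger_welch CvM statistic matches a direct computation", {
  set.seed(60)
  chain <- rnorm(800)
  got <- heidelberger_welch(chain)
  # direct recomputation on the full (0%-discard) chain with an
  # independently coded Bartlett lag-window variance
  n <- length(chain)
  x2 <- chain[(n %/% 2 + 1):n]
  L <- floor(sqrt(length(x2)))
  cv <- as.numeric(acf(x2, lag.max = L, type = "covariance",
                       demean = TRUE, plot = FALSE)$acf)
  s0 <- cv[1] + 2 * sum((1 - (1:L) / L) * cv[-1])
  S <- cumsum(chain)
  B <- (S - seq_len(n) * mean(chain)) / sqrt(n * s0)
  expect_equal(got$cvm, sum(B^2) / n, tolerance = 1e-6)
  expect_equal(got$discarded, 0)
})

test_that("durbin_watson arithmetic and null behaviour", {
  expect_equal(durbin_watson(c(1, -1, 1, -1)), 3.0)
  expect_equal(durbin_watson(c(2, 2, 2, 2)), 0.0)
  expect_error(durbin_watson(c(0, 0, 0)), "degenerate")
  expect_error(durbin_watson(c(1, 2)), "at least 3")
  set.seed(67)
  dw <- durbin_watson(rnorm(10000))
  expect_true(dw > 1.9 && dw < 2.1)
  expect_true(dw >= 0 && dw <= 4)
})

test_that("diagnose_draws gates a well-mixed fit and reports per chain", {
  syn <- generate_panel(synthetic_config(n_areas = 1), seed = 71)
  obs <- syn$panel[!syn$panel$is_projected, ]
  fit <- fit_model(obs$admissions, panel_X(obs),
                   fit_config(n_iterations = 1500, seed = 7),
                   years = obs$year)
  resid <- rnorm(12)  # well-behaved one-step errors
  set.seed(72)
  rep <- diagnose_draws(fit, residuals = resid, rl_precision = 0.02)
  expect_s3_class(rep, "diagnostics_report")
  expect_true(all(c("log_likelihood", "obs_variance", "level_variance")
                  %in% rep$chain))
  expect_true(is.finite(attr(rep, "durbin_watson")))
  expect_type(attr(rep, "passed"), "logical")
})
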