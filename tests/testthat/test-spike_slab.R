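# Spike-and-slab prior construction, collapsed marginals against a
# quadrature oracle, Gibbs sweep against exhaustive enumeration, and
# conditional draws against closed forms.

make_problem <- function(n = 20, K = 3, beta = c(2, 0, 0), sd_eps = 1,
                         seed = 3, ems = 1.5, rsq = 0.5) {
  set.seed(seed)
  X <- scale(matrix(rnorm(n * K), n, K))[, , drop = FALSE]
  attributes(X)[c("scaled:center", "scaled:scale")] <- NULL
  z <- drop(X %*% beta) + rnorm(n, 0, sd_eps)
  prior <- build_prior(X, z, expected_model_size = ems,
                       expected_rsq = rsq, prior_obs_weight = 1,
                       prior_df = 3)
  list(X = X, z = z, prior = prior)
}

test_that("build_prior implements the stated arithmetic", {
  set.seed(1)
  X <- matrix(rnorm(13 * 9), 13, 9)
  y <- rnorm(13, 100, 10)
  pr <- build_prior(X, y, expected_model_size = 5, expected_rsq = 0.70,
                    prior_obs_weight = 13, prior_df = 12)
  expect_equal(pr$inclusion_prob, rep(5 / 9, 9))
  expect_equal(pr$variance_prior_sum_of_squares, 12 * 0.30 * var(y))

  pr1 <- build_prior(X[, 1, drop = FALSE], y, expected_model_size = 1,
                     expected_rsq = 0.5)
  expect_equal(pr1$inclusion_prob, 1.0)

  expect_error(build_prior(X, y, expected_model_size = 10), "model_size")
  Xz <- cbind(X[, 1:2], bad = 0)
  expect_error(build_prior(Xz, y, 1), "bad")
})

test_that("slab information mixes full and diagonal cross-products", {
  set.seed(2)
  X <- scale(matrix(rnorm(30), 10, 3))
  y <- rnorm(10)
  pr <- build_prior(X, y, 2, prior_obs_weight = 5, prior_df = 4,
                    diagonal_shrinkage = 0.25)
  XtX <- crossprod(X)
  expect_equal(pr$slab_information,
               (5 / 10) * (0.25 * XtX + 0.75 * diag(diag(XtX))))
})

test_that("log_marginal matches the quadrature oracle for all patterns", {
  pb <- make_problem()
  pats <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  for (i in seq_len(nrow(pats))) {
    g <- pats[i, ]
    expect_equal(log_marginal(g, pb$z, pb$X, pb$prior),
                 oracle_log_marginal(g, pb$z, pb$X, pb$prior),
                 tolerance = 1e-6)
  }
})

test_that("an uninformative zero covariate leaves the marginal unchanged", {
  pb <- make_problem(K = 2, beta = c(1, 0))
  # extend with an all-zero column whose slab precision is an isolated
  # diagonal entry
  X3 <- cbind(pb$X, 0)
  info3 <- rbind(cbind(pb$prior$slab_information, 0), 0)
  info3[3, 3] <- 2.5
  pr3 <- spike_slab_prior(c(pb$prior$inclusion_prob, 0.5), info3,
                          pb$prior$variance_prior_df,
                          pb$prior$variance_prior_sum_of_squares)
  expect_equal(log_marginal(c(1, 0, 1), pb$z, X3, pr3),
               log_marginal(c(1, 0), pb$z, pb$X, pb$prior))
})

test_that("gibbs sweep recovers enumeration posterior and pins spikes", {
  pb <- make_problem()
  en <- oracle_enumerate_gamma(pb$z, pb$X, pb$prior)

  set.seed(41)
  n_sweep <- 30000L
  g <- c(0L, 0L, 0L)
  freq <- matrix(NA_integer_, n_sweep, 3)
  for (s in seq_len(n_sweep)) {
    g <- gibbs_gamma_sweep(g, pb$z, pb$X, pb$prior)
    freq[s, ] <- g
  }
  for (k in 1:3) {
    se <- mc_se_batch(freq[, k])
    expect_lt(abs(mean(freq[, k]) - en$marginal_inclusion[k]),
              3 * max(se, 1e-3))
  }

  # prior inclusion probability 0 pins the coordinate off
  pr0 <- pb$prior
  pr0$inclusion_prob[2] <- 0
  set.seed(5)
  g <- c(1L, 1L, 0L)
  on2 <- replicate(200, {
    g <<- gibbs_gamma_sweep(g, pb$z, pb$X, pr0)
    g[2]
  })
  expect_true(all(on2 == 0L))
})

test_that("a dominant signal is always selected", {
  # orthogonal design, effect 20x the noise SD
  pb <- make_problem(n = 24, beta = c(20, 0, 0), sd_eps = 1, seed = 9,
                     ems = 1.5, rsq = 0.5)
  set.seed(6)
  g <- c(0L, 0L, 0L)
  on1 <- replicate(2000, {
    g <<- gibbs_gamma_sweep(g, pb$z, pb$X, pb$prior)
    g[1]
  })
  expect_gt(mean(on1), 0.99)
})

test_that("draw_beta_sigma respects the zero pattern bitwise", {
  pb <- make_problem()
  set.seed(8)
  for (rep in 1:25) {
    g <- sample(0:1, 3, replace = TRUE)
    d <- draw_beta_sigma(g, pb$z, pb$X, pb$prior)
    expect_identical(d$inclusion, as.integer(g))
    expect_true(all(d$coefficients[g == 0] == 0))
    expect_gt(d$obs_variance, 0)
  }
})

test_that("empty-model sigma^2 draws follow the closed-form inverse gamma", {
  pb <- make_problem()
  a <- pb$prior$variance_prior_df / 2
  b <- pb$prior$variance_prior_sum_of_squares / 2
  n <- length(pb$z)
  set.seed(10)
  draws <- replicate(1e4, draw_beta_sigma(c(0, 0, 0), pb$z, pb$X,
                                          pb$prior)$obs_variance)
  # 1/sigma^2 ~ Gamma(a + n/2, b + z'z/2)
  u <- pgamma(1 / draws, shape = a + n / 2,
              rate = b + sum(pb$z^2) / 2)
  expect_gt(ks.test(u, "punif")$p.value, 0.01)
})

test_that("posterior coefficient mean approaches truth as the slab vanishes", {
  set.seed(12)
  n <- 30
  X <- scale(matrix(rnorm(n * 3), n, 3))
  z <- 2 * X[, 1]                      # noiseless
  pr <- build_prior(X, z, 1, expected_rsq = 0.99,
                    prior_obs_weight = 1e-8, prior_df = 3)
  set.seed(13)
  b1 <- replicate(2000, draw_beta_sigma(c(1, 0, 0), z, X,
                                        pr)$coefficients[1])
  expect_lt(abs(mean(b1) - 2), 1e-3)
})

test_that("included coefficient matches the conjugate closed form", {
  pb <- make_problem(seed = 15)
  g <- c(1, 0, 1)
  act <- c(1, 3)
  Om <- pb$prior$slab_information[act, act]
  V <- solve(crossprod(pb$X[, act]) + Om)
  bhat <- drop(V %*% crossprod(pb$X[, act], pb$z))
  set.seed(16)
  n_draw <- 4000L
  bd <- replicate(n_draw, draw_beta_sigma(g, pb$z, pb$X,
                                          pb$prior)$coefficients[act])
  se <- apply(bd, 1, sd) / sqrt(n_draw)
  expect_true(all(abs(rowMeans(bd) - bhat) < 3 * se))
})
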