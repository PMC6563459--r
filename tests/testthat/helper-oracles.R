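# Independent oracles used across test files. These deliberately take
# "dense" routes (joint covariance construction, quadrature, normal
# equations) rather than the package's recursive/collapsed computations.

# Joint moments of the local-level model:
#   mu_1 ~ N(m0, P0), mu_{t+1} = mu_t + eta_t, y_t = mu_t + eps_t
oracle_joint <- function(n, obs_var, lev_var, m0, P0) {
  S_mu <- matrix(0, n, n)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      S_mu[s, t] <- P0 + lev_var * (min(s, t) - 1)
    }
  }
  list(mean = rep(m0, n), S_mu = S_mu, S_y = S_mu + diag(obs_var, n))
}

# log N(y; mean, Sigma) via Cholesky
oracle_dmvnorm_log <- function(y, mean, Sigma) {
  R <- chol(Sigma)
  u <- backsolve(R, y - mean, transpose = TRUE)
  -0.5 * length(y) * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(u^2)
}

# Smoothing moments of mu | y by dense Gaussian conditioning
oracle_smooth <- function(y, obs_var, lev_var, m0, P0) {
  J <- oracle_joint(length(y), obs_var, lev_var, m0, P0)
  W <- J$S_mu %*% solve(J$S_y)
  list(mean = drop(J$mean + W %*% (y - J$mean)),
       var = diag(J$S_mu - W %*% t(J$S_mu)))
}

# Collapsed spike-slab marginal by one-dimensional quadrature over
# sigma^2: beta integrated analytically through the dense Gaussian
# y | gamma, sigma^2 ~ N(X_g b0_g, sigma^2 (I + X_g Om_g^{-1} X_g')),
# then sigma^2 integrated numerically against its IG(a, b) prior.
oracle_log_marginal <- function(gamma, z, X, prior) {
  act <- which(gamma == 1)
  n <- length(z)
  a <- prior$variance_prior_df / 2
  b <- prior$variance_prior_sum_of_squares / 2
  if (length(act) == 0L) {
    C <- diag(1, n)
    m <- rep(0, n)
  } else {
    Om <- prior$slab_information[act, act, drop = FALSE]
    Xa <- X[, act, drop = FALSE]
    C <- diag(1, n) + Xa %*% solve(Om, t(Xa))
    m <- drop(Xa %*% prior$slab_mean[act])
  }
  Rc <- chol(C)
  u <- backsolve(Rc, z - m, transpose = TRUE)
  q <- sum(u^2)
  ldC <- 2 * sum(log(diag(Rc)))
  # integrand over s = sigma^2, scaled by exp(shift) for stability
  log_f <- function(s) {
    -0.5 * n * log(2 * pi * s) - 0.5 * ldC - q / (2 * s) +
      a * log(b) - lgamma(a) - (a + 1) * log(s) - b / s
  }
  shift <- log_f((b + q / 2) / (a + n / 2 + 1))  # near the mode
  val <- stats::integrate(function(s) exp(log_f(s) - shift), 0, Inf,
                          rel.tol = 1e-12, abs.tol = 0)$value
  shift + log(val)
}

# Exhaustive-enumeration posterior over all 2^K inclusion patterns
oracle_enumerate_gamma <- function(z, X, prior) {
  K <- ncol(X)
  pats <- as.matrix(expand.grid(rep(list(0:1), K)))
  lp <- apply(pats, 1L, function(g) {
    log_marginal(g, z, X, prior) +
      sum(g * log(prior$inclusion_prob) +
            (1 - g) * log(1 - prior$inclusion_prob))
  })
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  list(patterns = pats, weights = w,
       marginal_inclusion = drop(t(pats) %*% w))
}

# Batch-means Monte-Carlo standard error for a (possibly autocorrelated)
# 0/1 or numeric chain
mc_se_batch <- function(x, n_batch = 50L) {
  n <- length(x)
  bs <- floor(n / n_batch)
  means <- vapply(seq_len(n_batch), function(i) {
    mean(x[((i - 1L) * bs + 1L):(i * bs)])
  }, numeric(1))
  stats::sd(means) / sqrt(n_batch)
}

# Small standardized helper: default-schema covariate matrix of a panel
# subset, in thousands of persons
panel_X <- function(panel_rows) {
  as.matrix(panel_rows[, c("pop_total", "pop_0_15", "pop_16_24",
                           "pop_25_34", "pop_35_44", "pop_45_54",
                           "pop_55_64", "pop_65_74", "pop_75plus")]) / 1000
}
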