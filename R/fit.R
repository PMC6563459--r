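#' Sampler configuration
#'
#' All tunables of the per-area Gibbs sampler. Defaults follow the
#' production settings: 20,000 iterations with a 10% burn-in, 5 expected
#' nonzero coefficients, 70% expected explained variance, a
#' Gamma(0.01, 0.01 * s_y^2) prior on the level-innovation precision, and
#' the level-innovation standard deviation initialized at 5% of — and
#' truncated at 150% of — the series SD.
#'
#' @param n_iterations Total MCMC iterations (default 20000).
#' @param burn_in_fraction Fraction discarded as burn-in, in (0, 1)
#'   (default 0.10; the count is rounded to the nearest integer).
#' @param seed Integer RNG seed, or NULL to leave the RNG state alone.
#' @param expected_model_size Expected number of included covariates
#'   (default 5).
#' @param expected_rsq Expected explained variance (default 0.70).
#' @param prior_obs_weight Slab-information weight in prior observations
#'   (default 0.01, weakly informative; setting it to the training length
#'   makes the slab as informative as the data).
#' @param variance_gamma_shape Shape of the gamma prior on the
#'   level-innovation precision (default 0.01).
#' @param variance_gamma_rate_factor Rate of the same prior as a multiple
#'   of the series sample variance `s_y^2` (default 0.01).
#' @param level_sd_fractions Named numeric vector `c(prior_guess, initial,
#'   upper_limit)` of the series SD: prior guess for the level-innovation
#'   SD (documented, realized through the gamma prior), the sampler's
#'   initial value, and a hard truncation of the level-innovation SD.
#' @param level_init One of "first" (anchor the level prior mean and the
#'   sampler start at the first series value) or "mean" (at the series
#'   mean).
#' @param level_init_diffuse_factor The initial-level prior variance as a
#'   multiple of `s_y^2` (default 1e6, i.e. effectively diffuse).
#' @param diagonal_shrinkage Slab-information averaging weight passed to
#'   [build_prior].
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(n_iterations = 20000L,
                       burn_in_fraction = 0.10,
                       seed = NULL,
                       expected_model_size = 5,
                       expected_rsq = 0.70,
                       prior_obs_weight = 0.01,
                       variance_gamma_shape = 0.01,
                       variance_gamma_rate_factor = 0.01,
                       level_sd_fractions = c(prior_guess = 0.01,
                                              initial = 0.05,
                                              upper_limit = 1.50),
                       level_init = c("first", "mean"),
                       level_init_diffuse_factor = 1e6,
                       diagonal_shrinkage = 0.5) {
  if (n_iterations < 1) stop("argument error: n_iterations must be >= 1")
  if (burn_in_fraction <= 0 || burn_in_fraction >= 1) {
    stop("argument error: burn_in_fraction must be in (0, 1)")
  }
  stopifnot(variance_gamma_shape > 0, variance_gamma_rate_factor > 0,
            all(level_sd_fractions > 0), level_init_diffuse_factor > 0)
  structure(
    list(n_iterations = as.integer(n_iterations),
         burn_in_fraction = burn_in_fraction,
         seed = seed,
         expected_model_size = expected_model_size,
         expected_rsq = expected_rsq,
         prior_obs_weight = prior_obs_weight,
         variance_gamma_shape = variance_gamma_shape,
         variance_gamma_rate_factor = variance_gamma_rate_factor,
         level_sd_fractions = level_sd_fractions,
         level_init = match.arg(level_init),
         level_init_diffuse_factor = level_init_diffuse_factor,
         diagonal_shrinkage = diagonal_shrinkage),
    class = "fit_config"
  )
}

#' Sample variance of an annual series
#'
#' The (n - 1)-denominator sample variance `s_y^2`, the scale anchor of the
#' variance priors.
#'
#' @param values Numeric vector, length >= 2.
#' @return Nonnegative scalar.
#' @export
series_variance <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop("argument error: need at least 2 values for a sample variance")
  }
  if (anyNA(values)) stop("argument error: values contain NA")
  stats::var(values)
}

# Draw the level-innovation variance from its truncated full conditional.
# Precision ~ Gamma(shape, rate) truncated so that sd(eta) <= sd_cap.
.draw_level_variance <- function(mu, shape0, rate0, sd_cap) {
  shape <- shape0 + (length(mu) - 1) / 2
  rate <- rate0 + sum(diff(mu)^2) / 2
  lam_min <- 1 / sd_cap^2
  p_hi <- stats::pgamma(lam_min, shape, rate = rate, lower.tail = FALSE)
  if (p_hi <= 0) {
    return(sd_cap^2)  # all conditional mass beyond the cap: pin at the cap
  }
  u <- stats::runif(1L, 0, p_hi)
  lam <- stats::qgamma(u, shape, rate = rate, lower.tail = FALSE)
  1 / lam
}

#' Fit the local-level + spike-and-slab model to one area
#'
#' Runs the three-block Gibbs cycle: (1) a forward-filtering
#' backward-sampling draw of the level path given the current regression
#' fit and variances, applied to `y - X beta`; (2) the level-innovation
#' variance from its (truncated) inverse-gamma full conditional; (3) a
#' stochastic-search sweep of the inclusion indicators followed by a
#' conditional draw of the coefficients and observation variance, on
#' `y - mu`. The first `burn_in_fraction` of iterations (rounded to the
#' nearest integer) is discarded. Identical inputs and seed give identical
#' draws.
#'
#' Covariates are mean-centered and scaled to unit variance internally;
#' `coefficients` are reported on the original covariate scale while
#' `coefficients_std` (with `scaling`) back the forecast path.
#'
#' @param series Numeric training series (annual counts), contiguous,
#'   length >= 8, no missing values.
#' @param covariates Numeric matrix (length(series) x K) of demographic
#'   covariates on their natural scale (e.g. populations in thousands).
#' @param config A [fit_config].
#' @param years Optional integer fiscal-year keys (start years); checked
#'   for contiguity when supplied.
#' @return An object of class `posterior_draws` with matrices
#'   `level_paths` (draw x year), `coefficients`, `coefficients_std`,
#'   `inclusions`, vectors `obs_variances`, `level_variances`,
#'   `log_likelihoods`, plus `scaling`, `years` and the `config` echo.
#' @export
fit_model <- function(series, covariates, config = fit_config(),
                      years = NULL) {
  y <- as.numeric(series)
  n <- length(y)
  if (n < 8L) {
    stop("insufficient data: training series must have >= 8 points")
  }
  if (anyNA(y) || any(!is.finite(y))) {
    stop("input error: series contains missing or non-finite values")
  }
  X <- as.matrix(covariates)
  if (nrow(X) != n) {
    stop("input error: covariate rows must match series length")
  }
  if (anyNA(X) || any(!is.finite(X))) {
    stop("input error: covariates contain missing or non-finite values")
  }
  if (!is.null(years)) {
    years <- as.integer(years)
    if (length(years) != n || any(diff(years) != 1L)) {
      stop("contiguity error: years must be consecutive integers")
    }
  } else {
    years <- seq_len(n)
  }
  if (!is.null(config$seed)) set.seed(config$seed)

  K <- ncol(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  if (any(scl == 0)) {
    bad <- colnames(X)[scl == 0]
    if (is.null(bad) || any(!nzchar(bad))) bad <- which(scl == 0)
    stop(sprintf("degenerate design: zero-variance covariate(s): %s",
                 paste(bad, collapse = ", ")))
  }
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")

  s2y <- series_variance(y)
  if (s2y == 0) {
    warning("degenerate series: zero sample variance; priors use scale 1")
    s2y <- 1
  }
  sdy <- sqrt(s2y)
  fr <- config$level_sd_fractions
  prior <- build_prior(Xs, y, config$expected_model_size,
                       config$expected_rsq,
                       prior_obs_weight = config$prior_obs_weight,
                       prior_df = n - 1,
                       diagonal_shrinkage = config$diagonal_shrinkage)
  a_sig <- prior$variance_prior_df / 2
  b_sig <- prior$variance_prior_sum_of_squares / 2
  pi_k <- prior$inclusion_prob
  Omega <- prior$slab_information
  b0 <- prior$slab_mean
  XtX <- crossprod(Xs)

  level_anchor <- if (config$level_init == "first") y[1L] else mean(y)
  init_var <- config$level_init_diffuse_factor * s2y
  eta_shape0 <- config$variance_gamma_shape
  eta_rate0 <- config$variance_gamma_rate_factor * s2y
  sd_cap <- fr[["upper_limit"]] * sdy

  # sampler state
  beta <- numeric(K)
  gamma <- integer(K)
  sigma2_eps <- (1 - config$expected_rsq) * s2y
  sigma2_eta <- (fr[["initial"]] * sdy)^2

  n_burn <- round(config$burn_in_fraction * config$n_iterations)
  n_keep <- config$n_iterations - n_burn
  level_paths <- matrix(NA_real_, n_keep, n)
  coefs_std <- matrix(NA_real_, n_keep, K)
  incl <- matrix(NA_integer_, n_keep, K)
  obs_var <- lev_var <- ll <- numeric(n_keep)

  chol_cache <- new.env(parent = emptyenv())
  tXs <- t(Xs)
  for (it in seq_len(config$n_iterations)) {
    z1 <- y - drop(Xs %*% beta)
    kf <- .kf_full(z1, sigma2_eps, sigma2_eta, level_anchor, init_var)
    mu <- .ffbs_core(kf$filtered_mean, kf$filtered_variance, sigma2_eta)

    sigma2_eta <- .draw_level_variance(mu, eta_shape0, eta_rate0, sd_cap)

    z2 <- y - mu
    pc <- list(XtX = XtX, Xtz = drop(tXs %*% z2),
               ztz = sum(z2^2), n = n)
    gamma <- .ss_sweep(gamma, pc, Omega, b0, pi_k, a_sig, b_sig,
                       chol_cache)
    d <- .ss_draw_beta_sigma(which(gamma == 1L), pc, Omega, b0,
                             a_sig, b_sig, chol_cache)
    beta <- d$coefficients
    sigma2_eps <- d$obs_variance

    if (it > n_burn) {
      g <- it - n_burn
      level_paths[g, ] <- mu
      coefs_std[g, ] <- beta
      incl[g, ] <- gamma
      obs_var[g] <- sigma2_eps
      lev_var[g] <- sigma2_eta
      ll[g] <- kf$log_likelihood
    }
  }

  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("x", seq_len(K))
  colnames(coefs_std) <- colnames(incl) <- nm
  coefs_orig <- sweep(coefs_std, 2L, scl, "/")
  structure(
    list(level_paths = level_paths,
         obs_variances = obs_var,
         level_variances = lev_var,
         coefficients = coefs_orig,
         coefficients_std = coefs_std,
         inclusions = incl,
         log_likelihoods = ll,
         scaling = list(center = ctr, scale = scl),
         years = years,
         series = y,
         config = config),
    class = "posterior_draws"
  )
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("posterior_draws: %d retained draws, %d years, %d covariates\n",
              nrow(x$level_paths), ncol(x$level_paths),
              ncol(x$coefficients)))
  cat(sprintf("  years %d-%d; mean obs SD %.2f; mean level-innovation SD %.2f\n",
              min(x$years), max(x$years),
              mean(sqrt(x$obs_variances)), mean(sqrt(x$level_variances))))
  invisible(x)
}
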