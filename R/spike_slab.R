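#' Spike-and-slab prior for static regression
#'
#' Container for the prior of the regression block: independent Bernoulli
#' inclusion probabilities (the "spike"), a conditional Gaussian prior on
#' the included coefficients (the "slab", parameterized by an information
#' matrix so that `beta_g | sigma^2 ~ N(slab_mean_g,
#' sigma^2 * solve(slab_information_g))`), and an inverse-gamma prior on
#' the observation variance expressed as degrees of freedom and a prior
#' sum of squares: `sigma^2 ~ IG(df/2, ss/2)`.
#'
#' @param inclusion_prob Numeric vector of prior inclusion probabilities,
#'   one per covariate, each in \[0, 1\].
#' @param slab_information Symmetric positive-semidefinite prior
#'   information matrix (K x K).
#' @param variance_prior_df Prior degrees of freedom, > 0.
#' @param variance_prior_sum_of_squares Prior sum of squares, > 0.
#' @param slab_mean Prior coefficient means (default all zero).
#' @return An object of class `spike_slab_prior`.
#' @export
spike_slab_prior <- function(inclusion_prob, slab_information,
                             variance_prior_df,
                             variance_prior_sum_of_squares,
                             slab_mean = rep(0, length(inclusion_prob))) {
  K <- length(inclusion_prob)
  if (any(inclusion_prob < 0 | inclusion_prob > 1)) {
    stop("invalid prior: inclusion probabilities must lie in [0, 1]")
  }
  slab_information <- as.matrix(slab_information)
  if (!isTRUE(all.equal(slab_information, t(slab_information),
                        tolerance = 1e-8))) {
    stop("invalid prior: slab_information must be symmetric")
  }
  if (nrow(slab_information) != K || length(slab_mean) != K) {
    stop("invalid prior: dimension mismatch")
  }
  if (variance_prior_df <= 0 || variance_prior_sum_of_squares <= 0) {
    stop("invalid prior: variance prior df and sum of squares must be > 0")
  }
  structure(
    list(inclusion_prob = as.numeric(inclusion_prob),
         slab_mean = as.numeric(slab_mean),
         slab_information = slab_information,
         variance_prior_df = as.numeric(variance_prior_df),
         variance_prior_sum_of_squares =
           as.numeric(variance_prior_sum_of_squares)),
    class = "spike_slab_prior"
  )
}

#' Build the default spike-and-slab prior from expectations
#'
#' Translates the analyst-level settings — the expected number of nonzero
#' coefficients and the expected explained variance — into a
#' [spike_slab_prior]. Each covariate gets prior inclusion probability
#' `expected_model_size / K`; the observation-variance prior sum of
#' squares is `prior_df * (1 - expected_rsq) * var(response)`; and the
#' slab information is `(prior_obs_weight / n) * (w * X'X +
#' (1 - w) * diag(X'X))`, a Zellner-style g-prior averaged with its
#' diagonal to stabilize collinear demographic covariates.
#'
#' @param covariates Numeric design matrix (n x K), columns standardized.
#' @param response Numeric response vector (annual counts), length n.
#' @param expected_model_size Expected number of included covariates,
#'   0 < value <= K.
#' @param expected_rsq Expected proportion of response variance explained,
#'   in (0, 1).
#' @param prior_obs_weight Prior observation weight (prior "sample size");
#'   defaults to n, the length of the training series.
#' @param prior_df Degrees of freedom of the variance prior; defaults to
#'   n - 1.
#' @param diagonal_shrinkage Averaging weight `w` between the full and
#'   diagonalized cross-product, in \[0, 1\]; default 0.5.
#' @return A [spike_slab_prior].
#' @export
build_prior <- function(covariates, response, expected_model_size,
                        expected_rsq = 0.70,
                        prior_obs_weight = nrow(as.matrix(covariates)),
                        prior_df = nrow(as.matrix(covariates)) - 1,
                        diagonal_shrinkage = 0.5) {
  X <- as.matrix(covariates)
  n <- nrow(X)
  K <- ncol(X)
  if (length(response) != n) {
    stop("argument error: response length must match design rows")
  }
  if (expected_model_size <= 0 || expected_model_size > K) {
    stop("argument error: expected_model_size must be in (0, K]")
  }
  if (expected_rsq <= 0 || expected_rsq >= 1) {
    stop("argument error: expected_rsq must be in (0, 1)")
  }
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(X)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop(sprintf("degenerate design: zero-variance covariate(s): %s",
                 paste(bad, collapse = ", ")))
  }
  XtX <- crossprod(X)
  w <- diagonal_shrinkage
  info <- (prior_obs_weight / n) * (w * XtX + (1 - w) * diag(diag(XtX),
                                                             nrow = K))
  ss <- prior_df * (1 - expected_rsq) * stats::var(response)
  spike_slab_prior(
    inclusion_prob = rep(expected_model_size / K, K),
    slab_information = info,
    variance_prior_df = prior_df,
    variance_prior_sum_of_squares = ss
  )
}

# Collapsed log marginal likelihood of the response given an active set,
# with beta and sigma^2 integrated out under the conjugate
# normal--inverse-gamma pair. Internal fast path shared by log_marginal(),
# gibbs_gamma_sweep() and fit_model(); takes precomputed cross-products.
#   active: integer indices of included covariates
#   a, b:   IG(a, b) parameters of sigma^2 (a = df/2, b = ss/2)
.ss_chol <- function(active, XtX, Omega, b0, cache = NULL) {
  key <- if (is.null(cache)) NULL else paste(active, collapse = ",")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  Om <- Omega[active, active, drop = FALSE]
  Vinv <- XtX[active, active, drop = FALSE] + Om
  R <- tryCatch(chol(Vinv), error = function(e) NULL)
  if (is.null(R)) {
    stop("numerical degeneracy: singular conditional information matrix")
  }
  Ro <- tryCatch(chol(Om), error = function(e) NULL)
  if (is.null(Ro)) {
    stop("numerical degeneracy: singular slab information submatrix")
  }
  b0a <- b0[active]
  Omb0 <- drop(Om %*% b0a)
  ent <- list(R = R, Om = Om, Omb0 = Omb0,
              b0_quad = sum(b0a * Omb0),
              logdet_Om = 2 * sum(log(diag(Ro))),
              logdet_Vinv = 2 * sum(log(diag(R))))
  if (!is.null(cache)) cache[[key]] <- ent
  ent
}

.ss_logm <- function(active, XtX, Xtz, ztz, Omega, b0, n, a, b,
                     cache = NULL) {
  const <- -0.5 * n * log(2 * pi) + a * log(b) - lgamma(a) +
    lgamma(a + n / 2)
  if (length(active) == 0L) {
    return(const - (a + n / 2) * log(b + ztz / 2))
  }
  ch <- .ss_chol(active, XtX, Omega, b0, cache)
  rhs <- Xtz[active] + ch$Omb0
  # beta_hat' Vinv beta_hat via the Cholesky factor
  u <- backsolve(ch$R, rhs, transpose = TRUE)
  sse <- ztz + ch$b0_quad - sum(u^2)
  const + 0.5 * ch$logdet_Om - 0.5 * ch$logdet_Vinv -
    (a + n / 2) * log(b + sse / 2)
}

.ss_precompute <- function(response, covariates) {
  X <- as.matrix(covariates)
  z <- as.numeric(response)
  list(XtX = crossprod(X), Xtz = drop(crossprod(X, z)),
       ztz = sum(z^2), n = length(z))
}

#' Collapsed log marginal likelihood of an inclusion pattern
#'
#' Computes `log p(response | gamma)` for the static regression with the
#' coefficients and observation variance integrated out analytically under
#' the conjugate normal--inverse-gamma prior. This is the quantity whose
#' ratios drive stochastic search variable selection.
#'
#' @param gamma Binary (0/1) inclusion vector, length K.
#' @param response Numeric vector: the regression target (typically the
#'   level-adjusted series `y - mu`).
#' @param covariates Numeric design matrix (n x K).
#' @param prior A [spike_slab_prior].
#' @return Scalar log marginal likelihood.
#' @export
log_marginal <- function(gamma, response, covariates, prior) {
  X <- as.matrix(covariates)
  if (length(gamma) != ncol(X)) {
    stop("contract error: gamma length must equal number of covariates")
  }
  pc <- .ss_precompute(response, X)
  a <- prior$variance_prior_df / 2
  b <- prior$variance_prior_sum_of_squares / 2
  .ss_logm(which(gamma == 1), pc$XtX, pc$Xtz, pc$ztz,
           prior$slab_information, prior$slab_mean, pc$n, a, b)
}

# One full-conditional Bernoulli update of every coordinate, fixed column
# order, on precomputed cross-products. Shared by gibbs_gamma_sweep() and
# fit_model().
.ss_sweep <- function(gamma, pc, Omega, b0, pi_k, a, b, cache = NULL) {
  K <- length(gamma)
  logm_cur <- .ss_logm(which(gamma == 1), pc$XtX, pc$Xtz, pc$ztz,
                       Omega, b0, pc$n, a, b, cache)
  for (k in seq_len(K)) {
    if (pi_k[k] <= 0) {
      if (gamma[k] == 1) {
        gamma[k] <- 0
        logm_cur <- .ss_logm(which(gamma == 1), pc$XtX, pc$Xtz, pc$ztz,
                             Omega, b0, pc$n, a, b, cache)
      }
      next
    }
    if (pi_k[k] >= 1) {
      if (gamma[k] == 0) {
        gamma[k] <- 1
        logm_cur <- .ss_logm(which(gamma == 1), pc$XtX, pc$Xtz, pc$ztz,
                             Omega, b0, pc$n, a, b, cache)
      }
      next
    }
    flipped <- gamma
    flipped[k] <- 1 - gamma[k]
    logm_flip <- .ss_logm(which(flipped == 1), pc$XtX, pc$Xtz, pc$ztz,
                          Omega, b0, pc$n, a, b, cache)
    if (gamma[k] == 1) {
      logm1 <- logm_cur; logm0 <- logm_flip
    } else {
      logm1 <- logm_flip; logm0 <- logm_cur
    }
    # P(gamma_k = 1 | rest) on the log-odds scale
    logit <- (logm1 + log(pi_k[k])) - (logm0 + log1p(-pi_k[k]))
    p1 <- 1 / (1 + exp(-logit))
    new_k <- as.integer(stats::runif(1L) < p1)
    if (new_k != gamma[k]) {
      gamma[k] <- new_k
      logm_cur <- logm_flip
    }
  }
  gamma
}

#' One Gibbs sweep over the inclusion indicators
#'
#' Resamples each inclusion indicator in fixed column order from its full
#' conditional Bernoulli distribution, computed from collapsed
#' marginal-likelihood ratios ([log_marginal]). Covariates with prior
#' inclusion probability 0 (or 1) are pinned off (or on).
#'
#' @param gamma Current binary inclusion vector.
#' @param response Regression target vector.
#' @param covariates Numeric design matrix.
#' @param prior A [spike_slab_prior].
#' @return Updated binary inclusion vector.
#' @export
gibbs_gamma_sweep <- function(gamma, response, covariates, prior) {
  X <- as.matrix(covariates)
  if (length(gamma) != ncol(X)) {
    stop("contract error: gamma length must equal number of covariates")
  }
  pc <- .ss_precompute(response, X)
  .ss_sweep(as.integer(gamma), pc, prior$slab_information, prior$slab_mean,
            prior$inclusion_prob,
            prior$variance_prior_df / 2,
            prior$variance_prior_sum_of_squares / 2)
}

# Conditional draw of (sigma^2, beta) given the active set, on precomputed
# cross-products. Shared by draw_beta_sigma() and fit_model().
.ss_draw_beta_sigma <- function(active, pc, Omega, b0, a, b,
                                cache = NULL) {
  K <- nrow(Omega)
  beta <- numeric(K)
  if (length(active) == 0L) {
    sse <- pc$ztz
    sigma2 <- 1 / stats::rgamma(1L, shape = a + pc$n / 2,
                                rate = b + sse / 2)
    return(list(coefficients = beta, obs_variance = sigma2))
  }
  ch <- .ss_chol(active, pc$XtX, Omega, b0, cache)
  rhs <- pc$Xtz[active] + ch$Omb0
  u <- backsolve(ch$R, rhs, transpose = TRUE)
  bhat <- backsolve(ch$R, u)
  sse <- pc$ztz + ch$b0_quad - sum(u^2)
  sigma2 <- 1 / stats::rgamma(1L, shape = a + pc$n / 2,
                              rate = b + max(sse, 0) / 2)
  beta[active] <- bhat +
    sqrt(sigma2) * backsolve(ch$R, stats::rnorm(length(active)))
  list(coefficients = beta, obs_variance = sigma2)
}

#' Draw coefficients and observation variance given the inclusion pattern
#'
#' Samples `sigma^2` from its inverse-gamma full conditional and then the
#' included coefficients from their Gaussian full conditional; excluded
#' coefficients are exactly zero.
#'
#' @inheritParams gibbs_gamma_sweep
#' @return An object of class `regression_draw` with fields `inclusion`,
#'   `coefficients` (zeros off the active set) and `obs_variance`.
#' @export
draw_beta_sigma <- function(gamma, response, covariates, prior) {
  X <- as.matrix(covariates)
  if (length(gamma) != ncol(X)) {
    stop("contract error: gamma length must equal number of covariates")
  }
  pc <- .ss_precompute(response, X)
  d <- .ss_draw_beta_sigma(which(gamma == 1), pc, prior$slab_information,
                           prior$slab_mean,
                           prior$variance_prior_df / 2,
                           prior$variance_prior_sum_of_squares / 2)
  structure(list(inclusion = as.integer(gamma),
                 coefficients = d$coefficients,
                 obs_variance = d$obs_variance),
            class = "regression_draw")
}
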