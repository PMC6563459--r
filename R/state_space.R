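#' Local-level model parameters
#'
#' Bundles the variances and initial-state prior of a Gaussian local-level
#' model: `y_t = mu_t + eps_t`, `mu_{t+1} = mu_t + eta_t`, with
#' `eps_t ~ N(0, obs_variance)` and `eta_t ~ N(0, level_variance)`, all
#' errors independent with mean zero.
#'
#' @param obs_variance Observation-noise variance (count^2 units), > 0.
#' @param level_variance Level-innovation variance (count^2 units), >= 0.
#'   Zero gives a fixed (static) latent level.
#' @param level_init_mean Prior mean of the level at the first time point.
#' @param level_init_variance Prior variance of the initial level, > 0.
#'   Large values give an effectively diffuse initialization.
#' @return An object of class `local_level_params`.
#' @export
local_level_params <- function(obs_variance, level_variance,
                               level_init_mean = 0,
                               level_init_variance = 1e6) {
  if (!is.numeric(obs_variance) || length(obs_variance) != 1L ||
      !is.finite(obs_variance) || obs_variance <= 0) {
    stop("invalid parameter: obs_variance must be a positive finite number")
  }
  if (!is.numeric(level_variance) || length(level_variance) != 1L ||
      !is.finite(level_variance) || level_variance < 0) {
    stop("invalid parameter: level_variance must be finite and >= 0")
  }
  if (!is.finite(level_init_mean)) {
    stop("invalid parameter: level_init_mean must be finite")
  }
  if (!is.finite(level_init_variance) || level_init_variance <= 0) {
    stop("invalid parameter: level_init_variance must be > 0")
  }
  structure(
    list(obs_variance = as.numeric(obs_variance),
         level_variance = as.numeric(level_variance),
         level_init_mean = as.numeric(level_init_mean),
         level_init_variance = as.numeric(level_init_variance)),
    class = "local_level_params"
  )
}

# Variance floor guarding against negative variances from float cancellation.
.VAR_FLOOR <- 1e-12

# Slim filtering recursion shared by kalman_filter() and the fit loop:
# plain list, no validation, log-density inlined.
.kf_full <- function(y, sv, wv, a0, P0) {
  n <- length(y)
  pm <- pv <- fm <- fv <- innov <- innov_var <- numeric(n)
  a <- a0
  P <- P0
  ll <- 0
  log2pi <- 1.8378770664093453
  for (t in seq_len(n)) {
    pm[t] <- a
    pv[t] <- P
    Ft <- P + sv
    v <- y[t] - a
    innov[t] <- v
    innov_var[t] <- Ft
    ll <- ll - 0.5 * (log2pi + log(Ft) + v * v / Ft)
    K <- P / Ft
    a <- a + K * v
    P <- P * (1 - K)
    if (P < .VAR_FLOOR) P <- .VAR_FLOOR
    fm[t] <- a
    fv[t] <- P
    P <- P + wv
  }
  list(filtered_mean = fm, filtered_variance = fv, predicted_mean = pm,
       predicted_variance = pv, innovation = innov,
       innovation_variance = innov_var, log_likelihood = ll)
}

# Backward-sampling pass shared by ffbs_draw() and the fit loop.
.ffbs_core <- function(fm, fv, wv) {
  n <- length(fm)
  z <- stats::rnorm(n)
  mu <- numeric(n)
  mu[n] <- fm[n] + sqrt(fv[n]) * z[n]
  if (n > 1L) {
    for (t in (n - 1L):1L) {
      denom <- fv[t] + wv
      if (denom <= 0) {
        mu[t] <- fm[t]
      } else {
        J <- fv[t] / denom
        m <- fm[t] + J * (mu[t + 1L] - fm[t])
        v <- fv[t] * (1 - J)
        mu[t] <- m + sqrt(if (v > 0) v else 0) * z[t]
      }
    }
  }
  mu
}

#' Kalman filter for the local-level model
#'
#' Runs the exact Gaussian filtering recursion on a (regression-adjusted)
#' annual series and accumulates the log-likelihood as the sum of the
#' one-step innovation log-densities.
#'
#' @param series Numeric vector of length >= 2, no missing values. Usually
#'   the observed counts minus the regression fit, `y - X beta`.
#' @param params A [local_level_params] object.
#' @return An object of class `kalman_filter_state` with per-year vectors
#'   `filtered_mean`, `filtered_variance`, `predicted_mean`,
#'   `predicted_variance`, `innovation`, `innovation_variance`, and scalar
#'   `log_likelihood`.
#' @export
kalman_filter <- function(series, params) {
  if (!inherits(params, "local_level_params")) {
    stop("invalid parameter: params must be a local_level_params object")
  }
  series <- as.numeric(series)
  if (length(series) < 2L) {
    stop("series must have length >= 2")
  }
  if (anyNA(series) || any(!is.finite(series))) {
    stop("contiguity error: series contains missing or non-finite values")
  }
  out <- .kf_full(series, params$obs_variance, params$level_variance,
                  params$level_init_mean, params$level_init_variance)
  out$series <- series
  structure(out, class = "kalman_filter_state")
}

#' Forward-filtering backward-sampling draw of the level path
#'
#' Draws one exact sample from the joint smoothing distribution of the
#' latent level `mu_{1:T}` given the data, conditional on the model
#' parameters used to run the filter. Consumes R's current RNG state; seed
#' upstream for reproducibility.
#'
#' @param filter_state A `kalman_filter_state` produced by [kalman_filter]
#'   with the same `params`.
#' @param params The [local_level_params] used for the filter.
#' @return Numeric vector: one draw of the level path, same length as the
#'   filtered series.
#' @export
ffbs_draw <- function(filter_state, params) {
  if (!inherits(filter_state, "kalman_filter_state")) {
    stop("contract error: filter_state must come from kalman_filter()")
  }
  fm <- filter_state$filtered_mean
  fv <- filter_state$filtered_variance
  if (length(fv) != length(fm)) {
    stop("contract error: mismatched filter state lengths")
  }
  .ffbs_core(fm, fv, params$level_variance)
}

#' Simulate the latent level forward
#'
#' Iterates the random walk `mu_{T+h} = mu_{T+h-1} + eta` for `horizon`
#' steps from a given starting level. With `level_variance = 0` the path is
#' constant at `last_level`.
#'
#' @param last_level Numeric scalar: the level at the forecast origin.
#' @param params A [local_level_params] object (only `level_variance` is
#'   used).
#' @param horizon Positive integer number of steps.
#' @return Numeric vector of length `horizon`.
#' @export
simulate_level_path <- function(last_level, params, horizon) {
  if (length(horizon) != 1L || !is.finite(horizon) || horizon < 1) {
    stop("argument error: horizon must be a positive integer")
  }
  horizon <- as.integer(horizon)
  sd_eta <- sqrt(params$level_variance)
  last_level + cumsum(stats::rnorm(horizon, 0, sd_eta))
}
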