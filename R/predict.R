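# Posterior-predictive now/forecasting. Each retained draw carries its own
# level endpoint, variances and (possibly empty) covariate set; averaging
# the predictive draws across the chain is Bayesian model averaging over
# inclusion patterns.

.summarize_draw_matrix <- function(pred, years) {
  structure(
    list(horizon_years = years,
         predictive_draws = pred,
         point_estimate = apply(pred, 2L, stats::median),
         mean_estimate = colMeans(pred),
         lower_95 = apply(pred, 2L, stats::quantile, probs = 0.025,
                          names = FALSE),
         upper_95 = apply(pred, 2L, stats::quantile, probs = 0.975,
                          names = FALSE)),
    class = "forecast_result"
  )
}

#' Posterior-predictive forecast
#'
#' For each retained posterior draw, simulates the latent level forward
#' from the end of that draw's level path with that draw's
#' level-innovation variance, adds the draw's regression contribution for
#' the projected covariates and Gaussian observation noise. Point estimate
#' is the per-year posterior-predictive median (the mean is also emitted);
#' intervals are equal-tailed 2.5%/97.5% quantiles. Negative draws are
#' retained (not truncated); a warning is issued when more than 1% of
#' draws are negative.
#'
#' @param draws A `posterior_draws` object from [fit_model].
#' @param future_covariates Matrix with exactly `horizon` rows of
#'   projected covariates on the original scale, columns as in training.
#' @param horizon Positive integer number of years ahead.
#' @return An object of class `forecast_result` with fields
#'   `horizon_years`, `predictive_draws` (draw x horizon),
#'   `point_estimate`, `mean_estimate`, `lower_95`, `upper_95`, and
#'   `inclusion_probabilities`.
#' @export
posterior_predictive <- function(draws, future_covariates, horizon) {
  if (!inherits(draws, "posterior_draws")) {
    stop("contract error: draws must be a posterior_draws object")
  }
  if (horizon < 1) stop("argument error: horizon must be >= 1")
  horizon <- as.integer(horizon)
  Xf <- as.matrix(future_covariates)
  if (nrow(Xf) != horizon) {
    stop("alignment error: future_covariates must have exactly horizon rows")
  }
  if (ncol(Xf) != length(draws$scaling$scale)) {
    stop("alignment error: covariate columns differ from training design")
  }
  Xfs <- sweep(sweep(Xf, 2L, draws$scaling$center), 2L,
               draws$scaling$scale, "/")
  G <- nrow(draws$level_paths)
  Tn <- ncol(draws$level_paths)
  last_level <- draws$level_paths[, Tn]
  sd_eta <- sqrt(draws$level_variances)
  sd_eps <- sqrt(draws$obs_variances)

  # level random walk, vectorized across draws: cumulative sums of
  # per-draw-scaled innovations along the horizon
  E <- matrix(stats::rnorm(G * horizon), G, horizon) * sd_eta
  if (horizon > 1L) {
    for (h in 2:horizon) E[, h] <- E[, h] + E[, h - 1L]
  }
  level <- last_level + E
  reg <- draws$coefficients_std %*% t(Xfs)          # G x horizon
  noise <- matrix(stats::rnorm(G * horizon), G, horizon) * sd_eps
  pred <- level + reg + noise

  frac_neg <- mean(pred < 0)
  if (frac_neg > 0.01) {
    warning(sprintf(
      "%.1f%% of posterior-predictive draws are negative (not truncated)",
      100 * frac_neg))
  }
  res <- .summarize_draw_matrix(pred, max(draws$years) + seq_len(horizon))
  res$inclusion_probabilities <- inclusion_probabilities(draws)
  res
}

#' Marginal posterior inclusion probabilities
#'
#' Column means of the retained inclusion-indicator draws: the Bayesian
#' model averaging weight of each covariate.
#'
#' @param draws A `posterior_draws` object.
#' @return Named numeric vector of probabilities in \[0, 1\].
#' @export
inclusion_probabilities <- function(draws) {
  if (!inherits(draws, "posterior_draws")) {
    stop("contract error: draws must be a posterior_draws object")
  }
  if (nrow(draws$inclusions) < 1L) {
    stop("contract error: no retained draws")
  }
  colMeans(draws$inclusions)
}

#' @export
print.forecast_result <- function(x, ...) {
  df <- data.frame(year = x$horizon_years,
                   point = round(x$point_estimate, 1),
                   lower_95 = round(x$lower_95, 1),
                   upper_95 = round(x$upper_95, 1),
                   mean = round(x$mean_estimate, 1))
  cat("forecast_result (posterior-predictive):\n")
  print(df, row.names = FALSE)
  invisible(x)
}
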