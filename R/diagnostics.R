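# Single-chain MCMC diagnostic gates: Raftery-Lewis dependence factor,
# Geweke window comparison, Heidelberger-Welch stationarity, and the
# Durbin-Watson statistic on one-step prediction (nowcasting) errors.

# Spectral density at frequency zero via a Yule-Walker AR fit with AIC
# order selection (Levinson-Durbin recursion). Used by the Geweke and
# Heidelberger-Welch variance estimates.
.spectrum0_ar <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  v0 <- sum(xc^2) / n
  if (v0 == 0) stop("degenerate chain: zero variance")
  p_max <- min(n - 1L, floor(10 * log10(n)))
  # autocovariances with denominator n
  r <- vapply(0:p_max, function(k) {
    sum(xc[1:(n - k)] * xc[(1 + k):n]) / n
  }, numeric(1))
  best_aic <- n * log(v0)          # order 0
  best_s0 <- v0
  phi <- numeric(0)
  v <- v0
  for (p in seq_len(p_max)) {
    if (p == 1L) {
      k_p <- r[2] / r[1]
      phi_new <- k_p
    } else {
      k_p <- (r[p + 1] - sum(phi * r[p:2])) / v
      phi_new <- c(phi - k_p * rev(phi), k_p)
    }
    v <- v * (1 - k_p^2)
    phi <- phi_new
    if (v <= 0) break
    aic <- n * log(v) + 2 * p
    if (aic < best_aic) {
      best_aic <- aic
      best_s0 <- v / (1 - sum(phi))^2
    }
  }
  best_s0
}

#' Geweke convergence z-score
#'
#' Compares the mean of an early window of the chain with the mean of a
#' late window, standardized by spectral-density-at-zero estimates of each
#' window's long-run variance. |z| <= 1.96 is the conventional pass.
#'
#' @param chain Numeric vector of scalar MCMC draws, length >= 100.
#' @param first_fraction Fraction of the chain in the early window
#'   (default 0.1).
#' @param last_fraction Fraction in the late window (default 0.5).
#' @return Scalar z-score.
#' @export
geweke_z <- function(chain, first_fraction = 0.1, last_fraction = 0.5) {
  chain <- as.numeric(chain)
  n <- length(chain)
  if (n < 100L) stop("argument error: chain length must be >= 100")
  if (first_fraction + last_fraction > 1) {
    stop("argument error: window fractions must not overlap")
  }
  if (stats::var(chain) == 0) stop("degenerate chain: zero variance")
  n1 <- floor(first_fraction * n)
  n2 <- floor(last_fraction * n)
  x1 <- chain[seq_len(n1)]
  x2 <- chain[(n - n2 + 1L):n]
  s1 <- .spectrum0_ar(x1)
  s2 <- .spectrum0_ar(x2)
  (mean(x1) - mean(x2)) / sqrt(s1 / n1 + s2 / n2)
}

#' Raftery-Lewis dependence factor
#'
#' Estimates how many MCMC iterations are needed to estimate the
#' `quantile` of the chain to within `precision` with probability
#' `coverage`, via the dichotomized two-state Markov chain construction,
#' and returns the dependence factor `I` = required iterations divided by
#' the minimum for an iid chain. `I < 5` is the conventional gate.
#'
#' @param chain Numeric MCMC draws.
#' @param quantile Tail quantile of interest (default 0.025).
#' @param precision Acceptable error on the quantile's CDF value
#'   (default 0.005).
#' @param coverage Probability with which the precision must be met
#'   (default 0.95).
#' @return Scalar dependence factor `I` (> 0).
#' @export
raftery_lewis_I <- function(chain, quantile = 0.025, precision = 0.005,
                            coverage = 0.95) {
  chain <- as.numeric(chain)
  n <- length(chain)
  phi <- stats::qnorm(0.5 * (1 + coverage))
  n_min <- ceiling(phi^2 * quantile * (1 - quantile) / precision^2)
  if (n < n_min) {
    stop(sprintf(
      "insufficient length: chain has %d draws but the method needs >= %d",
      n, n_min))
  }
  cutoff <- stats::quantile(chain, probs = quantile, names = FALSE)
  z <- as.integer(chain <= cutoff)
  # choose the smallest thinning k at which a first-order Markov chain is
  # preferred to a second-order one by BIC
  k <- 0L
  repeat {
    k <- k + 1L
    zt <- z[seq(1L, n, by = k)]
    nt <- length(zt)
    if (nt < 3L * k || nt < 100L) {
      stop("insufficient length: chain too short for the two-state fit")
    }
    tri <- table(factor(zt[1:(nt - 2)], levels = 0:1),
                 factor(zt[2:(nt - 1)], levels = 0:1),
                 factor(zt[3:nt], levels = 0:1))
    g2 <- 0
    for (i1 in 1:2) for (i2 in 1:2) for (i3 in 1:2) {
      o <- tri[i1, i2, i3]
      if (o > 0) {
        e <- sum(tri[i1, i2, ]) * sum(tri[, i2, i3]) / sum(tri[, i2, ])
        g2 <- g2 + 2 * o * log(o / e)
      }
    }
    bic <- g2 - 2 * log(nt - 2)
    if (bic < 0 || k >= floor(n / 100)) break
  }
  zt <- z[seq(1L, n, by = k)]
  nt <- length(zt)
  from <- zt[1:(nt - 1)]
  to <- zt[2:nt]
  n01 <- sum(from == 0 & to == 1)
  n0 <- sum(from == 0)
  n10 <- sum(from == 1 & to == 0)
  n1 <- sum(from == 1)
  if (n0 == 0 || n1 == 0 || n01 == 0 || n10 == 0) {
    stop("degenerate chain: dichotomized chain never changes state")
  }
  alpha <- n01 / n0
  beta <- n10 / n1
  eps <- 0.001
  m <- ceiling(log(eps * (alpha + beta) / max(alpha, beta)) /
                 log(abs(1 - alpha - beta)))
  n_keep <- ceiling((2 - alpha - beta) * alpha * beta /
                      (alpha + beta)^3 * (phi / precision)^2)
  (m * k + n_keep * k) / n_min
}

# Bartlett-window long-run variance (lag-window estimate of the spectral
# density at zero, truncation sqrt(n)). Used by the stationarity test: a
# lag-window estimate keeps power against trend-like nonstationarity,
# where an AR fit would absorb the trend into a near-unit root.
.s0_bartlett <- function(x) {
  n <- length(x)
  L <- max(2L, floor(sqrt(n)))
  xc <- x - mean(x)
  r <- vapply(0:L, function(k) {
    sum(xc[1:(n - k)] * xc[(1 + k):n]) / n
  }, numeric(1))
  if (r[1] == 0) stop("degenerate chain: zero variance")
  max(r[1] + 2 * sum((1 - (1:L) / L) * r[-1]), 1e-12)
}

# Asymptotic CDF of the Cramer-von Mises statistic (4-term Bessel-K
# series; validated against the published 50/90/95/99% quantiles).
.pcramer <- function(q, eps = 1e-5) {
  if (q <= 0) return(0)
  total <- 0
  for (k in 0:3) {
    u <- (4 * k + 1)^2 / (16 * q)
    if (u > -log(eps)) next
    coef <- exp(lgamma(k + 0.5) - lgamma(0.5) - lfactorial(k)) *
      sqrt(4 * k + 1) / sqrt(q)
    total <- total + coef * exp(-u) * besselK(u, 0.25)
  }
  min(max(total / pi, 0), 1)
}

#' Heidelberger-Welch stationarity test
#'
#' Iteratively applies the Cramer-von Mises test of stationarity to the
#' chain, discarding initial 10% increments (up to 50%) until the test
#' stops rejecting at level `alpha`. The long-run variance is a
#' Bartlett-window (lag sqrt(n)) spectral estimate at frequency zero from
#' the second half of the full chain.
#'
#' @param chain Numeric MCMC draws, length >= 100.
#' @param alpha Significance level of the stationarity test
#'   (default 0.05).
#' @return List with `pass` (logical) and `discarded` (fraction of the
#'   chain discarded before the test first passed; NA when it never did).
#' @export
heidelberger_welch <- function(chain, alpha = 0.05) {
  chain <- as.numeric(chain)
  n_full <- length(chain)
  if (n_full < 100L) stop("argument error: chain length >= 100 required")
  if (stats::var(chain) == 0) stop("degenerate chain: zero variance")
  s0 <- .s0_bartlett(chain[(n_full %/% 2 + 1L):n_full])
  for (frac in seq(0, 0.5, by = 0.1)) {
    start <- floor(frac * n_full) + 1L
    x <- chain[start:n_full]
    n <- length(x)
    S <- cumsum(x)
    k <- seq_len(n)
    B <- (S - k * mean(x)) / sqrt(n * s0)
    cvm <- sum(B^2) / n
    if (.pcramer(cvm) < 1 - alpha) {
      return(list(pass = TRUE, discarded = frac, cvm = cvm))
    }
  }
  list(pass = FALSE, discarded = NA_real_, cvm = cvm)
}

#' Durbin-Watson statistic
#'
#' `DW = sum((e_t - e_{t-1})^2) / sum(e_t^2)`, in \[0, 4\]; values near 2
#' indicate uncorrelated one-step prediction errors.
#'
#' @param residuals Numeric vector of one-step prediction errors,
#'   length >= 3, not all zero.
#' @return Scalar in \[0, 4\].
#' @export
durbin_watson <- function(residuals) {
  e <- as.numeric(residuals)
  if (length(e) < 3L) stop("argument error: need at least 3 residuals")
  if (all(e == 0)) stop("degenerate residuals: all zero")
  sum(diff(e)^2) / sum(e^2)
}

#' Combined diagnostic pass rule
#'
#' The acceptance gate applied to each chain: Raftery-Lewis dependence
#' factor strictly below 5, |Geweke z| within `geweke_bound`, a
#' Heidelberger-Welch pass, and (when supplied) Durbin-Watson inside
#' `dw_band`.
#'
#' @param raftery_lewis_I Dependence factor.
#' @param geweke_z Geweke z-score.
#' @param heidelberger_welch_pass Logical.
#' @param durbin_watson Optional DW statistic (NA skips the DW gate).
#' @param dw_band Acceptance band for DW.
#' @param geweke_bound Two-sided Geweke bound.
#' @return Logical.
#' @export
diagnostic_gate <- function(raftery_lewis_I, geweke_z,
                            heidelberger_welch_pass,
                            durbin_watson = NA_real_,
                            dw_band = c(1.5, 2.5),
                            geweke_bound = 1.96) {
  dw_ok <- is.na(durbin_watson) ||
    (durbin_watson >= dw_band[1] && durbin_watson <= dw_band[2])
  isTRUE(raftery_lewis_I < 5) && isTRUE(abs(geweke_z) <= geweke_bound) &&
    isTRUE(heidelberger_welch_pass) && dw_ok
}

#' Diagnostic gates for one fitted area
#'
#' Applies the four gates to the fitted chains: the log-likelihood trace,
#' both variance chains and each coefficient chain restricted to draws
#' where the covariate is included (chains with fewer than 100 such draws
#' are reported as NA and do not gate). The overall `passed` flag requires
#' Raftery-Lewis `I < 5`, `|Geweke z| <= 1.96`, a Heidelberger-Welch pass,
#' and — when residuals are supplied — a Durbin-Watson statistic inside
#' `dw_band`.
#'
#' @param draws A `posterior_draws` object.
#' @param residuals Optional one-step prediction errors for the
#'   Durbin-Watson gate.
#' @param dw_band Length-2 acceptance band for Durbin-Watson
#'   (default c(1.5, 2.5)).
#' @param geweke_bound Two-sided bound on the Geweke z (default 1.96).
#' @param rl_quantile,rl_precision Passed to [raftery_lewis_I]; relax
#'   `rl_precision` for short test chains.
#' @return An object of class `diagnostics_report`: a data.frame with one
#'   row per chain (`chain`, `raftery_lewis_I`, `geweke_z`,
#'   `heidelberger_welch_pass`, `passed`) plus attributes
#'   `durbin_watson` and `passed` (overall flag).
#' @export
diagnose_draws <- function(draws, residuals = NULL,
                           dw_band = c(1.5, 2.5), geweke_bound = 1.96,
                           rl_quantile = 0.025, rl_precision = 0.005) {
  if (!inherits(draws, "posterior_draws")) {
    stop("contract error: draws must be a posterior_draws object")
  }
  chains <- list(log_likelihood = draws$log_likelihoods,
                 obs_variance = draws$obs_variances,
                 level_variance = draws$level_variances)
  K <- ncol(draws$coefficients)
  for (kk in seq_len(K)) {
    sel <- draws$inclusions[, kk] == 1L
    if (sum(sel) >= 100L) {
      chains[[paste0("coef_", colnames(draws$coefficients)[kk])]] <-
        draws$coefficients[sel, kk]
    }
  }
  rows <- lapply(names(chains), function(nm) {
    ch <- chains[[nm]]
    rl <- tryCatch(raftery_lewis_I(ch, quantile = rl_quantile,
                                   precision = rl_precision),
                   error = function(e) NA_real_)
    gz <- tryCatch(geweke_z(ch), error = function(e) NA_real_)
    hw <- tryCatch(heidelberger_welch(ch)$pass,
                   error = function(e) NA)
    pass <- diagnostic_gate(rl, gz, hw, geweke_bound = geweke_bound)
    data.frame(chain = nm, raftery_lewis_I = rl, geweke_z = gz,
               heidelberger_welch_pass = hw, passed = pass,
               stringsAsFactors = FALSE)
  })
  rep_df <- do.call(rbind, rows)
  dw <- if (is.null(residuals)) NA_real_ else durbin_watson(residuals)
  dw_ok <- if (is.na(dw)) TRUE else (dw >= dw_band[1] && dw <= dw_band[2])
  overall <- all(rep_df$passed) && dw_ok
  structure(rep_df, class = c("diagnostics_report", "data.frame"),
            durbin_watson = dw, dw_band = dw_band, passed = overall)
}
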