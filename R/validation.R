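# Rolling nowcast-validation protocol: hold out the last 1-5 observed
# years, refit on the truncated series, and score the point nowcasts
# against the measured values, area by area and aggregated nationally.

#' Nowcast validation windows
#'
#' Builds the four training/target windows of the validation protocol
#' from a panel's observed fiscal-year keys: the first 10 years predict
#' years 11, 12 and 13 (horizons 1-3), and the first 8 years predict year
#' 13 (horizon 5). With keys 2003..2015 this gives (2003-2012 -> 2013,
#' h=1), (-> 2014, h=2), (-> 2015, h=3) and (2003-2010 -> 2015, h=5).
#'
#' @param panel_years Integer fiscal-year keys of the observed panel
#'   (>= 13 consecutive years; only the first 13 are used).
#' @return List of four windows, each a list with `train_years`,
#'   `target_year`, `horizon`.
#' @export
make_windows <- function(panel_years) {
  yrs <- sort(unique(as.integer(panel_years)))
  if (length(yrs) < 13L) {
    stop("insufficient span: need at least 13 observed years")
  }
  if (any(diff(yrs) != 1L)) {
    stop("contiguity error: observed years must be consecutive")
  }
  yrs <- yrs[1:13]
  train10 <- yrs[1:10]
  train8 <- yrs[1:8]
  list(
    list(train_years = train10, target_year = yrs[11], horizon = 1L),
    list(train_years = train10, target_year = yrs[12], horizon = 2L),
    list(train_years = train10, target_year = yrs[13], horizon = 3L),
    list(train_years = train8, target_year = yrs[13], horizon = 5L)
  )
}

#' Signed percent nowcast error
#'
#' `100 * (predicted - measured) / measured`; negative values are
#' underestimates.
#'
#' @param predicted Predicted count(s).
#' @param measured Measured count(s), > 0.
#' @return Percent error(s).
#' @export
percent_error <- function(predicted, measured) {
  if (any(measured <= 0)) {
    stop("division-domain error: measured counts must be > 0")
  }
  100 * (predicted - measured) / measured
}

#' Summarize per-area nowcast errors
#'
#' Median, interquartile range (linear-interpolation / type-7 quantiles),
#' range, and the count of areas within +/-10% (boundary inclusive).
#'
#' @param per_area_errors Numeric vector of percent errors, one per area.
#' @return List with `median`, `iqr_lo`, `iqr_hi`, `min`, `max`,
#'   `within_10pct_count`, `n`.
#' @export
summarize_errors <- function(per_area_errors) {
  e <- as.numeric(per_area_errors)
  if (length(e) < 1L) stop("contract error: no errors supplied")
  q <- stats::quantile(e, probs = c(0.25, 0.75), type = 7, names = FALSE)
  list(median = stats::median(e), iqr_lo = q[1], iqr_hi = q[2],
       min = min(e), max = max(e),
       within_10pct_count = sum(abs(e) <= 10), n = length(e))
}

#' Calibration regression of nowcasts on measured values
#'
#' Ordinary least squares of the nowcasted counts (response) on the
#' measured counts (predictor), with intercept. A slope near 1 and r^2
#' near 1 indicate well-calibrated nowcasts across areas.
#'
#' @param nowcasted Numeric vector of nowcasted counts per area.
#' @param measured Numeric vector of measured counts per area (same
#'   length, >= 3).
#' @return List with `slope`, `intercept`, `r2`.
#' @export
calibration_regression <- function(nowcasted, measured) {
  if (length(nowcasted) != length(measured) || length(measured) < 3L) {
    stop("argument error: need >= 3 paired areas")
  }
  if (stats::var(measured) == 0) {
    stop("degenerate regression: zero variance in measured values")
  }
  x <- as.numeric(measured)
  y <- as.numeric(nowcasted)
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  sse <- sum((y - intercept - slope * x)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) as.numeric(sse == 0) else 1 - sse / sst
  list(slope = slope, intercept = intercept, r2 = r2)
}

#' Random-walk baseline forecast
#'
#' The no-drift random-walk (ARIMA(0,1,0)) point forecast: the last
#' observed value, at every horizon.
#'
#' @param training_series Numeric series, length >= 2.
#' @param horizon Positive integer.
#' @return Numeric vector of length `horizon`.
#' @export
random_walk_baseline <- function(training_series, horizon) {
  y <- as.numeric(training_series)
  if (length(y) < 2L) stop("contract error: training series too short")
  if (horizon < 1) stop("argument error: horizon must be >= 1")
  rep(y[length(y)], horizon)
}

#' Run the full nowcast-validation protocol on a panel
#'
#' For every area, fits the model on the two training spans of
#' [make_windows] (the horizon-1/2/3 windows share one fit), nowcasts the
#' held-out years, and scores point nowcasts (posterior-predictive
#' medians) against the measured counts. The random-walk baseline is
#' scored on the same windows; RMSE/MAE are pooled across all windows and
#' areas.
#'
#' @param panel An area panel data.frame (see [read_panel]) with observed
#'   rows for >= 13 consecutive years.
#' @param config A [fit_config]; its `seed` is used as the base seed, one
#'   deterministic offset per area.
#' @return An object of class `validation_report`: list with `per_area`
#'   (data.frame: area_id, window, horizon, target_year, predicted,
#'   measured, error_pct, baseline), `national` (per-window totals and
#'   errors), `summaries` (per-window error summaries), `calibration`
#'   (5-year window), and pooled `model_rmse`, `model_mae`,
#'   `baseline_rmse`, `baseline_mae`.
#' @export
validate_nowcasts <- function(panel, config = fit_config()) {
  obs <- panel[!panel$is_projected, , drop = FALSE]
  windows <- make_windows(obs$year)
  areas <- unique(obs$area_id)
  cov_cols <- .panel_covariate_columns(panel)
  base_seed <- if (is.null(config$seed)) 1L else config$seed

  rows <- list()
  for (ai in seq_along(areas)) {
    ar <- areas[ai]
    sub <- obs[obs$area_id == ar, , drop = FALSE]
    sub <- sub[order(sub$year), , drop = FALSE]
    for (tr in list(windows[[1]]$train_years, windows[[4]]$train_years)) {
      h_max <- max(vapply(windows, function(w) {
        if (identical(w$train_years, tr)) w$horizon else 0L
      }, integer(1)))
      wset <- Filter(function(w) identical(w$train_years, tr), windows)
      tr_idx <- sub$year %in% tr
      cfg <- config
      cfg$seed <- (base_seed + 7919L * ai + length(tr)) %% 2147483647L
      fit <- fit_model(sub$admissions[tr_idx],
                       as.matrix(sub[tr_idx, cov_cols]) / 1000,
                       cfg, years = sub$year[tr_idx])
      fut_years <- max(tr) + seq_len(h_max)
      fut_idx <- match(fut_years, sub$year)
      fc <- posterior_predictive(
        fit, as.matrix(sub[fut_idx, cov_cols]) / 1000, h_max)
      bl <- random_walk_baseline(sub$admissions[tr_idx], h_max)
      for (w in wset) {
        hi <- w$target_year - max(tr)
        rows[[length(rows) + 1L]] <- data.frame(
          area_id = ar,
          window = sprintf("h%d_%d", w$horizon, w$target_year),
          horizon = w$horizon,
          target_year = w$target_year,
          predicted = fc$point_estimate[hi],
          measured = sub$admissions[sub$year == w$target_year],
          baseline = bl[hi],
          stringsAsFactors = FALSE)
      }
    }
  }
  per_area <- do.call(rbind, rows)
  per_area$error_pct <- percent_error(per_area$predicted,
                                      per_area$measured)

  win_labels <- vapply(windows, function(w) {
    sprintf("h%d_%d", w$horizon, w$target_year)
  }, character(1))
  national <- do.call(rbind, lapply(win_labels, function(wl) {
    s <- per_area[per_area$window == wl, , drop = FALSE]
    data.frame(window = wl,
               predicted = sum(s$predicted),
               measured = sum(s$measured),
               error_pct = percent_error(sum(s$predicted),
                                         sum(s$measured)),
               stringsAsFactors = FALSE)
  }))
  summaries <- lapply(stats::setNames(win_labels, win_labels),
                      function(wl) {
    summarize_errors(per_area$error_pct[per_area$window == wl])
  })
  w5 <- win_labels[4]
  s5 <- per_area[per_area$window == w5, , drop = FALSE]
  calibration <- if (nrow(s5) >= 3L) {
    calibration_regression(s5$predicted, s5$measured)
  } else {
    list(slope = NA_real_, intercept = NA_real_, r2 = NA_real_)
  }
  dev_m <- per_area$predicted - per_area$measured
  dev_b <- per_area$baseline - per_area$measured
  structure(
    list(per_area = per_area, national = national,
         summaries = summaries, calibration = calibration,
         model_rmse = sqrt(mean(dev_m^2)), model_mae = mean(abs(dev_m)),
         baseline_rmse = sqrt(mean(dev_b^2)),
         baseline_mae = mean(abs(dev_b))),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation_report: nowcast errors by window\n")
  print(x$national, row.names = FALSE)
  cat(sprintf("calibration (5y): slope %.3f, r2 %.3f\n",
              x$calibration$slope, x$calibration$r2))
  cat(sprintf("pooled RMSE %.1f (baseline %.1f), MAE %.1f (baseline %.1f)\n",
              x$model_rmse, x$baseline_rmse, x$model_mae, x$baseline_mae))
  invisible(x)
}
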