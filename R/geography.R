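# Area metadata, aggregation of predictive draws across geography tiers,
# and crude-rate arithmetic (events per 1,000 population).

#' Read an area-to-geography lookup table
#'
#' @param path CSV with header
#'   `area_id,region,supergroup,group,subgroup`.
#' @return Validated data.frame.
#' @export
read_geography <- function(path) {
  g <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  need <- c("area_id", "region", "supergroup", "group", "subgroup")
  if (!identical(names(g), need)) {
    stop(sprintf("named-column error: geography header must be %s",
                 paste(need, collapse = ",")))
  }
  if (anyDuplicated(g$area_id)) {
    stop("validation error: duplicate area_id in geography lookup")
  }
  if (any(!nzchar(as.matrix(g)))) {
    stop("validation error: empty geography fields")
  }
  g
}

#' Crude rate per 1,000 population
#'
#' @param count Event count(s).
#' @param population Population(s), > 0.
#' @return `1000 * count / population`.
#' @export
crude_rate <- function(count, population) {
  if (any(population <= 0)) {
    stop("domain error: population must be > 0")
  }
  1000 * count / population
}

#' Crude-rate change versus a baseline year
#'
#' @param count_now,pop_now Count and population in the comparison year.
#' @param count_base,pop_base Count and population in the baseline year.
#' @return List with `change_per_1000` (difference of crude rates) and
#'   `percent_change` (`100 * (rate_now / rate_base - 1)`).
#' @export
rate_change <- function(count_now, pop_now, count_base, pop_base) {
  r_now <- crude_rate(count_now, pop_now)
  r_base <- crude_rate(count_base, pop_base)
  list(change_per_1000 = r_now - r_base,
       percent_change = 100 * (r_now / r_base - 1))
}

#' Aggregate per-area predictive draws to a geography tier
#'
#' Element-wise sums of member-area predictive draws (areas treated as
#' independent; draw g of the aggregate is the sum of each member's draw
#' g), with point estimates and 95% intervals recomputed on the summed
#' draws. This is narrower — and correct under independence — compared to
#' summing per-area interval endpoints.
#'
#' @param forecasts Named list of `forecast_result` objects, names =
#'   area ids; all must share draw counts and horizon years.
#' @param geography Data.frame from [read_geography] (not needed for
#'   `level = "national"`).
#' @param level One of "national", "region", "supergroup", "group",
#'   "subgroup".
#' @return Named list of `forecast_result` objects, one per geography
#'   unit.
#' @export
aggregate_draws <- function(forecasts, geography = NULL,
                            level = c("national", "region", "supergroup",
                                      "group", "subgroup")) {
  level <- match.arg(level)
  ids <- names(forecasts)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("contract error: forecasts must be a named list keyed by area_id")
  }
  yrs <- forecasts[[1]]$horizon_years
  G <- nrow(forecasts[[1]]$predictive_draws)
  for (f in forecasts) {
    if (!identical(f$horizon_years, yrs) ||
        nrow(f$predictive_draws) != G) {
      stop("contract error: forecasts differ in draws or horizon years")
    }
  }
  if (level == "national") {
    groups <- list(national = ids)
  } else {
    if (is.null(geography)) {
      stop("argument error: geography lookup required for sub-national tiers")
    }
    missing_ids <- setdiff(ids, geography$area_id)
    if (length(missing_ids) > 0) {
      stop(sprintf("unmapped-area error: %s",
                   paste(missing_ids, collapse = ", ")))
    }
    key <- geography[[level]][match(ids, geography$area_id)]
    groups <- split(ids, key)
  }
  out <- lapply(groups, function(members) {
    total <- Reduce(`+`, lapply(forecasts[members],
                                function(f) f$predictive_draws))
    .summarize_draw_matrix(total, yrs)
  })
  out
}

#' Regional rate table for a forecast year
#'
#' Per geography unit: median (range) across member areas of the
#' forecasted counts, crude rates per 1,000, and rate change versus a
#' baseline year — unweighted across areas.
#'
#' @param forecasts Named list of per-area `forecast_result`s.
#' @param panel Area panel providing populations (and baseline counts).
#' @param geography Geography lookup.
#' @param level Geography tier (as in [aggregate_draws], sub-national).
#' @param forecast_year Fiscal-year key to tabulate.
#' @param baseline_year Fiscal-year key of the measured baseline.
#' @return Data.frame with one row per unit: medians and ranges of count,
#'   rate per 1,000 and rate change per 1,000.
#' @export
rate_table <- function(forecasts, panel, geography,
                       level = "region", forecast_year, baseline_year) {
  ids <- names(forecasts)
  key <- geography[[level]][match(ids, geography$area_id)]
  if (anyNA(key)) {
    stop(sprintf("unmapped-area error: %s",
                 paste(ids[is.na(key)], collapse = ", ")))
  }
  per_area <- do.call(rbind, lapply(seq_along(ids), function(i) {
    ar <- ids[i]
    fc <- forecasts[[ar]]
    j <- match(forecast_year, fc$horizon_years)
    if (is.na(j)) stop("alignment error: forecast_year not in horizon")
    cnt <- fc$point_estimate[j]
    pop_f <- panel$pop_total[panel$area_id == ar &
                               panel$year == forecast_year]
    pop_b <- panel$pop_total[panel$area_id == ar &
                               panel$year == baseline_year]
    cnt_b <- panel$admissions[panel$area_id == ar &
                                panel$year == baseline_year]
    rc <- rate_change(cnt, pop_f, cnt_b, pop_b)
    data.frame(unit = key[i], area_id = ar, count = cnt,
               rate_per_1000 = crude_rate(cnt, pop_f),
               rate_change_per_1000 = rc$change_per_1000,
               percent_change = rc$percent_change,
               stringsAsFactors = FALSE)
  }))
  agg <- function(v) c(median = stats::median(v), min = min(v),
                       max = max(v))
  out <- do.call(rbind, lapply(split(per_area, per_area$unit),
                               function(s) {
    data.frame(unit = s$unit[1],
               n_areas = nrow(s),
               count_median = stats::median(s$count),
               count_min = min(s$count), count_max = max(s$count),
               rate_median = stats::median(s$rate_per_1000),
               rate_min = min(s$rate_per_1000),
               rate_max = max(s$rate_per_1000),
               rate_change_median = stats::median(s$rate_change_per_1000),
               rate_change_min = min(s$rate_change_per_1000),
               rate_change_max = max(s$rate_change_per_1000),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
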