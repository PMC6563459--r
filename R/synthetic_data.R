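# Synthetic-panel generator with known ground truth, emulating small-area
# annual admission counts driven by a random-walk level plus a sparse
# linear signal from 8 age-stratum populations (and the total).

.AGE_STRATA <- c("pop_0_15", "pop_16_24", "pop_25_34", "pop_35_44",
                 "pop_45_54", "pop_55_64", "pop_65_74", "pop_75plus")

#' Synthetic-panel configuration
#'
#' The stated world of the generator: by default 20 areas with 13 observed
#' annual points and 5 projected years; smooth (linear trend + small
#' wiggle) population trajectories in 8 age strata; admissions equal to a
#' random-walk level anchored at a realistic base rate (~5.8 events per
#' 1,000 total population) plus a sparse linear signal in per-thousand
#' populations plus Gaussian noise.
#'
#' @param n_areas Number of areas (default 20; the full study-scale
#'   preset is 324).
#' @param n_years_observed Observed annual points per area (default 13).
#' @param n_years_projected Projected years beyond the observed window
#'   (default 5).
#' @param first_year First fiscal-year key (default 2003).
#' @param true_coefficients Numeric length-9 vector of true coefficients
#'   (counts per thousand persons) on (pop_total, 8 strata); default
#'   sparse with 2 nonzero entries.
#' @param level_innovation_sd SD of the level random-walk innovations, in
#'   counts (default 10).
#' @param obs_noise_sd SD of the observation noise, in counts
#'   (default 30).
#' @param base_rate Baseline admissions per 1,000 total population
#'   anchoring the initial level (default 5.8).
#' @param population_base_range Per-stratum base population range,
#'   persons (default 8,000-40,000, i.e. LTLA-scale totals of
#'   ~60k-320k).
#' @param population_trend_range Per-stratum linear trend range,
#'   persons/year (default -200..400).
#' @param population_wiggle_sd SD of the year-on-year population wiggle,
#'   persons (default 50; projections extrapolate the trend with no
#'   wiggle).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_areas = 20L,
                             n_years_observed = 13L,
                             n_years_projected = 5L,
                             first_year = 2003L,
                             true_coefficients = c(0, 0, 3, 0, 0, 0, 0,
                                                   2, 0),
                             level_innovation_sd = 10,
                             obs_noise_sd = 30,
                             base_rate = 5.8,
                             population_base_range = c(8000, 40000),
                             population_trend_range = c(-200, 400),
                             population_wiggle_sd = 50) {
  stopifnot(n_areas >= 1, n_years_observed >= 2, n_years_projected >= 0,
            length(true_coefficients) == 9L,
            level_innovation_sd >= 0, obs_noise_sd > 0, base_rate > 0)
  structure(
    list(n_areas = as.integer(n_areas),
         n_years_observed = as.integer(n_years_observed),
         n_years_projected = as.integer(n_years_projected),
         first_year = as.integer(first_year),
         true_coefficients = as.numeric(true_coefficients),
         level_innovation_sd = level_innovation_sd,
         obs_noise_sd = obs_noise_sd,
         base_rate = base_rate,
         population_base_range = population_base_range,
         population_trend_range = population_trend_range,
         population_wiggle_sd = population_wiggle_sd),
    class = "synthetic_config"
  )
}

#' Generate stratified population trajectories
#'
#' Each of the 8 age strata follows an area-specific linear trend plus
#' small Gaussian wiggle over the observed years; projected years
#' extrapolate the trend deterministically. Totals are exact stratum
#' sums. Consumes the current RNG state.
#'
#' @param config A [synthetic_config].
#' @return List of per-area data.frames with columns `year`,
#'   `is_projected`, `pop_total`, and the 8 stratum columns.
#' @export
generate_populations <- function(config) {
  n_y <- config$n_years_observed + config$n_years_projected
  years <- config$first_year + seq_len(n_y) - 1L
  is_proj <- c(rep(FALSE, config$n_years_observed),
               rep(TRUE, config$n_years_projected))
  lapply(seq_len(config$n_areas), function(a) {
    base <- stats::runif(8L, config$population_base_range[1],
                         config$population_base_range[2])
    trend <- stats::runif(8L, config$population_trend_range[1],
                          config$population_trend_range[2])
    strata <- sapply(1:8, function(s) {
      obs_t <- seq_len(config$n_years_observed) - 1L
      wig <- stats::rnorm(config$n_years_observed, 0,
                          config$population_wiggle_sd)
      obs <- base[s] + trend[s] * obs_t + wig
      proj <- if (config$n_years_projected > 0) {
        base[s] + trend[s] *
          (config$n_years_observed - 1L +
             seq_len(config$n_years_projected))
      } else numeric(0)
      pmax(c(obs, proj), 100)
    })
    colnames(strata) <- .AGE_STRATA
    df <- data.frame(year = years, is_projected = is_proj,
                     pop_total = rowSums(strata))
    cbind(df, as.data.frame(strata))
  })
}

#' Generate admission counts with known truth
#'
#' For each area: `y_t = mu_t + sum_k beta_k * pop_{k,t}/1000 + eps_t`
#' with `mu` a random walk started at `base_rate * pop_total_1 / 1000`
#' minus the initial regression signal (so counts start near the base
#' rate). Negative counts are floored at 0 with a message. Consumes the
#' current RNG state.
#'
#' @param populations Output of [generate_populations].
#' @param config The same [synthetic_config].
#' @return List with `panel` (stacked area-panel data.frame in the
#'   flat-file schema) and `truth` (per-area level paths, coefficients
#'   and variances).
#' @export
generate_admissions <- function(populations, config) {
  beta <- config$true_coefficients
  truth <- list()
  floored <- 0L
  rows <- lapply(seq_along(populations), function(a) {
    pops <- populations[[a]]
    n_obs <- sum(!pops$is_projected)
    X <- as.matrix(pops[, c("pop_total", .AGE_STRATA)]) / 1000
    signal <- drop(X %*% beta)
    mu0 <- config$base_rate * pops$pop_total[1] / 1000 - signal[1]
    mu <- mu0 + c(0, cumsum(stats::rnorm(n_obs - 1L, 0,
                                         config$level_innovation_sd)))
    y <- mu + signal[seq_len(n_obs)] +
      stats::rnorm(n_obs, 0, config$obs_noise_sd)
    neg <- y < 0
    floored <<- floored + sum(neg)
    y[neg] <- 0
    truth[[a]] <<- list(level = mu, coefficients = beta,
                        level_innovation_sd = config$level_innovation_sd,
                        obs_noise_sd = config$obs_noise_sd)
    data.frame(area_id = sprintf("A%03d", a),
               year = pops$year,
               admissions = c(y, rep(NA_real_,
                                     config$n_years_projected)),
               pops[, c("pop_total", .AGE_STRATA)],
               is_projected = pops$is_projected,
               stringsAsFactors = FALSE)
  })
  if (floored > 0L) {
    message(sprintf("floored %d negative synthetic counts at 0", floored))
  }
  panel <- do.call(rbind, rows)
  rownames(panel) <- NULL
  names(truth) <- sprintf("A%03d", seq_along(populations))
  list(panel = panel, truth = truth)
}

#' Generate a complete synthetic panel
#'
#' Seeds the RNG, generates populations and admissions, and returns a
#' panel in the flat-file schema together with the ground truth and a
#' randomly assigned geography lookup (9 regions, 3/6/12 ONS-style
#' supergroups/groups/subgroups).
#'
#' @param config A [synthetic_config].
#' @param seed Integer seed (same config + seed gives an identical
#'   panel).
#' @return List with `panel`, `truth`, `geography`, `config`, `seed`;
#'   class `synthetic_panel`.
#' @export
generate_panel <- function(config = synthetic_config(), seed = 1L) {
  set.seed(seed)
  pops <- generate_populations(config)
  ga <- generate_admissions(pops, config)
  ids <- unique(ga$panel$area_id)
  regions <- paste0("Region", 1:9)
  sg <- paste0("Supergroup", 1:3)
  gr <- paste0("Group", 1:6)
  sub <- paste0("Subgroup", 1:12)
  geography <- data.frame(
    area_id = ids,
    region = sample(regions, length(ids), replace = TRUE),
    supergroup = sg[((seq_along(ids) - 1L) %% 3L) + 1L],
    group = gr[((seq_along(ids) - 1L) %% 6L) + 1L],
    subgroup = sub[((seq_along(ids) - 1L) %% 12L) + 1L],
    stringsAsFactors = FALSE)
  structure(list(panel = ga$panel, truth = ga$truth,
                 geography = geography, config = config, seed = seed),
            class = "synthetic_panel")
}
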