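#' Default raw bout-length distribution (epochs)
#'
#' Probability mass over planted vigorous run lengths in 10-s epochs,
#' chosen so that about 92% of runs last up to 1 min (6 epochs), about 98%
#' up to 2 min (12 epochs), and a small tail beyond 12 epochs becomes long
#' VPA sessions — the mix observed in free-living wrist-accelerometer
#' cohorts of nonexercisers.
#'
#' @return named numeric vector over run lengths `1..15` summing to 1.
#' @export
default_bout_length_dist <- function() {
  p <- c(0.30, 0.25, 0.15, 0.12, 0.06, 0.043,        # 1..6 epochs: 0.923
         0.016, 0.012, 0.009, 0.007, 0.006, 0.004,   # 7..12: cumulative 0.977
         0.010, 0.008, 0.005)                        # >12: long VPA tail
  names(p) <- as.character(seq_along(p))
  p / sum(p)
}

#' Simulation configuration for synthetic accelerometer cohorts
#'
#' Bundles and validates every parameter of the synthetic cohort generator:
#' the epoch-series generator (wear, sleep, activity-state dwell times,
#' vigorous-run planting) and the competing-risks survival generator.
#'
#' Defaults emulate a 7-day wrist-worn accelerometer protocol in older
#' nonexercising adults: 10-s epochs, about 3 vigorous runs per day, 7.4 h
#' sleep, near-complete wear, and cause-specific mortality rates on the
#' order of 1.5 (CVD), 3.2 (cancer) and 0.5 (other) per 1,000 person-years
#' with administrative censoring at 6.9 years.
#'
#' @param n_participants positive integer, cohort size.
#' @param days_per_participant monitoring days per participant (default 7).
#' @param bout_rate_per_day Poisson mean of planted vigorous runs per day
#'   (population mean; see `p_zero_vilpa` and `rate_shape`).
#' @param p_zero_vilpa probability that a participant does no VILPA at all
#'   (their run rate is 0); set to 0 for a homogeneous-rate cohort.
#' @param rate_shape gamma shape of participant-level rate heterogeneity
#'   (participant rate ~ Gamma(shape, shape/bout_rate_per_day), mean
#'   `bout_rate_per_day`); `Inf` gives every participant the same rate.
#' @param bout_length_dist probability vector over run lengths in epochs
#'   (support `1..K`); must sum to 1.
#' @param wear_hours_dist function `(n, rng-free)` returning `n` daily wear
#'   hours in `[0, 24]`; the default draws 23.5-24 h with a small chance of
#'   a low-wear (<16 h) day.
#' @param state_dwell_params named list of mean dwell times in minutes for
#'   the awake states `sedentary`, `standing`, `walking`.
#' @param sleep_hours mean nightly sleep duration in hours.
#' @param p_walk_moderate probability that a (non-planted) walking dwell is
#'   moderate intensity (100-400 mg) rather than light (<100 mg).
#' @param beta_exposure named numeric, log hazard ratio per min/day of true
#'   VILPA duration for causes `cvd`, `cancer`, `other`.
#' @param baseline_hazards named numeric, constant baseline hazards per year
#'   for the same causes.
#' @param covariate_effects named numeric, shared log-hazard effects of the
#'   covariates `age` (per year, centred at 62), `sex_male`, `smoking`
#'   (ordinal 0/1/2) and `confounder`.
#' @param admin_censor_years administrative censoring horizon in years.
#' @param start_date first monitoring day (a Monday by default so a 7-day
#'   wear includes one weekend).
#' @param seed integer root seed; per-participant substreams are derived
#'   from it so identical seed + config reproduces the cohort exactly.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_participants,
                       days_per_participant = 7,
                       bout_rate_per_day = 12,
                       p_zero_vilpa = 0.112,
                       rate_shape = 2,
                       bout_length_dist = default_bout_length_dist(),
                       wear_hours_dist = NULL,
                       state_dwell_params = list(sedentary = 25, standing = 5,
                                                 walking = 4),
                       sleep_hours = 7.4,
                       p_walk_moderate = 0.55,
                       beta_exposure = c(cvd = -0.10, cancer = -0.09,
                                         other = -0.05),
                       baseline_hazards = c(cvd = 0.0015, cancer = 0.0032,
                                            other = 0.0005),
                       covariate_effects = c(age = 0.08, sex_male = 0.4,
                                             smoking = 0.3, confounder = 0.2),
                       admin_censor_years = 6.9,
                       start_date = as.Date("2014-01-06"),
                       seed = 1L) {
  if (is.null(wear_hours_dist)) {
    wear_hours_dist <- function(n) {
      # mostly near-complete wear; ~5% of days fail the 16-h rule
      h <- stats::runif(n, 23.5, 24)
      low <- stats::runif(n) < 0.05
      h[low] <- stats::runif(sum(low), 8, 15)
      h
    }
  }
  cfg <- list(
    n_participants = n_participants,
    days_per_participant = days_per_participant,
    epoch_seconds = 10L,
    bout_rate_per_day = bout_rate_per_day,
    p_zero_vilpa = p_zero_vilpa,
    rate_shape = rate_shape,
    bout_length_dist = bout_length_dist,
    wear_hours_dist = wear_hours_dist,
    state_dwell_params = state_dwell_params,
    sleep_hours = sleep_hours,
    p_walk_moderate = p_walk_moderate,
    beta_exposure = beta_exposure,
    baseline_hazards = baseline_hazards,
    covariate_effects = covariate_effects,
    admin_censor_years = admin_censor_years,
    start_date = as.Date(start_date),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  chk_pos <- function(x, nm) {
    if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
      stop("invalid sim_config field '", nm, "': must be strictly positive")
    }
  }
  chk_pos(cfg$n_participants, "n_participants")
  chk_pos(cfg$days_per_participant, "days_per_participant")
  if (cfg$bout_rate_per_day < 0) {
    stop("invalid sim_config field 'bout_rate_per_day': must be non-negative")
  }
  if (cfg$p_zero_vilpa < 0 || cfg$p_zero_vilpa >= 1) {
    stop("invalid sim_config field 'p_zero_vilpa': must be in [0, 1)")
  }
  if (!(is.infinite(cfg$rate_shape) || cfg$rate_shape > 0)) {
    stop("invalid sim_config field 'rate_shape': must be positive or Inf")
  }
  p <- cfg$bout_length_dist
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("invalid sim_config field 'bout_length_dist': must be a probability vector summing to 1")
  }
  chk_pos(unlist(cfg$state_dwell_params), "state_dwell_params")
  chk_pos(cfg$sleep_hours, "sleep_hours")
  chk_pos(cfg$baseline_hazards, "baseline_hazards")
  chk_pos(cfg$admin_censor_years, "admin_censor_years")
  need <- c("cvd", "cancer", "other")
  if (!all(need %in% names(cfg$beta_exposure)) ||
      !all(need %in% names(cfg$baseline_hazards))) {
    stop("invalid sim_config field 'beta_exposure'/'baseline_hazards': must name causes ",
         paste(need, collapse = ", "))
  }
  invisible(cfg)
}

# Internal: deterministic per-participant substream seed (< 2^31), so
# participants are reproducible independently of generation order.
participant_seed <- function(root_seed, i) {
  as.integer((as.numeric(root_seed) * 2011 + as.numeric(i) * 7919) %% 2147483629)
}
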