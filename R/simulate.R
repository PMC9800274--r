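#' Simulate one participant's epoch series
#'
#' Generates an ordered 10-s epoch series of `days_per_participant` days
#' (8,640 epochs per day). Each day is laid out as contiguous nonwear blocks
#' at the day edges (don/doff behaviour), a sleep block at the start of
#' wear, and an awake period evolving as a semi-Markov chain over
#' sedentary/standing/walking states with exponential dwell times. Vigorous
#' runs are planted into the awake period: their count per day is
#' Poisson(`bout_rate_per_day`), their lengths follow `bout_length_dist`,
#' they never touch sleep or nonwear, never cross midnight, and successive
#' runs are separated by at least one non-vigorous epoch. Planted epochs are
#' ambulatory with acceleration at or above 400 mg; non-planted walking
#' epochs draw below 400 mg, so with the state-conditional draws the bout
#' engine recovers the planted runs exactly.
#'
#' @param config a [sim_config()].
#' @param participant_id identifier used in the output.
#' @param seed optional integer seed for this participant's substream;
#'   derived from `config$seed` and `participant_id` position by
#'   [simulate_cohort()].
#' @return an epoch series data frame (`participant_id`, `timestamp`,
#'   `state`, `accel_mg`) with attribute `"planted_runs"`: a data frame of
#'   the planted vigorous runs (`day_index`, `day`, `start_epoch`,
#'   `n_epochs`, `duration_s`) for oracle use.
#' @export
simulate_epoch_series <- function(config, participant_id = "p1", seed = NULL) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  n_day <- 8640L                      # 10-s epochs per day
  d <- config$days_per_participant
  dwell <- config$state_dwell_params

  # participant-level vigorous-run rate: a zero-VILPA mass plus gamma
  # heterogeneity around the population mean
  rate <- config$bout_rate_per_day
  if (config$p_zero_vilpa > 0 && stats::runif(1) < config$p_zero_vilpa) {
    rate <- 0
  } else if (is.finite(config$rate_shape)) {
    rate <- stats::rgamma(1, shape = config$rate_shape,
                          rate = config$rate_shape / max(rate, 1e-12))
  }

  states <- character(n_day * d)
  accel <- numeric(n_day * d)
  wear_h <- config$wear_hours_dist(d)
  wear_h <- pmin(pmax(wear_h, 0), 24)
  runs <- vector("list", d)

  for (day_i in seq_len(d)) {
    off <- (day_i - 1L) * n_day
    n_wear <- as.integer(round(wear_h[day_i] * 360))
    n_nonwear <- n_day - n_wear
    # nonwear split between day start and day end
    n_lead <- if (n_nonwear > 0) as.integer(round(stats::runif(1) * n_nonwear)) else 0L
    n_trail <- n_nonwear - n_lead
    n_sleep <- min(as.integer(round(config$sleep_hours * 360 *
                                      stats::runif(1, 0.85, 1.15))), n_wear)
    awake_start <- n_lead + n_sleep + 1L
    awake_end <- n_day - n_trail
    n_awake <- awake_end - awake_start + 1L

    st <- character(n_day)
    if (n_lead > 0) st[seq_len(n_lead)] <- "nonwear"
    if (n_sleep > 0) st[n_lead + seq_len(n_sleep)] <- "sleep"
    if (n_trail > 0) st[(n_day - n_trail + 1L):n_day] <- "nonwear"

    if (n_awake > 0) {
      # semi-Markov awake chain: exponential dwells, epochs of 10 s
      awake_states <- c("sedentary", "standing", "walking")
      trans_p <- c(sedentary = 0.55, standing = 0.27, walking = 0.18)
      n_seg <- ceiling(n_awake / (min(unlist(dwell)) * 6)) + 20L
      seg_state <- sample(awake_states, n_seg, replace = TRUE, prob = trans_p)
      seg_len <- pmax(1L, as.integer(round(
        stats::rexp(n_seg, rate = 1 / (unlist(dwell)[seg_state] * 6)))))
      chain <- rep(seg_state, seg_len)
      while (length(chain) < n_awake) {
        s2 <- sample(awake_states, 50, replace = TRUE, prob = trans_p)
        l2 <- pmax(1L, as.integer(round(
          stats::rexp(50, rate = 1 / (unlist(dwell)[s2] * 6)))))
        chain <- c(chain, rep(s2, l2))
      }
      st[awake_start:awake_end] <- chain[seq_len(n_awake)]
    }

    # plant vigorous runs inside the awake period, pairwise non-adjacent
    day_runs <- data.frame(day_index = integer(0), start_epoch = integer(0),
                           n_epochs = integer(0))
    if (rate > 0 && n_awake > 2) {
      n_runs <- stats::rpois(1, rate)
      if (n_runs > 0) {
        lens <- sample(seq_along(config$bout_length_dist), n_runs,
                       replace = TRUE, prob = config$bout_length_dist)
        occupied <- rep(FALSE, n_day)
        for (k in seq_len(n_runs)) {
          L <- lens[k]
          if (L + 2L > n_awake) next  # day too short to hold this run
          placed <- FALSE
          for (try in 1:50) {
            s0 <- awake_start + as.integer(floor(stats::runif(1) * (n_awake - L)))
            span <- max(awake_start, s0 - 1L):min(awake_end, s0 + L)
            if (s0 + L - 1L <= awake_end && !any(occupied[span])) {
              occupied[s0:(s0 + L - 1L)] <- TRUE
              day_runs <- rbind(day_runs, data.frame(
                day_index = day_i, start_epoch = off + s0, n_epochs = L))
              placed <- TRUE
              break
            }
          }
          # a run that cannot be placed without touching another is dropped
        }
        if (nrow(day_runs) > 0) {
          for (k in seq_len(nrow(day_runs))) {
            i0 <- day_runs$start_epoch[k] - off
            idx <- i0:(i0 + day_runs$n_epochs[k] - 1L)
            st[idx] <- ifelse(stats::runif(length(idx)) < 0.3, "running", "walking")
          }
        }
      }
    }
    runs[[day_i]] <- day_runs

    # state-conditional acceleration draws (mg); planted runs >= 400
    ac <- numeric(n_day)
    ac[st == "nonwear"] <- 0
    ac[st == "sleep"] <- stats::runif(sum(st == "sleep"), 0, 15)
    ac[st == "sedentary"] <- stats::runif(sum(st == "sedentary"), 5, 40)
    ac[st == "standing"] <- stats::runif(sum(st == "standing"), 20, 90)
    walk <- which(st %in% c("walking", "running"))
    if (length(walk) > 0) {
      mod <- stats::runif(length(walk)) < config$p_walk_moderate
      ac[walk] <- ifelse(mod, stats::runif(length(walk), 100, 399),
                         stats::runif(length(walk), 30, 99))
    }
    if (nrow(day_runs) > 0) {
      for (k in seq_len(nrow(day_runs))) {
        i0 <- day_runs$start_epoch[k] - off
        idx <- i0:(i0 + day_runs$n_epochs[k] - 1L)
        ac[idx] <- stats::runif(length(idx), 400, 900)
      }
    }
    states[off + seq_len(n_day)] <- st
    accel[off + seq_len(n_day)] <- ac
  }

  t0 <- as.POSIXct(paste(config$start_date, "00:00:00"), tz = "UTC")
  series <- data.frame(
    participant_id = participant_id,
    timestamp = t0 + 10 * (seq_len(n_day * d) - 1L),
    state = states,
    accel_mg = accel,
    stringsAsFactors = FALSE
  )
  planted <- do.call(rbind, runs)
  planted$duration_s <- 10 * planted$n_epochs
  planted$day <- config$start_date + (planted$day_index - 1L)
  attr(series, "planted_runs") <- planted
  series
}

#' Ground-truth exposure from a planted-run log
#'
#' Recomputes the per-participant daily VILPA duration and length-
#' standardized frequency directly from the generator's log of planted
#' vigorous runs (not from the noisy epoch series), restricted to
#' wear-valid days, for use as an oracle against the bout engine.
#'
#' @param planted planted-run log (attribute `"planted_runs"` of
#'   [simulate_epoch_series()] output).
#' @param valid_days dates of wear-valid days ([validate_days()]).
#' @param participant_id identifier for the output row.
#' @return one-row data frame: `participant_id`,
#'   `true_vilpa_min_per_day_1min`, `true_vilpa_min_per_day_2min`,
#'   `true_freq_std_1min`, `true_freq_std_2min`.
#' @export
true_exposure_from_runs <- function(planted, valid_days, participant_id) {
  per_day <- function(f) {
    if (length(valid_days) == 0) return(NA_real_)
    mean(vapply(valid_days, function(d) {
      r <- planted[planted$day == d, , drop = FALSE]
      f(r[order(r$start_epoch), , drop = FALSE])
    }, numeric(1)))
  }
  data.frame(
    participant_id = participant_id,
    true_vilpa_min_per_day_1min = per_day(function(r)
      sum(r$duration_s[r$n_epochs <= 6L]) / 60),
    true_vilpa_min_per_day_2min = per_day(function(r)
      sum(r$duration_s[r$n_epochs <= 12L]) / 60),
    true_freq_std_1min = per_day(function(r)
      standardize_bouts(r$duration_s[r$n_epochs <= 6L], 60)),
    true_freq_std_2min = per_day(function(r)
      standardize_bouts(r$duration_s[r$n_epochs <= 12L], 120)),
    stringsAsFactors = FALSE
  )
}

#' Simulate a covariate table
#'
#' Draws the reduced covariate schema used throughout the synthetic
#' cohorts: age (years, roughly 62 +/- 7.6, the profile of the emulated
#' cohort), sex, a three-level smoking history, one continuous standardized
#' confounder, and baseline prevalent CVD/cancer indicators.
#'
#' @param n number of participants.
#' @param ids participant identifiers.
#' @return data frame with columns `participant_id`, `age`, `sex_male`,
#'   `smoking` (0 never / 1 previous / 2 current), `confounder`,
#'   `prevalent_cvd`, `prevalent_cancer`.
#' @export
simulate_covariates <- function(n, ids = paste0("p", seq_len(n))) {
  data.frame(
    participant_id = ids,
    age = pmin(pmax(stats::rnorm(n, 61.8, 7.6), 43), 79),
    sex_male = stats::rbinom(n, 1, 0.438),
    smoking = sample(0:2, n, replace = TRUE, prob = c(0.554, 0.354, 0.092)),
    confounder = stats::rnorm(n),
    prevalent_cvd = stats::rbinom(n, 1, 0.10),
    prevalent_cancer = stats::rbinom(n, 1, 0.08),
    stringsAsFactors = FALSE
  )
}

#' Simulate competing-risks survival outcomes
#'
#' Draws cause-specific event times from constant-baseline exponential
#' hazards `h_c(t | x, z) = lambda_c * exp(beta_c * x + gamma' z)` for the
#' causes CVD, cancer and other death. The observed time is the minimum
#' over causes and the administrative censoring horizon; the cause label is
#' the minimizing cause, or `"censored"` at the horizon.
#'
#' @param true_exposures data frame with `participant_id` and an exposure
#'   column (`exposure_col`), one row per participant.
#' @param covariates covariate table ([simulate_covariates()]) aligned by
#'   `participant_id`; may be `NULL` for exposure-only hazards.
#' @param config a [sim_config()] (uses `beta_exposure`,
#'   `baseline_hazards`, `covariate_effects`, `admin_censor_years`).
#' @param exposure_col name of the exposure column in `true_exposures`.
#' @return data frame `participant_id`, `time_years`, `cause` (one of
#'   `"cvd"`, `"cancer"`, `"other_death"`, `"censored"`).
#' @export
simulate_survival <- function(true_exposures, covariates, config,
                              exposure_col = "true_vilpa_min_per_day_1min") {
  n <- nrow(true_exposures)
  if (!is.null(covariates)) {
    if (nrow(covariates) != n) {
      stop("true_exposures and covariates have mismatched lengths")
    }
    covariates <- covariates[match(true_exposures$participant_id,
                                   covariates$participant_id), , drop = FALSE]
    if (any(is.na(covariates$participant_id))) {
      stop("covariate table does not cover all participants")
    }
    g <- config$covariate_effects
    lp_cov <- g[["age"]] * (covariates$age - 62) +
      g[["sex_male"]] * covariates$sex_male +
      g[["smoking"]] * covariates$smoking +
      g[["confounder"]] * covariates$confounder
  } else {
    lp_cov <- rep(0, n)
  }
  x <- true_exposures[[exposure_col]]
  causes <- c("cvd", "cancer", "other")
  times <- sapply(causes, function(cc) {
    rate <- config$baseline_hazards[[cc]] *
      exp(config$beta_exposure[[cc]] * x + lp_cov)
    stats::rexp(n, rate = rate)
  })
  times <- matrix(times, ncol = length(causes),
                  dimnames = list(NULL, causes))
  tmin <- apply(times, 1, min)
  which_c <- causes[apply(times, 1, which.min)]
  cens <- tmin > config$admin_censor_years
  data.frame(
    participant_id = true_exposures$participant_id,
    time_years = pmin(tmin, config$admin_censor_years),
    cause = ifelse(cens, "censored",
                   ifelse(which_c == "other", "other_death", which_c)),
    stringsAsFactors = FALSE
  )
}

#' Simulate a full synthetic cohort
#'
#' Wires the epoch-series, covariate and survival generators into one
#' seeded cohort. The true exposure table is recomputed from each
#' participant's planted-run log (not from the epoch series), restricted to
#' wear-valid days, so downstream bout-engine output can be checked against
#' ground truth. Survival depends on the true daily VILPA duration through
#' the configured cause-specific log hazard ratios.
#'
#' @param config a [sim_config()].
#' @return list with elements `epoch_series` (list of per-participant epoch
#'   data frames), `covariates`, `outcomes`, `true_exposures`,
#'   `validity` (list of per-participant [validate_days()] results).
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  n <- config$n_participants
  ids <- sprintf("p%04d", seq_len(n))
  series_list <- vector("list", n)
  truth <- vector("list", n)
  validity <- vector("list", n)
  for (i in seq_len(n)) {
    s <- simulate_epoch_series(config, ids[i],
                               seed = participant_seed(config$seed, i))
    series_list[[i]] <- s
    v <- validate_days(s)
    validity[[i]] <- v
    truth[[i]] <- true_exposure_from_runs(attr(s, "planted_runs"),
                                          v$valid_days, ids[i])
  }
  names(series_list) <- ids
  names(validity) <- ids
  true_exposures <- do.call(rbind, truth)
  set.seed(participant_seed(config$seed, n + 1L))
  covariates <- simulate_covariates(n, ids)
  surv_x <- true_exposures$true_vilpa_min_per_day_1min
  surv_in <- true_exposures
  surv_in$true_vilpa_min_per_day_1min[is.na(surv_x)] <- 0
  outcomes <- simulate_survival(surv_in, covariates, config)
  list(epoch_series = series_list, covariates = covariates,
       outcomes = outcomes, true_exposures = true_exposures,
       validity = validity)
}
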