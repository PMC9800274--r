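# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

# Build a small epoch series from state/accel vectors (10-s spacing, UTC).
make_series <- function(states, accel, start = "2014-01-06 08:00:00",
                        pid = "p1") {
  t0 <- as.POSIXct(start, tz = "UTC")
  data.frame(
    participant_id = pid,
    timestamp = t0 + 10 * (seq_along(states) - 1L),
    state = states,
    accel_mg = accel,
    stringsAsFactors = FALSE
  )
}

# A full synthetic day: n epochs of a base state, with vigorous runs
# (walking at 500 mg) planted at given start indices / lengths.
make_day <- function(run_starts = integer(0), run_lengths = integer(0),
                     n = 8640, base_state = "sedentary", base_accel = 20,
                     start = "2014-01-06 00:00:00", pid = "p1") {
  states <- rep(base_state, n)
  accel <- rep(base_accel, n)
  for (i in seq_along(run_starts)) {
    idx <- run_starts[i]:(run_starts[i] + run_lengths[i] - 1L)
    states[idx] <- "walking"
    accel[idx] <- 500
  }
  make_series(states, accel, start, pid)
}

# VILPA-like exposure draws: a zero point mass plus a gamma body.
draw_exposures <- function(n, p_zero = 0.112, shape = 2, scale = 2.2) {
  ifelse(stats::runif(n) < p_zero, 0, stats::rgamma(n, shape, scale = scale))
}

# Config for single-cause exponential survival (the two other causes are
# made negligible; baseline_hazards validation requires them positive).
single_cause_config <- function(n, beta, lambda0, censor_years = 6.9) {
  sim_config(
    n_participants = n,
    beta_exposure = c(cvd = beta, cancer = 0, other = 0),
    baseline_hazards = c(cvd = lambda0, cancer = 1e-12, other = 1e-12),
    admin_censor_years = censor_years
  )
}

# Draw a modelling-scale cohort (exposure + single-cause survival) without
# epoch series; used for model-fitting tests.
sim_linear_cohort <- function(n, beta, lambda0, censor_years = 6.9) {
  x <- draw_exposures(n)
  te <- data.frame(participant_id = sprintf("p%05d", seq_len(n)),
                   true_vilpa_min_per_day_1min = x,
                   stringsAsFactors = FALSE)
  cfg <- single_cause_config(n, beta, lambda0, censor_years)
  sv <- simulate_survival(te, NULL, cfg)
  out <- data.frame(participant_id = te$participant_id, exposure = x,
                    time_years = sv$time_years, cause = sv$cause,
                    stringsAsFactors = FALSE)
  out
}

# Independent brute-force rolling-sum accumulator (deliberately written as
# an explicit while-loop state machine, unlike the package implementation).
oracle_standardize <- function(durations, standard) {
  acc <- 0; bouts <- 0; i <- 1
  while (i <= length(durations)) {
    acc <- acc + durations[i]
    if (acc >= standard) { bouts <- bouts + 1; acc <- 0 }
    i <- i + 1
  }
  bouts + acc / standard
}

# Independent Cox partial log-likelihood by explicit risk-set enumeration
# (no ties assumed).
oracle_cox_loglik <- function(time, status, X, beta) {
  eta <- as.numeric(X %*% beta)
  ll <- 0
  for (i in which(status == 1)) {
    risk <- time >= time[i]
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}
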