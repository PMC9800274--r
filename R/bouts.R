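#' Assign activity intensity to classified epochs
#'
#' Maps a 10-second epoch's activity class and mean acceleration to an
#' intensity label. Ambulatory classes (walking, running) are split by the
#' standard wrist-acceleration thresholds: light below 100 mg, moderate from
#' 100 mg, vigorous from 400 mg (mg = milli-gravity). Non-ambulatory classes
#' carry their intensity regardless of acceleration: sedentary epochs are
#' sedentary, standing utilitarian movement is light, and sleep/nonwear pass
#' through unchanged.
#'
#' @param state character vector of activity classes; one of `"nonwear"`,
#'   `"sleep"`, `"sedentary"`, `"standing"`, `"walking"`, `"running"`.
#' @param accel_mg numeric vector of epoch mean accelerations in milli-gravity
#'   (non-negative).
#' @return character vector of intensities in
#'   `{"sedentary","light","moderate","vigorous","sleep","nonwear"}`.
#' @examples
#' classify_intensity(c("walking", "walking", "sedentary"), c(450, 100, 500))
#' @export
classify_intensity <- function(state, accel_mg) {
  valid <- c("nonwear", "sleep", "sedentary", "standing", "walking", "running")
  bad <- setdiff(unique(state), valid)
  if (length(bad) > 0) {
    stop("unknown activity state label(s): ", paste(bad, collapse = ", "))
  }
  if (any(!is.finite(accel_mg)) || any(accel_mg < 0)) {
    stop("accel_mg must be finite and non-negative")
  }
  out <- character(length(state))
  out[state == "nonwear"]   <- "nonwear"
  out[state == "sleep"]     <- "sleep"
  out[state == "sedentary"] <- "sedentary"
  out[state == "standing"]  <- "light"
  amb <- state %in% c("walking", "running")
  out[amb] <- ifelse(accel_mg[amb] >= 400, "vigorous",
                     ifelse(accel_mg[amb] >= 100, "moderate", "light"))
  out
}

#' Detect vigorous bouts in an epoch series
#'
#' Finds maximal runs of consecutive vigorous epochs within each
#' participant-day. Runs never cross a day boundary (a run spanning midnight
#' is split). Each bout is categorised by its raw length: up to 6 epochs
#' (<= 1 min) `short_1min`, 7-12 epochs (<= 2 min) `short_2min`, and more
#' than 12 consecutive vigorous windows `long_vpa` (a long VPA session, not
#' a VILPA bout).
#'
#' @param series an epoch series data frame as produced by
#'   [simulate_epoch_series()] or [read_epochs()]: columns `participant_id`,
#'   `timestamp` (POSIXct, strictly increasing, 10-s spacing within a day),
#'   `state`, `accel_mg`.
#' @return data frame with one row per bout: `participant_id`, `day` (Date),
#'   `start_epoch` (index into `series`), `n_epochs`, `duration_s`,
#'   `category`.
#' @export
detect_bouts <- function(series) {
  validate_epoch_series(series)
  intensity <- classify_intensity(series$state, series$accel_mg)
  vig <- intensity == "vigorous"
  day <- as.Date(series$timestamp, tz = "UTC")
  empty <- data.frame(
    participant_id = character(0), day = as.Date(character(0)),
    start_epoch = integer(0), n_epochs = integer(0),
    duration_s = numeric(0), category = character(0),
    stringsAsFactors = FALSE
  )
  idx <- which(vig)
  if (length(idx) == 0) return(empty)
  # break a run where epochs are non-adjacent or the day changes
  new_run <- c(TRUE, diff(idx) != 1L | day[idx[-1]] != day[idx[-length(idx)]])
  run_id <- cumsum(new_run)
  start <- idx[new_run]
  n <- as.integer(tabulate(run_id))
  data.frame(
    participant_id = series$participant_id[start],
    day = day[start],
    start_epoch = start,
    n_epochs = n,
    duration_s = 10 * n,
    category = ifelse(n > 12L, "long_vpa",
                      ifelse(n > 6L, "short_2min", "short_1min")),
    stringsAsFactors = FALSE
  )
}

#' Length-standardize a sequence of raw bout durations
#'
#' Converts raw bouts of variable length into analytic bouts of a fixed
#' standard length (1 or 2 min) by a rolling sum: durations are accumulated
#' in temporal order; whenever the running sum reaches or exceeds the
#' standard length one analytic bout is counted and the running sum is reset
#' to zero (any excess beyond the standard length is discarded); the terminal
#' remainder counts fractionally as `remainder / standard_s`.
#'
#' Five consecutive raw bouts of 20, 30, 20, 40 and 10 seconds standardized
#' to 60 s therefore yield 1.8333... analytic bouts (displayed 1.83): the
#' first three raw bouts complete one analytic bout, the last two contribute
#' 50/60.
#'
#' @param durations_s numeric vector of raw bout durations in seconds, in
#'   temporal order; every duration must be positive and no longer than
#'   `standard_s` (pass only the bouts of the matching length category).
#' @param standard_s standard bout length in seconds, 60 or 120.
#' @return a single non-negative number, the standardized bout count at full
#'   precision (round to 2 decimals for display only).
#' @examples
#' standardize_bouts(c(20, 30, 20, 40, 10), 60)  # 1.8333...
#' @export
standardize_bouts <- function(durations_s, standard_s) {
  if (!standard_s %in% c(60, 120)) {
    stop("standard_s must be 60 or 120 seconds")
  }
  if (length(durations_s) == 0) return(0)
  if (any(!is.finite(durations_s)) || any(durations_s <= 0)) {
    stop("bout durations must be positive and finite")
  }
  if (any(durations_s > standard_s)) {
    stop("bout duration exceeds the standard length ", standard_s,
         " s; category mismatch")
  }
  count <- 0
  run <- 0
  for (d in durations_s) {
    run <- run + d
    if (run >= standard_s) {
      count <- count + 1
      run <- 0  # excess beyond the standard length is discarded
    }
  }
  count + run / standard_s
}

#' Screen monitoring days for wear validity
#'
#' A monitoring day is valid when its wear time (time in any state other
#' than nonwear) is strictly greater than 16 hours. A participant is
#' included in analysis when they have at least three valid days of which at
#' least one is a weekend day (Saturday or Sunday of the local timestamp).
#'
#' @inheritParams detect_bouts
#' @return a list with `days`: data frame (`day`, `wear_hours`, `valid`,
#'   `weekend`), `valid_days`: the valid dates, and `included`: logical,
#'   whether the participant meets the inclusion rule.
#' @export
validate_days <- function(series) {
  validate_epoch_series(series)
  day <- as.Date(series$timestamp, tz = "UTC")
  worn <- series$state != "nonwear"
  wear_h <- tapply(worn, day, sum) * 10 / 3600
  days <- as.Date(names(wear_h))
  wd <- format(days, "%u")  # 1 = Monday ... 7 = Sunday
  out <- data.frame(
    day = days,
    wear_hours = as.numeric(wear_h),
    valid = as.numeric(wear_h) > 16,   # strict: exactly 16.0 h is invalid
    weekend = wd %in% c("6", "7"),
    stringsAsFactors = FALSE
  )
  list(
    days = out,
    valid_days = out$day[out$valid],
    included = sum(out$valid) >= 3 && any(out$valid & out$weekend)
  )
}

#' Build a participant's exposure record from detected bouts
#'
#' Computes, per valid monitoring day and then averaged across valid days:
#' daily VILPA duration (min/day) for the up-to-1-min and up-to-2-min bout
#' definitions (the 2-min definition cumulatively includes bouts up to
#' 1 min), length-standardized VILPA bout frequency for both standard
#' lengths, long VPA session duration and frequency (runs longer than 12
#' epochs, used as model adjustment terms), daily light- and
#' moderate-intensity minutes, and sleep hours. Invalid days contribute
#' nothing. The rolling-sum standardization is scoped within each
#' participant-day and resets at day boundaries.
#'
#' @inheritParams detect_bouts
#' @param bouts bout table from [detect_bouts()] for the same participant;
#'   computed from `series` when omitted.
#' @param validity result of [validate_days()]; computed when omitted.
#' @return one-row data frame (an exposure record) with columns
#'   `participant_id`, `n_valid_days`, `vilpa_min_per_day_1min`,
#'   `vilpa_min_per_day_2min`, `freq_std_1min`, `freq_std_2min`,
#'   `long_vpa_min_per_day`, `long_vpa_freq`, `light_min_per_day`,
#'   `moderate_min_per_day`, `sleep_h_per_day`; or `NULL` with a warning if
#'   the participant fails the inclusion rule.
#' @export
compute_exposures <- function(series, bouts = NULL, validity = NULL) {
  if (is.null(validity)) validity <- validate_days(series)
  if (!validity$included || length(validity$valid_days) == 0) {
    warning("participant excluded: fewer than 3 valid days or no valid weekend day")
    return(NULL)
  }
  if (is.null(bouts)) bouts <- detect_bouts(series)
  valid_days <- validity$valid_days
  nvd <- length(valid_days)
  intensity <- classify_intensity(series$state, series$accel_mg)
  day <- as.Date(series$timestamp, tz = "UTC")
  on_valid <- day %in% valid_days

  per_day <- function(f) {
    vals <- vapply(valid_days, f, numeric(1))
    mean(vals)
  }
  day_bouts <- function(d) bouts[bouts$day == d, , drop = FALSE]

  dur1 <- per_day(function(d) {
    b <- day_bouts(d); sum(b$duration_s[b$n_epochs <= 6L]) / 60
  })
  dur2 <- per_day(function(d) {
    b <- day_bouts(d); sum(b$duration_s[b$n_epochs <= 12L]) / 60
  })
  f1 <- per_day(function(d) {
    b <- day_bouts(d)
    standardize_bouts(b$duration_s[b$n_epochs <= 6L], 60)
  })
  f2 <- per_day(function(d) {
    b <- day_bouts(d)
    standardize_bouts(b$duration_s[b$n_epochs <= 12L], 120)
  })
  long_min <- per_day(function(d) {
    b <- day_bouts(d); sum(b$duration_s[b$n_epochs > 12L]) / 60
  })
  long_n <- per_day(function(d) {
    b <- day_bouts(d); sum(b$n_epochs > 12L)
  })
  dayf <- factor(day[on_valid], levels = as.character(valid_days))
  min_in <- function(which_int, per_hour = FALSE) {
    by_day <- tapply(intensity[on_valid] == which_int, dayf, sum)
    by_day[is.na(by_day)] <- 0
    mean(by_day) * 10 / if (per_hour) 3600 else 60
  }
  light <- min_in("light")
  moderate <- min_in("moderate")
  sleep_h <- min_in("sleep", per_hour = TRUE)

  data.frame(
    participant_id = series$participant_id[1],
    n_valid_days = nvd,
    vilpa_min_per_day_1min = dur1,
    vilpa_min_per_day_2min = dur2,
    freq_std_1min = f1,
    freq_std_2min = f2,
    long_vpa_min_per_day = long_min,
    long_vpa_freq = long_n,
    light_min_per_day = light,
    moderate_min_per_day = moderate,
    sleep_h_per_day = sleep_h,
    stringsAsFactors = FALSE
  )
}

#' Cap exposure variables at an upper percentile
#'
#' Winsorizes the VILPA exposure columns of an exposure table at their
#' empirical upper percentile (default 97.5th, linear-interpolation
#' definition) to limit the influence of sparse data in the exposure tail.
#' Values above the percentile are replaced by it; capping is idempotent.
#'
#' @param records exposure table (rows from [compute_exposures()]).
#' @param percentile upper percentile in (0, 100); default 97.5.
#' @param fields columns to cap; defaults to the four VILPA exposure columns.
#' @param thresholds optional named vector of pre-computed cap values (as
#'   recorded in the `"cap_thresholds"` attribute of an earlier call);
#'   re-applying a recorded cap is exactly idempotent, whereas re-estimating
#'   the percentile on already-capped data moves it by the interpolation
#'   sliver below the cap.
#' @return the exposure table with capped columns and attribute
#'   `"cap_thresholds"`; the input is not modified. With fewer than 40
#'   records the table is returned uncapped with a warning (the percentile
#'   is not meaningful).
#' @export
cap_exposures <- function(records, percentile = 97.5,
                          fields = c("vilpa_min_per_day_1min",
                                     "vilpa_min_per_day_2min",
                                     "freq_std_1min", "freq_std_2min"),
                          thresholds = NULL) {
  stopifnot(percentile > 0, percentile < 100)
  if (nrow(records) < 40) {
    warning("fewer than 40 records; exposures returned uncapped")
    return(records)
  }
  fields <- intersect(fields, names(records))
  caps <- numeric(0)
  for (f in fields) {
    cap <- if (!is.null(thresholds)) {
      thresholds[[f]]
    } else {
      stats::quantile(records[[f]], percentile / 100, type = 7, names = FALSE)
    }
    records[[f]] <- pmin(records[[f]], cap)
    caps[f] <- cap
  }
  attr(records, "cap_thresholds") <- caps
  records
}

# Internal: structural checks shared by the bout-engine entry points.
validate_epoch_series <- function(series) {
  need <- c("participant_id", "timestamp", "state", "accel_mg")
  miss <- setdiff(need, names(series))
  if (length(miss) > 0) {
    stop("epoch series is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(series) == 0) stop("epoch series is empty")
  ts <- as.numeric(series$timestamp)
  if (any(diff(ts) <= 0)) stop("epoch timestamps must be strictly increasing")
  day <- as.Date(series$timestamp, tz = "UTC")
  same_day <- diff(as.integer(day)) == 0
  if (any(diff(ts)[same_day] != 10)) {
    stop("epoch timestamps must have constant 10-s spacing within a day")
  }
  invisible(TRUE)
}
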