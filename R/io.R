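#' Read and write epoch series CSV
#'
#' Epoch series are exchanged as CSV with columns `participant_id`,
#' `timestamp` (ISO-8601, UTC), `state`, `accel_mg`. Gzip-compressed files
#' (`.gz`) are read and written transparently. Reading validates the schema
#' and timestamp monotonicity per participant.
#'
#' @param path file path (`.csv` or `.csv.gz`).
#' @return `read_epochs()`: a single data frame covering all participants,
#'   ordered by participant then time.
#' @export
read_epochs <- function(path) {
  df <- read_table_file(path, c("participant_id", "timestamp", "state", "accel_mg"))
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC",
                             tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  if (any(is.na(df$timestamp))) {
    stop("unparseable ISO-8601 timestamps in ", path)
  }
  df$accel_mg <- as.numeric(df$accel_mg)
  for (pid in unique(df$participant_id)) {
    sub <- df[df$participant_id == pid, ]
    if (any(diff(as.numeric(sub$timestamp)) <= 0)) {
      stop("non-monotone timestamps for participant ", pid, " in ", path)
    }
  }
  df
}

#' @rdname read_epochs
#' @param series epoch series data frame (or list of them, row-bound).
#' @export
write_epochs <- function(series, path) {
  if (is.list(series) && !is.data.frame(series)) {
    series <- do.call(rbind, series)
  }
  out <- series
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  write_table_file(out, path)
  invisible(path)
}

#' Read/write a generic analysis table (covariates, outcomes, exposures)
#'
#' @param path file path (`.csv` or `.csv.gz`).
#' @param required character vector of columns that must be present.
#' @return data frame.
#' @export
read_table_file <- function(path, required = character(0)) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  # read.csv handles gzip-compressed files transparently
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse ", path, ": ",
                                          conditionMessage(e)))
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop("file ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  if (nrow(df) == 0) stop("file ", path, " contains no rows")
  df
}

#' @rdname read_table_file
#' @param df data frame to write.
#' @export
write_table_file <- function(df, path) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "w")
    on.exit(close(con))
    utils::write.csv(df, con, row.names = FALSE)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Pipeline configuration
#'
#' Assembles and validates the configuration of the end-to-end analysis
#' pipeline. All fields can also be supplied from a YAML file via
#' [read_pipeline_config()].
#'
#' @param epochs_path,covariates_path,outcomes_path input CSV paths.
#' @param bout_length bout definition in minutes, 1 or 2.
#' @param exposure `"duration"` (min/day) or `"frequency"`
#'   (length-standardized bouts/day).
#' @param outcome `"all_cause"`, `"cvd"` or `"cancer"`.
#' @param cap_percentile winsorization percentile (default 97.5).
#' @param landmark_years landmark exclusion window (default 2).
#' @param knot_percentiles spline knot percentiles (default 10, 50, 90).
#' @param covariates adjustment covariate column names.
#' @param grid_size dose-response grid size.
#' @param seed integer seed (used only where a stage is stochastic).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(epochs_path, covariates_path, outcomes_path,
                            bout_length = 1,
                            exposure = c("duration", "frequency"),
                            outcome = c("all_cause", "cvd", "cancer"),
                            cap_percentile = 97.5,
                            landmark_years = 2,
                            knot_percentiles = c(10, 50, 90),
                            covariates = c("age", "sex_male", "smoking",
                                           "confounder",
                                           "light_min_per_day",
                                           "moderate_min_per_day"),
                            grid_size = 200,
                            seed = 1L) {
  exposure <- match.arg(exposure)
  outcome <- match.arg(outcome)
  if (!bout_length %in% c(1, 2)) stop("bout_length must be 1 or 2")
  stopifnot(cap_percentile > 0, cap_percentile < 100)
  if (length(knot_percentiles) != 3 || any(diff(knot_percentiles) <= 0) ||
      any(knot_percentiles <= 0) || any(knot_percentiles >= 100)) {
    stop("knot_percentiles must be 3 strictly increasing values in (0, 100)")
  }
  structure(list(
    epochs_path = epochs_path, covariates_path = covariates_path,
    outcomes_path = outcomes_path, bout_length = bout_length,
    exposure = exposure, outcome = outcome,
    cap_percentile = cap_percentile, landmark_years = landmark_years,
    knot_percentiles = knot_percentiles, covariates = covariates,
    grid_size = grid_size, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file whose keys mirror the `pipeline_config()` arguments.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}
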