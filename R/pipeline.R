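#' Run the full exposure-to-dose-response pipeline
#'
#' Executes the complete analytic pathway on epoch, covariate and outcome
#' tables: wear-validity screening and exposure extraction per participant,
#' merging with covariates and outcomes, landmark and prevalent-disease
#' exclusions, percentile capping, knot placement on the capped analysis
#' sample, spline dose-response model fitting (Cox for all-cause mortality,
#' Fine-Gray for cause-specific mortality with competing causes), curve
#' construction, minimal-dose (ED50) extraction, HRs at the median and
#' maximum exposure, diagnostic tests, and E-values. Each stage logs record
#' counts in and out, echoing a sample-derivation flow diagram.
#'
#' @param config a [pipeline_config()].
#' @param out_report optional path for the JSON report.
#' @param out_curve optional path for the curve CSV
#'   (columns `exposure`, `hr`, `ci_low`, `ci_high`).
#' @return the report, invisibly as a list (also written to `out_report`
#'   when given).
#' @export
run_pipeline <- function(config, out_report = NULL, out_curve = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  flow <- list()
  log_stage <- function(stage, n_in, n_out) {
    flow[[length(flow) + 1]] <<- list(stage = stage, n_in = n_in,
                                      n_out = n_out, n_removed = n_in - n_out)
  }

  epochs <- read_epochs(config$epochs_path)
  covariates <- read_table_file(config$covariates_path, "participant_id")
  outcomes <- read_table_file(config$outcomes_path,
                              c("participant_id", "time_years", "cause"))

  # exposure extraction with wear-validity screening
  ids <- unique(epochs$participant_id)
  exposures <- list()
  for (pid in ids) {
    s <- epochs[epochs$participant_id == pid, , drop = FALSE]
    v <- validate_days(s)
    if (!v$included) next
    exposures[[pid]] <- compute_exposures(s, validity = v)
  }
  exposures <- do.call(rbind, exposures)
  if (is.null(exposures) || nrow(exposures) == 0) {
    stop("pipeline stage 'extract': no participant passed the wear-validity rules")
  }
  log_stage("wear validity (>16 h, >=3 valid days incl. weekend)",
            length(ids), nrow(exposures))

  dat <- merge(exposures, covariates, by = "participant_id")
  dat <- merge(dat, outcomes, by = "participant_id")
  log_stage("merge with covariates and outcomes", nrow(exposures), nrow(dat))

  dat2 <- apply_exclusions(dat, config$landmark_years, config$outcome)
  excl <- attr(dat2, "exclusion_log")
  for (i in seq_len(nrow(excl))) {
    log_stage(excl$rule[i], excl$n_in[i], excl$n_retained[i])
  }

  dat2 <- cap_exposures(dat2, config$cap_percentile)
  exposure_col <- exposure_column(config$exposure, config$bout_length)
  # mutual adjustment for vigorous bouts longer than the chosen bout length
  dat2$long_adj <- if (config$bout_length == 1) {
    (dat2$vilpa_min_per_day_2min - dat2$vilpa_min_per_day_1min) +
      dat2$long_vpa_min_per_day
  } else {
    dat2$long_vpa_min_per_day
  }
  covs <- intersect(config$covariates, names(dat2))
  covs <- covs[vapply(covs, function(cv) length(unique(dat2[[cv]])) > 1, logical(1))]
  if (length(unique(dat2$long_adj)) > 1) covs <- c(covs, "long_adj")

  spec <- spline_spec(dat2[[exposure_col]], config$knot_percentiles / 100)
  fit <- if (config$outcome == "all_cause") {
    fit_cox(dat2, exposure_col, spec, covs)
  } else {
    fit_fine_gray(dat2, exposure_col, spec, covs, cause = config$outcome)
  }

  curve <- build_curve(fit, config$grid_size)
  md <- minimal_dose(curve)
  med <- stats::median(dat2[[exposure_col]][dat2[[exposure_col]] > 0])
  mx <- max(dat2[[exposure_col]])
  at_med <- hr_at(curve, med)
  at_max <- hr_at(curve, mx)
  ev_point <- function(at) {
    lim <- if (at$hr < 1) at$ci[2] else at$ci[1]  # limit closer to the null
    e <- evalue(at$hr, lim)
    list(evalue_point = e$evalue_point, evalue_ci = e$evalue_ci)
  }
  nonlin <- test_nonlinearity(fit)
  ph <- tryCatch(test_proportional_hazards(fit), error = function(e) NULL)

  report <- list(
    config = list(bout_length = config$bout_length, exposure = config$exposure,
                  outcome = config$outcome,
                  cap_percentile = config$cap_percentile,
                  landmark_years = config$landmark_years,
                  knot_percentiles = config$knot_percentiles,
                  covariates = covs, seed = config$seed),
    sample_flow = flow,
    n_analysis = nrow(dat2),
    n_events = fit$n_events,
    knots = fit$spline_spec$knots,
    coefficients = as.list(round(fit$coefficients, 10)),
    model_kind = fit$model_kind,
    nonlinearity = list(statistic = round(nonlin$statistic, 10),
                        df = nonlin$df, p_value = round(nonlin$p_value, 10)),
    proportional_hazards = if (is.null(ph)) NULL else
      stats::setNames(as.list(round(ph$p_value, 10)), ph$term),
    ed50 = list(exposure = round(md$ed50_exposure, 10),
                hr = round(md$hr_at_ed50, 10), ci = round(md$ci, 10)),
    hr_at_median = list(exposure = round(med, 10), hr = round(at_med$hr, 10),
                        ci = round(at_med$ci, 10),
                        evalue = ev_point(at_med)),
    hr_at_max = list(exposure = round(mx, 10), hr = round(at_max$hr, 10),
                     ci = round(at_max$ci, 10),
                     evalue = ev_point(at_max))
  )
  if (!is.null(out_curve)) {
    utils::write.csv(data.frame(exposure = curve$exposure, hr = curve$hr,
                                ci_low = curve$ci_low,
                                ci_high = curve$ci_high),
                     out_curve, row.names = FALSE)
  }
  if (!is.null(out_report)) {
    jsonlite::write_json(report, out_report, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }
  invisible(report)
}

# Internal: map (exposure kind, bout length) to the exposure column name.
exposure_column <- function(exposure, bout_length) {
  if (exposure == "duration") {
    paste0("vilpa_min_per_day_", bout_length, "min")
  } else {
    paste0("freq_std_", bout_length, "min")
  }
}
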