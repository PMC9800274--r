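#' Apply landmark and prevalent-disease exclusions
#'
#' Removes participants whose death (any cause) occurs within the first
#' `landmark_years` of follow-up, to limit reverse causation through
#' prodromal disease. Participants censored before the landmark are
#' retained; only deaths trigger removal. For cause-specific outcomes the
#' corresponding prevalent-disease participants are also removed
#' (`prevalent_cvd` for the CVD analysis, `prevalent_cancer` for cancer).
#'
#' @param records analysis table with columns `time_years`, `cause`, and for
#'   cause-specific outcomes a `prevalent_cvd` / `prevalent_cancer` flag.
#' @param landmark_years landmark window in years (default 2).
#' @param outcome one of `"all_cause"`, `"cvd"`, `"cancer"`.
#' @return the filtered table, with attribute `"exclusion_log"`: a data
#'   frame of counts in/removed/retained per rule.
#' @export
apply_exclusions <- function(records, landmark_years = 2,
                             outcome = c("all_cause", "cvd", "cancer")) {
  outcome <- match.arg(outcome)
  stopifnot(all(c("time_years", "cause") %in% names(records)))
  log <- data.frame(rule = character(0), n_in = integer(0),
                    n_removed = integer(0), n_retained = integer(0))
  note <- function(rule, n_in, n_rm) {
    rbind(log, data.frame(rule = rule, n_in = n_in, n_removed = n_rm,
                          n_retained = n_in - n_rm))
  }
  early_death <- records$cause != "censored" & records$time_years < landmark_years
  log <- note(sprintf("death within %g-year landmark", landmark_years),
              nrow(records), sum(early_death))
  records <- records[!early_death, , drop = FALSE]
  if (outcome != "all_cause") {
    flag <- paste0("prevalent_", outcome)
    if (!flag %in% names(records)) {
      stop("cause-specific analysis requires the '", flag, "' covariate flag")
    }
    prev <- records[[flag]] == 1
    log <- note(paste("prevalent", outcome, "at baseline"),
                nrow(records), sum(prev))
    records <- records[!prev, , drop = FALSE]
  }
  attr(records, "exclusion_log") <- log
  records
}

#' Restricted cubic spline specification from exposure percentiles
#'
#' Places the three spline knots at the 10th, 50th and 90th percentiles of
#' the (capped) analysis-sample exposure.
#'
#' @param x exposure vector of the analysis sample (after capping).
#' @param probs knot percentiles as proportions (default `c(.1, .5, .9)`).
#' @return object of class `spline_spec`: list with `knots` (length 3,
#'   strictly increasing).
#' @export
spline_spec <- function(x, probs = c(0.10, 0.50, 0.90)) {
  knots <- unname(stats::quantile(x, probs, type = 7))
  new_spline_spec(knots)
}

#' @rdname spline_spec
#' @param knots explicit knot locations (strictly increasing, length 3).
#' @export
new_spline_spec <- function(knots) {
  if (length(knots) != 3 || any(diff(knots) <= 0)) {
    stop("spline knots must be 3 strictly increasing values")
  }
  structure(list(knots = as.numeric(knots)), class = "spline_spec")
}

#' Restricted cubic spline basis (3 knots)
#'
#' Evaluates the two-column natural cubic spline basis with 3 knots:
#' column 1 is the exposure itself; column 2 is the restricted cubic term,
#' cubic between the knots, linear beyond the boundary knots, with
#' continuous second derivative, scaled by the squared knot span. Below the
#' first knot column 2 is exactly zero, so the basis at exposure 0 (with
#' non-negative exposures and a positive first knot) is the natural
#' referent.
#'
#' @param x numeric exposure values.
#' @param spec a [spline_spec()].
#' @return numeric matrix with columns `exp_lin`, `exp_nl`.
#' @export
rcs_basis <- function(x, spec) {
  if (!inherits(spec, "spline_spec")) spec <- new_spline_spec(spec)
  k <- spec$knots
  pp3 <- function(u) pmax(u, 0)^3
  nl <- (pp3(x - k[1]) -
           pp3(x - k[2]) * (k[3] - k[1]) / (k[3] - k[2]) +
           pp3(x - k[3]) * (k[2] - k[1]) / (k[3] - k[2])) / (k[3] - k[1])^2
  cbind(exp_lin = x, exp_nl = nl)
}

#' Fit a Cox proportional hazards dose-response model
#'
#' Fits the Cox model (Efron tie handling) for all-cause mortality with the
#' exposure entering through its restricted-cubic-spline basis, plus any
#' adjustment covariates. The partial-likelihood maximization is performed
#' by [survival::coxph()].
#'
#' @param records analysis table with `time_years`, `cause`, the exposure
#'   column and covariate columns.
#' @param exposure_col name of the exposure column.
#' @param spec a [spline_spec()]; computed from the records when `NULL`.
#' @param covariates character vector of adjustment covariate column names.
#' @return object of class `vilpa_fit`: list with `coefficients`,
#'   `covariance`, `log_likelihood`, `n_events`, `model_kind = "cox"`,
#'   `spline_spec`, `exposure_terms` (names of the spline coefficients),
#'   `exposure_range`, and the underlying `coxph` fit.
#' @export
fit_cox <- function(records, exposure_col, spec = NULL,
                    covariates = character(0)) {
  x <- records[[exposure_col]]
  if (is.null(spec)) spec <- spline_spec(x)
  status <- as.integer(records$cause != "censored")
  if (sum(status) < 2) stop("fewer than 2 events; cannot fit")
  basis <- rcs_basis(x, spec)
  dat <- data.frame(time_years = records$time_years, status = status,
                    exp_lin = basis[, 1], exp_nl = basis[, 2])
  for (cv in covariates) {
    if (is.null(records[[cv]])) stop("missing covariate column: ", cv)
    if (length(unique(records[[cv]])) < 2) {
      stop("constant covariate column: ", cv)
    }
    dat[[cv]] <- records[[cv]]
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(time_years, status) ~ exp_lin + exp_nl",
    if (length(covariates)) paste("+", paste(covariates, collapse = " + ")) else ""))
  cfit <- survival::coxph(fml, data = dat, ties = "efron")
  if (!is.null(cfit$info) && isTRUE(cfit$info$flag > 0)) {
    warning("possible separation or convergence issue in Cox fit")
  }
  new_vilpa_fit(cfit, "cox", spec, exposure_range = range(x), data = dat)
}

#' Fit a Fine-Gray subdistribution hazards dose-response model
#'
#' Fits the Fine-Gray model for one cause of death in the presence of
#' competing causes: competing-event participants remain in the risk sets
#' with time-varying weights from the Kaplan-Meier estimate of the
#' censoring distribution of the analysis sample. Implemented via the
#' weighted-data expansion of [survival::finegray()] followed by a weighted
#' Cox fit; coefficients are on the subdistribution log-hazard-ratio scale.
#' When the data contain no competing events the subdistribution and
#' cause-specific hazards coincide and a Cox fit is returned with a note.
#'
#' @inheritParams fit_cox
#' @param cause target cause, `"cvd"` or `"cancer"` (or `"other_death"`).
#' @return object of class `vilpa_fit` with `model_kind = "fine_gray"`.
#' @export
fit_fine_gray <- function(records, exposure_col, spec = NULL,
                          covariates = character(0), cause = "cvd") {
  x <- records[[exposure_col]]
  if (is.null(spec)) spec <- spline_spec(x)
  if (sum(records$cause == cause) < 2) {
    stop("fewer than 2 events of cause '", cause, "'; cannot fit")
  }
  basis <- rcs_basis(x, spec)
  lev <- c("censored", cause,
           setdiff(unique(records$cause), c("censored", cause)))
  ev <- factor(records$cause, levels = lev)
  dat <- data.frame(time_years = records$time_years, event = ev,
                    exp_lin = basis[, 1], exp_nl = basis[, 2])
  for (cv in covariates) dat[[cv]] <- records[[cv]]
  n_competing <- sum(records$cause != "censored" & records$cause != cause)
  if (n_competing == 0) {
    message("no competing events: subdistribution model coincides with Cox; ",
            "fitting Cox on the cause-specific status")
    rec2 <- records
    rec2$cause <- ifelse(records$cause == cause, cause, "censored")
    fit <- fit_cox(rec2, exposure_col, spec, covariates)
    fit$model_kind <- "fine_gray"
    fit$note <- "no competing events; Cox coincidence"
    return(fit)
  }
  fg <- survival::finegray(survival::Surv(time_years, event) ~ ., data = dat,
                           etype = cause)
  if (any(fg$fgwt <= 0)) stop("degenerate Fine-Gray weights")
  fg$fgwt <- pmax(fg$fgwt, 1e-8)
  fml <- stats::as.formula(paste(
    "survival::Surv(fgstart, fgstop, fgstatus) ~ exp_lin + exp_nl",
    if (length(covariates)) paste("+", paste(covariates, collapse = " + ")) else ""))
  cfit <- survival::coxph(fml, data = fg, weights = fg$fgwt, ties = "efron")
  new_vilpa_fit(cfit, "fine_gray", spec, exposure_range = range(x), data = fg)
}

# Internal constructor for fit results.
new_vilpa_fit <- function(cfit, kind, spec, exposure_range, data) {
  structure(list(
    coefficients = stats::coef(cfit),
    covariance = stats::vcov(cfit),
    log_likelihood = cfit$loglik[length(cfit$loglik)],
    n_events = cfit$nevent,
    model_kind = kind,
    spline_spec = spec,
    exposure_terms = c("exp_lin", "exp_nl"),
    exposure_range = exposure_range,
    fit = cfit,
    data = data
  ), class = "vilpa_fit")
}

#' @export
print.vilpa_fit <- function(x, ...) {
  cat(sprintf("<vilpa_fit: %s, %d events>\n", x$model_kind, x$n_events))
  cat("knots:", signif(x$spline_spec$knots, 4), "\n")
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' Wald test for departure from linearity
#'
#' Tests the nonlinear restricted-cubic-spline coefficient(s) of a fitted
#' dose-response model against zero with a Wald chi-square statistic
#' `b' V^{-1} b`. With a single nonlinear term this equals the squared
#' z-score of that coefficient.
#'
#' @param fit a `vilpa_fit`.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
test_nonlinearity <- function(fit) {
  nl <- setdiff(fit$exposure_terms, "exp_lin")
  if (length(nl) == 0 || !all(nl %in% names(fit$coefficients))) {
    stop("fit carries no nonlinear spline term")
  }
  b <- fit$coefficients[nl]
  V <- fit$covariance[nl, nl, drop = FALSE]
  stat <- as.numeric(t(b) %*% solve(V, b))
  df <- length(b)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Schoenfeld-residual proportional hazards check
#'
#' Tests the proportional hazards assumption by correlating scaled
#' Schoenfeld residuals with event time ([survival::cox.zph()]).
#'
#' @param fit a `vilpa_fit`.
#' @return data frame of per-term rows plus a `GLOBAL` row, columns
#'   `term`, `chisq`, `df`, `p_value`; the residual count (attribute
#'   `"n_residuals"`) equals the event count.
#' @export
test_proportional_hazards <- function(fit) {
  if (fit$n_events < 2) stop("fewer than 2 events; cannot test")
  z <- survival::cox.zph(fit$fit)
  out <- data.frame(term = rownames(z$table), chisq = z$table[, "chisq"],
                    df = z$table[, "df"], p_value = z$table[, "p"],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_residuals") <- fit$n_events
  out
}
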