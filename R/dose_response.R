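#' Build a dose-response curve from a fitted model
#'
#' Evaluates the fitted spline dose-response on an exposure grid from 0 to
#' the (capped) maximum exposure, relative to the zero-exposure referent:
#' `log HR(x) = [basis(x) - basis(0)]' beta` with pointwise delta-method
#' standard errors from the coefficient covariance and 95% Wald confidence
#' limits on the log scale. The referent has HR = 1 with a degenerate CI.
#'
#' @param fit a `vilpa_fit` from [fit_cox()] or [fit_fine_gray()].
#' @param grid_size number of grid points (default 200).
#' @param grid_max upper end of the grid; defaults to the fitted exposure
#'   maximum and must not exceed it.
#' @return object of class `dose_response_curve`: data frame with columns
#'   `exposure`, `log_hr`, `se`, `hr`, `ci_low`, `ci_high`.
#' @export
build_curve <- function(fit, grid_size = 200, grid_max = NULL) {
  if (is.null(grid_max)) grid_max <- fit$exposure_range[2]
  if (grid_max > fit$exposure_range[2] + 1e-9 || grid_max <= 0) {
    stop("grid must lie within the fitted exposure range [0, ",
         signif(fit$exposure_range[2], 4), "]")
  }
  grid <- seq(0, grid_max, length.out = grid_size)
  B <- rcs_basis(grid, fit$spline_spec)
  B0 <- rcs_basis(0, fit$spline_spec)
  D <- sweep(B, 2, B0)               # contrast with the zero referent
  idx <- fit$exposure_terms
  beta <- fit$coefficients[idx]
  V <- fit$covariance[idx, idx, drop = FALSE]
  log_hr <- as.numeric(D %*% beta)
  se <- sqrt(rowSums((D %*% V) * D))
  out <- data.frame(
    exposure = grid,
    log_hr = log_hr,
    se = se,
    hr = exp(log_hr),
    ci_low = exp(log_hr - 1.959964 * se),
    ci_high = exp(log_hr + 1.959964 * se)
  )
  class(out) <- c("dose_response_curve", "data.frame")
  out
}

#' Minimal dose (ED50) from a dose-response curve
#'
#' The optimal risk reduction is `1 - min(HR)` over the curve's exposure
#' grid; the minimal dose (ED50) is the smallest exposure at which half of
#' that reduction is attained, i.e. the smallest `x` with
#' `1 - HR(x) >= 0.5 * (1 - min HR)`, refined by linear interpolation of
#' the log hazard ratio between the bracketing grid points. The HR and its
#' pointwise 95% CI are reported at that exposure.
#'
#' @param curve a `dose_response_curve`.
#' @return list with `ed50_exposure`, `hr_at_ed50`, `ci` (length-2 vector).
#' @export
minimal_dose <- function(curve) {
  hr_min <- min(curve$hr)
  if (hr_min >= 1) {
    stop("curve shows no risk reduction (min HR >= 1); ED50 undefined")
  }
  target_hr <- (1 + hr_min) / 2          # HR at half the optimal reduction
  i <- which(curve$hr <= target_hr)[1]
  if (i == 1) {
    ed50 <- curve$exposure[1]
  } else {
    # interpolate the crossing on the log-HR scale between grid neighbours
    l0 <- curve$log_hr[i - 1]; l1 <- curve$log_hr[i]
    w <- (log(target_hr) - l0) / (l1 - l0)
    ed50 <- curve$exposure[i - 1] + w * (curve$exposure[i] - curve$exposure[i - 1])
  }
  at <- hr_at(curve, ed50)
  list(ed50_exposure = ed50, hr_at_ed50 = at$hr, ci = at$ci)
}

#' Hazard ratio at an exposure value
#'
#' Interpolates the dose-response curve at an arbitrary exposure within the
#' grid range; interpolation of the HR and of both CI limits is linear on
#' the log scale, so interpolated values always lie between the
#' neighbouring grid nodes and grid nodes are returned exactly.
#'
#' @param curve a `dose_response_curve`.
#' @param x exposure value in `[0, max(grid)]`.
#' @return list with `hr` and `ci` (length-2 vector).
#' @export
hr_at <- function(curve, x) {
  if (x < 0 || x > max(curve$exposure) + 1e-9) {
    stop("exposure ", x, " outside the curve range [0, ",
         signif(max(curve$exposure), 4), "]")
  }
  interp <- function(y) exp(stats::approx(curve$exposure, log(y), xout = x,
                                          rule = 2)$y)
  list(hr = interp(curve$hr),
       ci = c(interp(curve$ci_low), interp(curve$ci_high)))
}

#' E-value for unmeasured confounding
#'
#' Computes the E-value: the minimum strength of association, on the risk
#' ratio scale, that an unmeasured confounder would need with both exposure
#' and outcome to fully explain away an observed association. A protective
#' ratio is first inverted (`RR* = 1/HR`); then
#' `E = RR* + sqrt(RR* (RR* - 1))` for `RR* > 1` and 1 otherwise. The same
#' transform is applied to the confidence limit closer to the null; a CI
#' that crosses the null gives an E-value of 1. The hazard ratio is treated
#' as a rate ratio (rare-outcome setting).
#'
#' @param hr hazard ratio point estimate (> 0).
#' @param ci_limit_closer_to_null the CI limit closer to 1 (> 0), optional.
#' @return list with `hr_input`, `evalue_point`, `evalue_ci` (NA when no CI
#'   limit is supplied); values at full precision, conventionally reported
#'   to 2 decimals.
#' @examples
#' evalue(0.52, 0.72)  # E-values 3.26 and 2.12 (2 dp)
#' @export
evalue <- function(hr, ci_limit_closer_to_null = NULL) {
  if (!is.finite(hr) || hr <= 0) stop("hr must be a positive number")
  e_of <- function(r) {
    rr <- if (r < 1) 1 / r else r
    if (rr <= 1) 1 else rr + sqrt(rr * (rr - 1))
  }
  e_ci <- NA_real_
  if (!is.null(ci_limit_closer_to_null)) {
    cl <- ci_limit_closer_to_null
    if (!is.finite(cl) || cl <= 0) stop("CI limit must be a positive number")
    # a CI crossing the null needs no confounding to be explained away
    crosses <- (hr < 1 && cl >= 1) || (hr > 1 && cl <= 1) || hr == 1
    e_ci <- if (crosses) 1 else e_of(cl)
  }
  list(hr_input = hr, evalue_point = e_of(hr), evalue_ci = e_ci)
}
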