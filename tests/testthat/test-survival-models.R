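# Exclusion rules, spline basis, Cox and Fine-Gray fits, diagnostics.

test_that("landmark exclusion removes early deaths but keeps early censoring", {
  rec <- data.frame(
    participant_id = paste0("p", 1:5),
    time_years = c(1.5, 1.5, 2.5, 3.0, 6.9),
    cause = c("cvd", "censored", "cancer", "censored", "censored"),
    prevalent_cvd = c(0, 0, 1, 0, 0),
    prevalent_cancer = c(0, 0, 0, 0, 1),
    stringsAsFactors = FALSE
  )
  out <- apply_exclusions(rec, 2, "all_cause")
  expect_setequal(out$participant_id, c("p2", "p3", "p4", "p5"))
  log <- attr(out, "exclusion_log")
  expect_equal(log$n_in - log$n_removed, log$n_retained)

  out_cvd <- apply_exclusions(rec, 2, "cvd")
  expect_setequal(out_cvd$participant_id, c("p2", "p4", "p5"))
  out_ca <- apply_exclusions(rec, 2, "cancer")
  expect_setequal(out_ca$participant_id, c("p2", "p3", "p4"))

  # identity when nothing qualifies
  clean <- rec[rec$participant_id %in% c("p4"), ]
  expect_equal(nrow(apply_exclusions(clean, 2, "all_cause")), 1)
  expect_error(apply_exclusions(rec[, 1:3], 2, "cvd"), "prevalent_cvd")
})

test_that("restricted cubic basis is linear outside the boundary knots with C2 joins", {
  spec <- new_spline_spec(c(1, 3, 7))
  x_lo <- seq(-2, 1, by = 0.1)
  B <- rcs_basis(x_lo, spec)
  expect_equal(unname(B[, 2]), rep(0, length(x_lo)))  # zero below first knot
  expect_equal(unname(B[, 1]), x_lo)

  # second differences (curvature) continuous at every knot, zero outside
  h <- 1e-3
  curv <- function(x) {
    (rcs_basis(x + h, spec)[, 2] - 2 * rcs_basis(x, spec)[, 2] +
       rcs_basis(x - h, spec)[, 2]) / h^2
  }
  for (k in spec$knots) {
    expect_lt(abs(curv(k - 2 * h) - curv(k + 2 * h)), 1e-5 + 6 * h)
  }
  expect_lt(abs(curv(9)), 1e-6)   # linear above the last knot
  expect_lt(abs(curv(-1)), 1e-6)

  expect_error(new_spline_spec(c(3, 1, 7)), "strictly increasing")
})

test_that("spline fits span the same model space as the natural-spline basis", {
  set.seed(41)
  dat <- sim_linear_cohort(1500, beta = -0.25, lambda0 = 0.05)
  spec <- spline_spec(dat$exposure)
  fit <- fit_cox(dat, "exposure", spec)
  # oracle: same Cox model with splines::ns at identical knots
  k <- spec$knots
  ns_b <- splines::ns(dat$exposure, knots = k[2], Boundary.knots = k[c(1, 3)])
  df2 <- data.frame(time_years = dat$time_years,
                    status = as.integer(dat$cause != "censored"),
                    n1 = ns_b[, 1], n2 = ns_b[, 2])
  ofit <- survival::coxph(survival::Surv(time_years, status) ~ n1 + n2,
                          data = df2, ties = "efron")
  # identical maximized partial likelihood and fitted log HR curve
  expect_equal(fit$log_likelihood, ofit$loglik[2], tolerance = 1e-8)
  grid <- seq(0, max(dat$exposure), length.out = 30)
  mine <- rcs_basis(grid, spec) %*% fit$coefficients[c("exp_lin", "exp_nl")]
  mine <- mine - mine[1]
  ns_g <- predict(ns_b, grid)
  theirs <- ns_g %*% stats::coef(ofit)
  theirs <- theirs - theirs[1]
  expect_equal(as.numeric(mine), as.numeric(theirs), tolerance = 1e-6)
})

test_that("Cox partial likelihood matches brute-force risk-set enumeration", {
  rec <- data.frame(
    time_years = c(1, 2, 3, 4, 5, 6),
    cause = c("cvd", "censored", "cvd", "cvd", "censored", "cvd"),
    exposure = c(0, 1, 2, 0.5, 3, 1.5)
  )
  spec <- new_spline_spec(c(0.5, 1.5, 2.5))
  fit <- fit_cox(rec, "exposure", spec)
  X <- rcs_basis(rec$exposure, spec)
  ll <- oracle_cox_loglik(rec$time_years,
                          as.integer(rec$cause != "censored"),
                          X, fit$coefficients)
  expect_equal(fit$log_likelihood, ll, tolerance = 1e-8)
  expect_equal(fit$n_events, 4)
})

test_that("Cox recovers a planted log-linear effect and is calibrated under the null", {
  set.seed(60)
  dat <- sim_linear_cohort(4000, beta = -0.3, lambda0 = 0.04)
  spec <- spline_spec(dat$exposure)
  fit <- fit_cox(dat, "exposure", spec)
  cv <- build_curve(fit, 301)
  med <- stats::median(dat$exposure[dat$exposure > 0])
  at <- hr_at(cv, med)
  se <- (log(at$ci[2]) - log(at$hr)) / 1.959964
  expect_lt(abs(log(at$hr) - (-0.3 * med)) / se, 3)

  # null: |z| of the linear term rarely exceeds 3
  n_exceed <- 0
  for (rep in 1:30) {
    d0 <- sim_linear_cohort(800, beta = 0, lambda0 = 0.05)
    f0 <- fit_cox(d0, "exposure")
    z <- f0$coefficients["exp_lin"] /
      sqrt(f0$covariance["exp_lin", "exp_lin"])
    if (abs(z) > 3) n_exceed <- n_exceed + 1
  }
  expect_lte(n_exceed, 1)
})

test_that("coefficients are invariant to affine exposure rescaling", {
  set.seed(62)
  dat <- sim_linear_cohort(1200, beta = -0.3, lambda0 = 0.05)
  spec1 <- spline_spec(dat$exposure)
  fit1 <- fit_cox(dat, "exposure", spec1)
  dat2 <- dat
  dat2$exposure <- dat$exposure * 2.5
  spec2 <- new_spline_spec(spec1$knots * 2.5)
  fit2 <- fit_cox(dat2, "exposure", spec2)
  expect_equal(sign(fit1$coefficients), sign(fit2$coefficients))
  # log HR at matched exposures identical
  x0 <- c(1, 2, 4)
  l1 <- rcs_basis(x0, spec1) %*% fit1$coefficients[c("exp_lin", "exp_nl")]
  l2 <- rcs_basis(x0 * 2.5, spec2) %*% fit2$coefficients[c("exp_lin", "exp_nl")]
  expect_equal(as.numeric(l1), as.numeric(l2), tolerance = 1e-8)
})

test_that("Fine-Gray matches an independent competing-risks implementation", {
  skip_if_not_installed("cmprsk")
  set.seed(70)
  n <- 1500
  x <- draw_exposures(n)
  te <- data.frame(participant_id = sprintf("p%04d", 1:n),
                   true_vilpa_min_per_day_1min = x)
  cfg <- sim_config(n, beta_exposure = c(cvd = -0.25, cancer = 0.1, other = 0),
                    baseline_hazards = c(cvd = 0.03, cancer = 0.03, other = 1e-12),
                    admin_censor_years = 6.9)
  sv <- simulate_survival(te, NULL, cfg)
  dat <- data.frame(exposure = x, time_years = sv$time_years, cause = sv$cause)
  spec <- spline_spec(dat$exposure)
  fit <- fit_fine_gray(dat, "exposure", spec, cause = "cvd")
  X <- rcs_basis(dat$exposure, spec)
  crr_fit <- cmprsk::crr(dat$time_years, dat$cause, X,
                         failcode = "cvd", cencode = "censored")
  expect_equal(unname(fit$coefficients[c("exp_lin", "exp_nl")]),
               unname(crr_fit$coef), tolerance = 5e-3)
})

test_that("Fine-Gray weights are non-increasing step functions in (0, 1]", {
  set.seed(71)
  n <- 400
  x <- draw_exposures(n)
  te <- data.frame(participant_id = sprintf("p%04d", 1:n),
                   true_vilpa_min_per_day_1min = x)
  cfg <- sim_config(n, baseline_hazards = c(cvd = 0.05, cancer = 0.05,
                                            other = 0.01))
  sv <- simulate_survival(te, NULL, cfg)
  dat <- data.frame(exposure = x, time_years = sv$time_years, cause = sv$cause)
  fit <- fit_fine_gray(dat, "exposure", cause = "cvd")
  fg <- fit$data
  expect_true(all(fg$fgwt > 0 & fg$fgwt <= 1))
  for (id in unique(fg$`(id)`)[1:50]) {
    w <- fg$fgwt[fg$`(id)` == id][order(fg$fgstart[fg$`(id)` == id])]
    expect_true(all(diff(w) <= 1e-12))
  }
})

test_that("Fine-Gray recovers a planted subdistribution effect", {
  # simulate directly from the subdistribution model:
  # F1(t|x) = 1 - (1 - p(1 - exp(-t)))^exp(b x)
  set.seed(72)
  n <- 4000; b <- -0.3; p <- 0.3
  x <- draw_exposures(n)
  pr1 <- 1 - (1 - p)^exp(b * x)
  is1 <- stats::runif(n) < pr1
  u <- stats::runif(n)
  t1 <- -log(1 - (1 - (1 - u * pr1)^(1 / exp(b * x))) / p)
  t2 <- stats::rexp(n, 0.8)
  time <- ifelse(is1, t1, t2)
  cens <- stats::runif(n, 0.5, 8)
  obs <- pmin(time, cens)
  cause <- ifelse(time > cens, "censored", ifelse(is1, "cvd", "cancer"))
  dat <- data.frame(exposure = x, time_years = obs, cause = cause)
  fit <- fit_fine_gray(dat, "exposure",
                       spec = new_spline_spec(c(0.5, 2.5, 6)), cause = "cvd")
  # curve slope at the linear term recovers b within 3 s.e.
  z <- (fit$coefficients["exp_lin"] - b) /
    sqrt(fit$covariance["exp_lin", "exp_lin"])
  expect_lt(abs(z), 3)
})

test_that("the Wald nonlinearity test is a squared z-score with 1 df and has power", {
  set.seed(80)
  dat <- sim_linear_cohort(1000, beta = -0.25, lambda0 = 0.06)
  fit <- fit_cox(dat, "exposure")
  w <- test_nonlinearity(fit)
  z <- fit$coefficients["exp_nl"] / sqrt(fit$covariance["exp_nl", "exp_nl"])
  expect_equal(w$statistic, unname(z^2), tolerance = 1e-10)
  expect_equal(w$df, 1)

  # strongly quadratic log hazard: decisive rejection at large n
  n <- 4000
  x <- draw_exposures(n, p_zero = 0)
  lp <- -0.08 * (x - 4)^2
  time <- stats::rexp(n, 0.05 * exp(lp))
  dq <- data.frame(exposure = x, time_years = pmin(time, 6.9),
                   cause = ifelse(time <= 6.9, "cvd", "censored"))
  fq <- fit_cox(dq, "exposure")
  expect_lt(test_nonlinearity(fq)$p_value, 0.001)
})

test_that("Schoenfeld PH test is calibrated under PH and detects a planted violation", {
  set.seed(90)
  dat <- sim_linear_cohort(1200, beta = -0.3, lambda0 = 0.05)
  fit <- fit_cox(dat, "exposure")
  ph <- test_proportional_hazards(fit)
  expect_true("GLOBAL" %in% ph$term)
  expect_equal(attr(ph, "n_residuals"), fit$n_events)

  # global p-values roughly uniform under proportional hazards
  ps <- vapply(1:60, function(i) {
    d <- sim_linear_cohort(500, beta = -0.2, lambda0 = 0.08)
    # occasional small replicates separate on the sparse spline tail;
    # their p-values still belong in the calibration sample
    f <- suppressWarnings(fit_cox(d, "exposure"))
    ph_i <- test_proportional_hazards(f)
    ph_i$p_value[ph_i$term == "GLOBAL"]
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)

  # planted time-varying effect: strong early effect that vanishes
  n <- 5000
  x <- draw_exposures(n, p_zero = 0)
  lam1 <- 0.12 * exp(-0.6 * x)   # effect active before t = 2
  t_a <- stats::rexp(n, lam1)
  t_b <- 2 + stats::rexp(n, 0.12)  # no effect after t = 2
  time <- ifelse(t_a < 2, t_a, t_b)
  dtv <- data.frame(exposure = x, time_years = pmin(time, 6.9),
                    cause = ifelse(time <= 6.9, "cvd", "censored"))
  ftv <- fit_cox(dtv, "exposure")
  ph_tv <- test_proportional_hazards(ftv)
  expect_lt(ph_tv$p_value[ph_tv$term == "GLOBAL"], 0.05)
})
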