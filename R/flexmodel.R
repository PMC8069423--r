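# Flexible parametric modelling of the cumulative excess mortality rate on
# the log-time scale (Royston-Parmar form), fitted by maximum likelihood
# against life-table expected mortality:
#
#   eta(t, x) = s(ln t; gamma) + A(age) beta + sum_j [A_j(age) * s_j(ln t; delta_j)]
#   Lambda_E  = exp(eta),   lambda_E = Lambda_E * (d eta / d ln t) / t
#   l_i       = d_i * ln(h*_i + lambda_E(t_i, x_i)) - Lambda_E(t_i, x_i)
#
# where h*_i is the expected hazard at the subject's exit. Age enters
# centred (at 70 y) and scaled to decades, optionally through a restricted
# cubic spline, and time-dependent age effects interact the age basis with
# a second time spline. The cure variant replaces every time basis by the
# backward construction (linear term excluded), making Lambda_E
# structurally constant beyond the last knot.

#' Model specification for the flexible excess-hazard model
#'
#' @param tier `"full"` (baseline 4 df, age 3 df restricted cubic spline,
#'   2 df time-dependent effect per age basis column), `"reduced"`
#'   (baseline 3 df, linear proportional age) or `"custom"` (take the df
#'   arguments as given).
#' @param baseline_df Degrees of freedom of the baseline log-time spline.
#' @param age_df Age effect: 0 = none, 1 = linear, >1 = restricted cubic
#'   spline with `age_df` columns.
#' @param td_df Degrees of freedom of the time-dependent interaction per
#'   age basis column (0 = proportional).
#' @param age_center,age_scale Age is transformed to
#'   `(age - age_center) / age_scale` before basis construction, purely
#'   for numerical conditioning; predictions undo this.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(tier = c("full", "reduced", "custom"),
                       baseline_df = NULL, age_df = NULL, td_df = NULL,
                       age_center = 70, age_scale = 10) {
  tier <- match.arg(tier)
  if (tier == "full") {
    if (is.null(baseline_df)) baseline_df <- 4L
    if (is.null(age_df)) age_df <- 3L
    if (is.null(td_df)) td_df <- 2L
  } else if (tier == "reduced") {
    if (is.null(baseline_df)) baseline_df <- 3L
    if (is.null(age_df)) age_df <- 1L
    if (is.null(td_df)) td_df <- 0L
  } else {
    if (is.null(baseline_df)) baseline_df <- 3L
    if (is.null(age_df)) age_df <- 0L
    if (is.null(td_df)) td_df <- 0L
  }
  if (baseline_df < 1L) stop("baseline_df must be >= 1")
  if (td_df > 0L && age_df == 0L)
    stop("time-dependent terms require an age effect")
  structure(list(tier = tier, baseline_df = as.integer(baseline_df),
                 age_df = as.integer(age_df), td_df = as.integer(td_df),
                 age_center = age_center, age_scale = age_scale),
            class = "model_spec")
}

# age basis (values only; age splines are not differentiated in time)
.age_basis <- function(age_spec, age_df, ac) {
  if (age_df == 0L) return(NULL)
  if (age_df == 1L) return(matrix(ac, ncol = 1L,
                                  dimnames = list(NULL, "age")))
  A <- rcs_basis(age_spec, ac)$b
  colnames(A) <- paste0("age", seq_len(ncol(A)))
  A
}

# Build the packed design for the likelihood: X (eta) and Xd (d eta/d u).
.excess_design_core <- function(u, age, spec, time_spec, td_spec, age_spec,
                                cure) {
  ac <- (age - spec$age_center) / spec$age_scale
  Tb <- rcs_basis(time_spec, u)
  A <- .age_basis(age_spec, spec$age_df, ac)
  X <- cbind(intercept = 1, Tb$b)
  Xd <- cbind(0, Tb$db)
  p_time <- ncol(Tb$b)
  colnames(X)[1L + seq_len(p_time)] <- paste0("time", seq_len(p_time))
  if (!is.null(A)) {
    X <- cbind(X, A)
    Xd <- cbind(Xd, matrix(0, nrow(X), ncol(A)))
    if (spec$td_df > 0L) {
      Td <- rcs_basis(td_spec, u)
      for (j in seq_len(ncol(A))) {
        blk <- Td$b * A[, j]
        blkd <- Td$db * A[, j]
        colnames(blk) <- paste0(colnames(A)[j], ":td", seq_len(ncol(blk)))
        X <- cbind(X, blk)
        Xd <- cbind(Xd, blkd)
      }
    }
  }
  colnames(Xd) <- colnames(X)
  list(X = X, Xd = Xd)
}

#' Build the estimation design for the excess-hazard likelihood
#'
#' Precomputes spline bases at each subject's exit time, the expected
#' hazard at exit, and the knot specifications reused for prediction.
#'
#' @param cohort Cohort data frame (`sex`, `age_at_diagnosis`,
#'   `diagnosis_date`, `time_years`, `status`).
#' @param lt A [life_table()].
#' @param spec A [model_spec()].
#' @param cure Logical; `TRUE` builds every time basis backward (cure
#'   constraint, linear term excluded).
#' @param time_knots Optional [spline_spec()] overriding the default
#'   baseline knot placement (e.g. for cohorts without enough events).
#' @return An object of class `excess_design`.
#' @export
build_excess_design <- function(cohort, lt, spec, cure = FALSE,
                                time_knots = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  t <- cohort$time_years
  d <- cohort$status
  if (any(t <= 0)) stop("all follow-up times must be > 0")
  u <- log(t)
  u_ev <- u[d == 1L]
  kind <- if (cure) "backward" else "standard"
  # backward basis with m columns needs m + 2 knots (no linear term)
  time_spec <- if (!is.null(time_knots)) time_knots else
    place_knots(u_ev, if (cure) spec$baseline_df + 1L else
      spec$baseline_df, kind = kind)
  td_spec <- NULL
  if (spec$td_df > 0L)
    td_spec <- place_knots(u_ev, if (cure) spec$td_df + 1L else spec$td_df,
                           kind = kind)
  age_spec <- NULL
  if (spec$age_df > 1L) {
    ac <- (cohort$age_at_diagnosis - spec$age_center) / spec$age_scale
    age_spec <- place_knots(ac, spec$age_df, kind = "standard")
  }
  core <- .excess_design_core(u, cohort$age_at_diagnosis, spec,
                              time_spec, td_spec, age_spec, cure)
  cn <- sqrt(colMeans(core$X^2))
  Xs <- sweep(core$X, 2L, pmax(cn, 1e-300), "/")
  if (qr(Xs)$rank < ncol(Xs))
    stop("design matrix is rank deficient (collinear columns)")
  y0 <- decimal_year(cohort$diagnosis_date)
  hstar <- expected_hazard(lt, cohort$sex, cohort$age_at_diagnosis + t,
                           y0 + t)
  cum <- vapply(seq_len(nrow(cohort)), function(i)
    expected_cum_hazard(lt, cohort$sex[i], cohort$age_at_diagnosis[i],
                        cohort$diagnosis_date[i], t[i])$cumhaz, numeric(1))
  structure(list(X = core$X, Xd = core$Xd, t = t, d = d, u = u,
                 hstar = hstar, expected_cumhaz = cum,
                 spec = spec, cure = cure,
                 time_spec = time_spec, td_spec = td_spec,
                 age_spec = age_spec,
                 age = cohort$age_at_diagnosis),
            class = "excess_design")
}

#' Log likelihood (and gradient) of the excess-hazard model
#'
#' Returns the log likelihood at packed coefficients `theta`, with the
#' analytic gradient as attribute `"gradient"`. Where the total hazard
#' `h* + lambda_E` is non-positive at an event, the log term is replaced
#' by a finite linear penalty below a small floor, so the optimizer never
#' sees a non-finite value.
#'
#' @param theta Packed coefficient vector (intercept, baseline spline,
#'   age, time-dependent interactions).
#' @param design An [build_excess_design()] object.
#' @return Scalar log likelihood with attribute `gradient`.
#' @export
excess_loglik <- function(theta, design) {
  X <- design$X; Xd <- design$Xd
  eta <- drop(X %*% theta)
  etad <- drop(Xd %*% theta)
  Lam <- exp(eta)
  lam <- Lam * etad / design$t
  total <- design$hstar + lam
  tiny <- 1e-8
  pen <- total < tiny
  logtot <- numeric(length(total))
  logtot[!pen] <- log(total[!pen])
  logtot[pen] <- log(tiny) + (total[pen] - tiny) / tiny
  ll <- sum(design$d * logtot) - sum(Lam)
  inv_tot <- ifelse(pen, 1 / tiny, 1 / total)
  wl <- design$d * inv_tot
  g <- drop(crossprod(X, wl * lam - Lam) +
              crossprod(Xd, wl * Lam / design$t))
  attr(ll, "gradient") <- g
  ll
}

# deterministic starting values: least squares of a crude target log
# cumulative excess hazard on the design at event times
.excess_start <- function(design) {
  d <- design$d; t <- design$t
  D <- sum(d)
  E <- sum(design$expected_cumhaz)
  r <- max((D - E) / sum(t), 1e-4)
  ev <- d == 1L
  if (design$cure) {
    tK <- exp(max(design$time_spec$knots))
    pi0 <- min(max(exp(-r * tK), 0.02), 0.95)
    lam0 <- max(stats::median(t[ev]), 0.1)
    target <- log(-log(pi0 + (1 - pi0) * exp(-t[ev] / lam0)))
  } else {
    target <- log(r) + log(t[ev])
  }
  Xev <- design$X[ev, , drop = FALSE]
  th <- tryCatch(qr.solve(qr(Xev, LAPACK = TRUE), target),
                 error = function(e) NULL)
  if (is.null(th) || any(!is.finite(th))) {
    th <- numeric(ncol(design$X))
    th[1L] <- log(max(r, 1e-4))
  }
  th
}

.fit_theta <- function(design, start) {
  negll <- function(th) -as.numeric(excess_loglik(th, design))
  neggr <- function(th) -attr(excess_loglik(th, design), "gradient")
  fit <- stats::nlminb(start, negll, neggr,
                       control = list(iter.max = 500, eval.max = 1000))
  scale <- max(1, abs(fit$objective))
  gmax <- max(abs(neggr(fit$par)))
  tries <- 0L
  while (gmax > 1e-5 * scale && tries < 3L) {
    polish <- stats::optim(fit$par, negll, neggr, method = "BFGS",
                           control = list(maxit = 500, reltol = 1e-12))
    if (polish$value <= fit$objective) fit$par <- polish$par
    fit$objective <- negll(fit$par)
    gmax <- max(abs(neggr(fit$par)))
    tries <- tries + 1L
  }
  if (gmax > 1e-3 * scale)
    stop(sprintf(paste("excess-hazard model did not converge",
                       "(max |gradient| %.3g at loglik %.4f)"),
                 gmax, -fit$objective))
  fit
}

#' Fit the flexible parametric excess-hazard model
#'
#' Maximum-likelihood fit of the log cumulative excess hazard spline model
#' against life-table expected mortality. Starting values are
#' deterministic (least squares of a crude excess-rate target on the
#' design, with richer models warm-started from the proportional nested
#' fit), so refitting the same data and spec reproduces the same result.
#'
#' @inheritParams build_excess_design
#' @return An object of class `excess_fit` (or `c("cure_fit",
#'   "excess_fit")` when `cure = TRUE`) with elements `theta`, `vcov`,
#'   `loglik`, `n_subjects`, `n_events`, and the design metadata needed
#'   for prediction.
#' @export
fit_excess_model <- function(cohort, lt, spec = model_spec("reduced"),
                             cure = FALSE) {
  design <- build_excess_design(cohort, lt, spec, cure = cure)
  start <- .excess_start(design)
  if (spec$td_df > 0L) {
    # warm start: proportional nested model first
    ph_spec <- spec; ph_spec$td_df <- 0L
    ph_design <- build_excess_design(cohort, lt, ph_spec, cure = cure)
    ph_fit <- .fit_theta(ph_design, .excess_start(ph_design))
    start <- numeric(ncol(design$X))
    start[seq_along(ph_fit$par)] <- ph_fit$par
  }
  fit <- .fit_theta(design, start)
  negll <- function(th) -as.numeric(excess_loglik(th, design))
  neggr <- function(th) -attr(excess_loglik(th, design), "gradient")
  H <- stats::optimHess(fit$par, negll, neggr)
  vcov <- tryCatch(solve(H), error = function(e) {
    warning("observed information singular; ridged inverse used")
    solve(H + diag(1e-8 * max(diag(H)), nrow(H)))
  })
  vcov <- (vcov + t(vcov)) / 2
  etad <- drop(design$Xd %*% fit$par)
  if (any(etad < -1e-8 & design$d == 1L) && !cure)
    warning("fitted cumulative excess hazard is non-monotone at some event times")
  out <- list(theta = fit$par, vcov = vcov, loglik = -fit$objective,
              n_subjects = nrow(cohort), n_events = sum(cohort$status),
              spec = spec, cure = cure,
              time_spec = design$time_spec, td_spec = design$td_spec,
              age_spec = design$age_spec,
              coef_names = colnames(design$X))
  class(out) <- if (cure) c("cure_fit", "excess_fit") else "excess_fit"
  out
}

#' @export
print.excess_fit <- function(x, ...) {
  cat(sprintf("%s excess-hazard model: %d coefficients, %d subjects, %d events\n",
              if (x$cure) "Cure-constrained flexible" else "Flexible",
              length(x$theta), x$n_subjects, x$n_events))
  cat(sprintf("log-likelihood %.3f; baseline knots (years): %s\n", x$loglik,
              paste(signif(exp(x$time_spec$knots), 4), collapse = ", ")))
  invisible(x)
}

# prediction design rows at (age_i, t_i) pairs (vectors of equal length)
.predict_design <- function(fit, age, t) {
  u <- log(t)
  .excess_design_core(u, age, fit$spec, fit$time_spec, fit$td_spec,
                      fit$age_spec, fit$cure)
}

#' Predict net survival with delta-method confidence intervals
#'
#' `NS = exp(-exp(eta))`; the 95% interval is computed on the log
#' cumulative excess hazard scale and back-transformed, so it always lies
#' inside (0, 1).
#'
#' @param fit An `excess_fit`.
#' @param age Age at diagnosis (scalar; ignored if the model has no age
#'   effect).
#' @param times Prediction times in years (> 0).
#' @param level Confidence level (default 0.95).
#' @return Data frame `time`, `ns`, `lo`, `hi`, `se_eta`.
#' @export
predict_ns <- function(fit, age = 70, times = c(1, 5, 10), level = 0.95) {
  stopifnot(all(times > 0), length(age) == 1L)
  dz <- .predict_design(fit, rep(age, length(times)), times)
  eta <- drop(dz$X %*% fit$theta)
  se <- sqrt(pmax(rowSums((dz$X %*% fit$vcov) * dz$X), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(time = times,
             ns = exp(-exp(eta)),
             lo = exp(-exp(eta + z * se)),
             hi = exp(-exp(eta - z * se)),
             se_eta = se)
}

#' Predict the excess mortality rate with confidence intervals
#'
#' `EMR = exp(eta) * (d eta / d ln t) / t` (deaths per person-year). The
#' interval is delta-method on `ln EMR` where the rate is positive;
#' regions with a negative fitted rate are flagged (`negative = TRUE`,
#' interval `NA`) rather than clipped.
#'
#' @inheritParams predict_ns
#' @return Data frame `time`, `emr`, `lo`, `hi`, `negative`.
#' @export
predict_emr <- function(fit, age = 70, times = c(1, 5, 10), level = 0.95) {
  stopifnot(all(times > 0), length(age) == 1L)
  dz <- .predict_design(fit, rep(age, length(times)), times)
  eta <- drop(dz$X %*% fit$theta)
  etad <- drop(dz$Xd %*% fit$theta)
  emr <- exp(eta) * etad / times
  pos <- etad > 0
  lo <- hi <- rep(NA_real_, length(times))
  if (any(pos)) {
    G <- dz$X[pos, , drop = FALSE] + dz$Xd[pos, , drop = FALSE] / etad[pos]
    se <- sqrt(pmax(rowSums((G %*% fit$vcov) * G), 0))
    z <- stats::qnorm(1 - (1 - level) / 2)
    lo[pos] <- emr[pos] * exp(-z * se)
    hi[pos] <- emr[pos] * exp(z * se)
  }
  data.frame(time = times, emr = emr, lo = lo, hi = hi, negative = !pos)
}

#' Marginal (all-ages) net survival
#'
#' Averages the individual predicted net survival over the covariate
#' distribution of the estimation cohort, with a delta-method standard
#' error for the average.
#'
#' @param fit An `excess_fit`.
#' @param cohort The estimation cohort (its `age_at_diagnosis` column is
#'   used).
#' @param times Prediction times in years.
#' @param level Confidence level.
#' @return Data frame `time`, `ns`, `lo`, `hi`, `se`.
#' @export
marginal_ns <- function(fit, cohort, times = c(1, 5, 10), level = 0.95) {
  ages <- cohort$age_at_diagnosis
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- lapply(times, function(tt) {
    dz <- .predict_design(fit, ages, rep(tt, length(ages)))
    eta <- drop(dz$X %*% fit$theta)
    nsi <- exp(-exp(eta))
    gbar <- colMeans(-nsi * exp(eta) * dz$X)
    se <- sqrt(max(drop(t(gbar) %*% fit$vcov %*% gbar), 0))
    m <- mean(nsi)
    data.frame(time = tt, ns = m,
               lo = max(m - z * se, 0), hi = min(m + z * se, 1), se = se)
  })
  do.call(rbind, out)
}
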