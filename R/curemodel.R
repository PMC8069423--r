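# Statistical-cure layer: the cure-assumption decision rule, the
# cure-constrained flexible model (backward time bases, fitted by
# fit_excess_model(cure = TRUE)), and the three cure indicators --
# cure proportion P, time to cure TTC, median survival of the uncured
# MedS -- with confidence intervals.

#' Fit the flexible parametric cure model
#'
#' Same likelihood as [fit_excess_model()], but every time basis is built
#' backward with the linear term excluded, so the cumulative excess hazard
#' is structurally constant at and beyond the last knot (the cure point
#' `t_K`). The cure fraction is then
#' `pi(x) = exp(-Lambda_E(t_K | x)) = exp(-exp(gamma_0 + A(age) beta))`,
#' a smooth function of the coefficients.
#'
#' @inheritParams fit_excess_model
#' @return A `cure_fit` object (also of class `excess_fit`).
#' @export
fit_cure_model <- function(cohort, lt, spec = model_spec("reduced")) {
  fit <- fit_excess_model(cohort, lt, spec, cure = TRUE)
  fit$t_cure <- exp(max(fit$time_spec$knots))
  fit
}

#' Cure point of a fitted cure model
#' @param fit A `cure_fit`.
#' @return The last knot on the time scale (years); the fitted cumulative
#'   excess hazard is constant beyond it.
#' @export
cure_point <- function(fit) {
  stopifnot(inherits(fit, "cure_fit"))
  exp(max(fit$time_spec$knots))
}

#' Cure proportion with delta-method confidence interval
#'
#' On the complementary-log-log scale the cure proportion is linear in the
#' coefficients, so the interval is computed there and back-transformed
#' (always inside (0, 1)).
#'
#' @param fit A `cure_fit`.
#' @param age Age at diagnosis (scalar).
#' @param level Confidence level.
#' @return List with `pi`, `lo`, `hi`, `se_cloglog`.
#' @export
cure_fraction <- function(fit, age = 70, level = 0.95) {
  stopifnot(inherits(fit, "cure_fit"))
  tK <- cure_point(fit)
  dz <- .predict_design(fit, age, tK)
  eta <- drop(dz$X %*% fit$theta)
  se <- sqrt(max(drop(dz$X %*% fit$vcov %*% t(dz$X)), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(pi = exp(-exp(eta)),
       lo = exp(-exp(eta + z * se)),
       hi = exp(-exp(eta - z * se)),
       se_cloglog = se)
}

# net survival R(t | age) under a model object (fitted cure model or
# exact simulation truth)
.net_surv <- function(object, age, t) {
  if (inherits(object, "cure_truth"))
    return(object$pi + (1 - object$pi) *
             exp(-(t / object$scale)^object$shape))
  dz <- .predict_design(object, rep(age, length(t)), t)
  exp(-exp(drop(dz$X %*% object$theta)))
}

.cure_pi <- function(object, age) {
  if (inherits(object, "cure_truth")) return(object$pi)
  cure_fraction(object, age)$pi
}

.cure_upper <- function(object, age) {
  if (inherits(object, "cure_truth")) {
    # expand bracket until the net survival is numerically at its plateau
    up <- object$scale
    while (.net_surv(object, age, up) > object$pi * 1.000001 + 1e-12 &&
           up < 1e6) up <- up * 2
    return(up)
  }
  cure_point(object)
}

#' Conditional probability of cure
#'
#' `P(t | x) = pi(x) / R(t | x)`: the probability that a patient alive (in
#' the net sense) at `t` belongs to the cured group. Non-decreasing in
#' `t`, equal to `pi` at `t = 0` and to 1 at and beyond the cure point.
#'
#' @param object A `cure_fit` or [cure_truth()] object.
#' @param age Age at diagnosis (scalar; ignored for truth objects).
#' @param t Times in years (`>= 0`).
#' @return Numeric vector of conditional cure probabilities.
#' @export
conditional_cure_prob <- function(object, age = 70, t = 0) {
  if (any(t < 0)) stop("t must be >= 0")
  p <- .cure_pi(object, age)
  r <- ifelse(t == 0, 1, .net_surv(object, age, pmax(t, 1e-12)))
  pmin(p / r, 1)
}

# scalar root search to 1e-6 years; f must change sign on (lo, hi)
.cure_root <- function(f, lo, hi) {
  stats::uniroot(f, c(lo, hi), tol = 1e-6)$root
}

# one draw-free indicator solve; threshold on P(t) for TTC
.solve_ttc <- function(object, age, threshold) {
  p <- .cure_pi(object, age)
  if (p >= threshold) return(0)
  if (p <= 0) return(Inf)
  up <- .cure_upper(object, age)
  f <- function(t) conditional_cure_prob(object, age, t) - threshold
  lo <- min(1e-6, up / 1e6)
  if (f(lo) >= 0) return(0)
  if (f(up) < 0) return(Inf)
  .cure_root(f, lo, up)
}

.solve_meds <- function(object, age) {
  p <- .cure_pi(object, age)
  if (p >= 1) stop("median survival of uncured undefined when pi = 1")
  up <- .cure_upper(object, age)
  f <- function(t) {
    r <- .net_surv(object, age, t)
    (r - p) / (1 - p) - 0.5
  }
  lo <- min(1e-6, up / 1e6)
  if (f(lo) < 0) return(lo * 12)
  .cure_root(f, lo, up) * 12
}

# parametric simulation of coefficient uncertainty: eigenvalue square root
# of vcov (robust to near-singularity), B standard-normal draws
.theta_draws <- function(fit, B) {
  eg <- eigen(fit$vcov, symmetric = TRUE)
  S <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  Z <- matrix(stats::rnorm(B * length(fit$theta)), B)
  sweep(Z %*% S, 2L, fit$theta, "+")
}

.with_theta <- function(fit, theta) { fit$theta <- theta; fit }

#' Time to cure
#'
#' The delay from diagnosis until the conditional probability of cure
#' `P(t)` first reaches the threshold (default 95%), found by bracketed
#' root search to 1e-6 years; 0 when `pi(x)` already meets the threshold.
#' For fitted models the confidence interval comes from parametric
#' simulation of the coefficients (`B` multivariate-normal draws,
#' percentile interval, truncated below at 0); draws consume the current
#' RNG stream, so set a seed for reproducible intervals.
#'
#' @param object A `cure_fit` or [cure_truth()].
#' @param age Age at diagnosis (scalar).
#' @param threshold Conditional-cure threshold (default 0.95).
#' @param B Number of coefficient draws for the interval (fitted models
#'   only; `B = 0` skips it).
#' @param level Confidence level.
#' @return List with `estimate` (years), `lo`, `hi`.
#' @export
time_to_cure <- function(object, age = 70, threshold = 0.95, B = 2000,
                         level = 0.95) {
  est <- .solve_ttc(object, age, threshold)
  lo <- hi <- NA_real_
  if (inherits(object, "cure_fit") && B > 0) {
    draws <- .theta_draws(object, B)
    vals <- apply(draws, 1L, function(th)
      .solve_ttc(.with_theta(object, th), age, threshold))
    qs <- stats::quantile(vals, c((1 - level) / 2, 1 - (1 - level) / 2),
                          na.rm = TRUE, names = FALSE)
    lo <- max(qs[1L], 0); hi <- qs[2L]
  }
  list(estimate = est, lo = lo, hi = hi)
}

#' Median survival of the uncured
#'
#' The time at which the net survival of the uncured subgroup,
#' `S_u(t) = (R(t) - pi) / (1 - pi)`, reaches 50%, reported in months.
#' `S_u` is exactly 0 at the cure point, so the root always exists for a
#' fitted cure model. Interval by the same parametric coefficient
#' simulation as [time_to_cure()].
#'
#' @inheritParams time_to_cure
#' @return List with `estimate` (months), `lo`, `hi`.
#' @export
median_surv_uncured <- function(object, age = 70, B = 2000, level = 0.95) {
  est <- .solve_meds(object, age)
  lo <- hi <- NA_real_
  if (inherits(object, "cure_fit") && B > 0) {
    draws <- .theta_draws(object, B)
    vals <- apply(draws, 1L, function(th)
      .solve_meds(.with_theta(object, th), age))
    qs <- stats::quantile(vals, c((1 - level) / 2, 1 - (1 - level) / 2),
                          na.rm = TRUE, names = FALSE)
    lo <- max(qs[1L], 0); hi <- qs[2L]
  }
  list(estimate = est, lo = lo, hi = hi)
}

#' Net survival / excess mortality curve of a fitted model
#'
#' Convenience evaluation of `NS(t)` and `EMR(t)` on a grid, in the form
#' consumed by [check_cure_assumption()].
#'
#' @param fit An `excess_fit`.
#' @param age Age at diagnosis (scalar).
#' @param times Evaluation grid.
#' @return Data frame `time`, `ns`, `emr`.
#' @export
ns_emr_curve <- function(fit, age = 70, times = seq(0.1, 10, by = 0.1)) {
  dz <- .predict_design(fit, rep(age, length(times)), times)
  eta <- drop(dz$X %*% fit$theta)
  etad <- drop(dz$Xd %*% fit$theta)
  data.frame(time = times, ns = exp(-exp(eta)),
             emr = exp(eta) * etad / times)
}

#' Cure-assumption decision rule
#'
#' Statistical cure is accepted for a stratum/age when the fitted net
#' survival curve reaches a plateau and the excess mortality rate
#' approaches zero within the horizon: the EMR must fall strictly below
#' `eps` (default 0.05 deaths per person-year) at some time `t_plateau`
#' and stay below it up to the horizon, and the net survival drop between
#' `t_plateau` and the horizon must not exceed 0.02 (the numeric
#' operationalisation of "reached a plateau").
#'
#' @param curve Data frame with columns `time`, `ns`, `emr` covering
#'   `(0, horizon]` (e.g. from [ns_emr_curve()] or a step-EMR benchmark).
#' @param horizon Decision horizon in years (default 10).
#' @param eps EMR threshold (strict inequality; exactly `eps` rejects).
#' @return List with `accepted` (TRUE/FALSE, or NA when the curve is too
#'   short to decide), `t_plateau` (first sub-`eps` time), `emr_horizon`,
#'   `ns_drop` (NS(horizon) - NS(t_plateau)).
#' @export
check_cure_assumption <- function(curve, horizon = 10, eps = 0.05) {
  stopifnot(all(c("time", "ns", "emr") %in% names(curve)))
  curve <- curve[order(curve$time), , drop = FALSE]
  if (max(curve$time) < horizon) {
    warning("curve does not reach the horizon; cure assumption undecidable")
    return(list(accepted = NA, t_plateau = NA_real_,
                emr_horizon = NA_real_, ns_drop = NA_real_))
  }
  win <- curve[curve$time <= horizon, , drop = FALSE]
  i_h <- nrow(win)
  below <- win$emr < eps
  if (!any(below))
    return(list(accepted = FALSE, t_plateau = NA_real_,
                emr_horizon = win$emr[i_h], ns_drop = NA_real_))
  i_p <- which(below)[1L]
  t_plateau <- win$time[i_p]
  sustained <- all(win$emr[i_p:i_h] < eps)
  ns_drop <- win$ns[i_h] - win$ns[i_p]
  list(accepted = sustained && ns_drop > -0.02,
       t_plateau = t_plateau, emr_horizon = win$emr[i_h], ns_drop = ns_drop)
}

#' Cure indicators for a set of ages
#'
#' Computes the cure proportion (percent), time to cure (years) and
#' median survival of the uncured (months), each with its confidence
#' interval, for the requested ages, sharing one set of coefficient draws
#' across indicators and ages.
#'
#' @param fit A `cure_fit`.
#' @param ages Ages at diagnosis.
#' @param threshold Conditional-cure threshold.
#' @param B Coefficient draws for the intervals.
#' @param level Confidence level.
#' @return Data frame: `age`, `p_pct`, `p_lo`, `p_hi`, `ttc_years`,
#'   `ttc_lo`, `ttc_hi`, `meds_months`, `meds_lo`, `meds_hi`.
#' @export
cure_indicators <- function(fit, ages = c(25, 50, 75), threshold = 0.95,
                            B = 2000, level = 0.95) {
  stopifnot(inherits(fit, "cure_fit"))
  draws <- if (B > 0) .theta_draws(fit, B) else NULL
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  rows <- lapply(ages, function(a) {
    cf <- cure_fraction(fit, a, level)
    ttc <- .solve_ttc(fit, a, threshold)
    meds <- .solve_meds(fit, a)
    ttc_ci <- meds_ci <- c(NA_real_, NA_real_)
    if (!is.null(draws)) {
      tv <- apply(draws, 1L, function(th)
        .solve_ttc(.with_theta(fit, th), a, threshold))
      mv <- apply(draws, 1L, function(th)
        .solve_meds(.with_theta(fit, th), a))
      ttc_ci <- pmax(stats::quantile(tv, probs, na.rm = TRUE, names = FALSE), 0)
      meds_ci <- pmax(stats::quantile(mv, probs, na.rm = TRUE, names = FALSE), 0)
    }
    data.frame(age = a,
               p_pct = 100 * cf$pi, p_lo = 100 * cf$lo, p_hi = 100 * cf$hi,
               ttc_years = ttc, ttc_lo = ttc_ci[1L], ttc_hi = ttc_ci[2L],
               meds_months = meds, meds_lo = meds_ci[1L],
               meds_hi = meds_ci[2L])
  })
  do.call(rbind, rows)
}
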