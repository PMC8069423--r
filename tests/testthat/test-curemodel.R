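# Cure model: decision rule, structural cure constraint, indicator
# solvers against closed-form truth, and recovery on simulated cohorts.

fit_cure_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      lt <- synthetic_life_table()
      s <- simulate_cohort(params_const_pi(2500, pi = 0.4, seed = 21), lt)
      cache <<- list(fit = fit_cure_model(s$cohort, lt,
                                          model_spec("custom", baseline_df = 4)),
                     cohort = s$cohort, lt = lt)
    }
    cache
  }
})

test_that("cure-assumption rule reproduces the threshold branches", {
  tgrid <- seq(0.1, 10, by = 0.1)
  flat_ns <- 0.5 - 0.001 * tgrid
  # EMR settles at 0.03 with a flat NS: accept
  a <- check_cure_assumption(data.frame(
    time = tgrid, ns = flat_ns, emr = pmax(0.03, 0.5 - 0.2 * tgrid)))
  expect_true(a$accepted)
  expect_equal(a$t_plateau, tgrid[which(pmax(0.03, 0.5 - 0.2 * tgrid) < 0.05)[1]])
  # EMR still 0.08 at 10 years: reject
  b <- check_cure_assumption(data.frame(
    time = tgrid, ns = flat_ns, emr = pmax(0.08, 0.5 - 0.2 * tgrid)))
  expect_false(b$accepted)
  # boundary: EMR exactly 0.05 never counts as below the threshold
  c1 <- check_cure_assumption(data.frame(
    time = tgrid, ns = flat_ns, emr = pmax(0.05, 0.5 - 0.2 * tgrid)))
  expect_false(c1$accepted)
  # dip below eps followed by a late rise: not sustained, reject
  d <- check_cure_assumption(data.frame(
    time = tgrid, ns = flat_ns, emr = 0.03 + 0.04 * (tgrid > 8)))
  expect_false(d$accepted)
  # a sagging NS (no plateau) rejects even with low EMR
  e <- check_cure_assumption(data.frame(
    time = tgrid, ns = 0.6 - 0.03 * tgrid, emr = rep(0.01, length(tgrid))))
  expect_false(e$accepted)
  expect_warning(
    f <- check_cure_assumption(data.frame(time = 1:5, ns = 1, emr = 0)),
    "undecidable")
  expect_true(is.na(f$accepted))
})

test_that("cure fraction is the inverse cloglog of the plateau intercept", {
  fx <- fit_cure_fixture()
  f <- fx$fit
  f$theta[] <- 0
  f$theta[1] <- log(-log(0.4))
  expect_equal(cure_fraction(f)$pi, 0.4, tolerance = 1e-12)
})

test_that("the fitted cumulative excess hazard is constant beyond the cure
           point for random coefficient draws", {
  fx <- fit_cure_fixture()
  fit <- fx$fit
  tK <- cure_point(fit)
  set.seed(3)
  draws <- amlcure:::.theta_draws(fit, 20)
  for (r in 1:20) {
    f <- fit
    f$theta <- draws[r, ]
    r1 <- amlcure:::.net_surv(f, 70, tK)
    r2 <- amlcure:::.net_surv(f, 70, c(tK + 1, tK + 5))
    expect_lt(max(abs(r2 - r1)), 1e-10)
  }
})

test_that("conditional cure probability follows the mixture closed form", {
  tr <- cure_truth(0.4, shape = 1, scale = 1)
  expect_equal(conditional_cure_prob(tr, t = 0), 0.4)
  expect_equal(conditional_cure_prob(tr, t = 1), 0.4 / (0.4 + 0.6 * exp(-1)),
               tolerance = 1e-12)
  # fitted model: P(0) = pi, P(t >= t_K) = 1
  fx <- fit_cure_fixture()
  expect_equal(conditional_cure_prob(fx$fit, 70, 0),
               cure_fraction(fx$fit, 70)$pi, tolerance = 1e-12)
  expect_equal(conditional_cure_prob(fx$fit, 70, cure_point(fx$fit) + 2), 1,
               tolerance = 1e-9)
})

test_that("time-to-cure solver matches the closed form and its limits", {
  expect_equal(time_to_cure(cure_truth(0.4))$estimate,
               -log(0.05 * 0.4 / (0.95 * 0.6)), tolerance = 1e-4)
  expect_equal(time_to_cure(cure_truth(0.96))$estimate, 0)
  # monotone: TTC non-increasing in pi for a fixed uncured distribution
  ttcs <- vapply(seq(0.05, 0.9, by = 0.05), function(p)
    time_to_cure(cure_truth(p))$estimate, numeric(1))
  expect_true(all(diff(ttcs) <= 1e-9))
})

test_that("median survival of the uncured matches Weibull closed forms", {
  expect_equal(median_surv_uncured(cure_truth(0.4))$estimate, 12 * log(2),
               tolerance = 1e-4)
  expect_equal(median_surv_uncured(cure_truth(0, shape = 2))$estimate,
               12 * sqrt(log(2)), tolerance = 1e-3)
  # with no cured fraction MedS is the median of overall net survival
  tr0 <- cure_truth(0, shape = 1.3, scale = 2)
  meds_y <- median_surv_uncured(tr0)$estimate / 12
  expect_equal(amlcure:::.net_surv(tr0, 70, meds_y), 0.5, tolerance = 1e-5)
})

test_that("structural invariants hold on a grid for random draws", {
  fx <- fit_cure_fixture()
  fit <- fx$fit
  tK <- cure_point(fit)
  tgrid <- seq(1e-3, tK, length.out = 1000)
  set.seed(8)
  draws <- amlcure:::.theta_draws(fit, 20)
  for (r in 1:20) {
    f <- fit
    f$theta <- draws[r, ]
    R <- amlcure:::.net_surv(f, 70, tgrid)
    p <- cure_fraction(f, 70)$pi
    expect_true(all(diff(R) <= 1e-10))
    expect_true(all(R >= p - 1e-10))
    P <- conditional_cure_prob(f, 70, tgrid)
    expect_true(all(diff(P) >= -1e-10))
    expect_lt(abs((R[1000] - p) / (1 - p)), 1e-9)    # S_u(t_K) = 0
  }
})

test_that("cure and flexible models agree on net survival when the cohort
           is generated with true cure", {
  fx <- fit_cure_fixture()
  flex <- suppressWarnings(fit_excess_model(
    fx$cohort, fx$lt, model_spec("custom", baseline_df = 4)))
  tgrid <- seq(0.25, 10, by = 0.25)
  ns_cure <- amlcure:::.net_surv(fx$fit, 70, tgrid)
  ns_flex <- predict_ns(flex, times = tgrid)$ns
  expect_lt(max(abs(ns_cure - ns_flex)), 0.02)
})

test_that("indicators and intervals are recovered on one simulated cohort", {
  fx <- fit_cure_fixture()
  set.seed(30)
  ind <- cure_indicators(fx$fit, ages = 70, B = 400)
  expect_gt(ind$p_pct, 30); expect_lt(ind$p_pct, 50)
  expect_true(ind$ttc_lo <= ind$ttc_years && ind$ttc_years <= ind$ttc_hi)
  expect_true(ind$meds_lo <= ind$meds_months &&
                ind$meds_months <= ind$meds_hi)
  expect_gte(ind$ttc_lo, 0)
})
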