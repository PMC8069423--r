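# Flexible parametric excess-hazard model: likelihood values, gradient,
# recovery against closed forms, nesting, predictions, and agreement with
# an independent implementation of the same model.

make_fit <- function(n = 800, pi = 0, shape = 1, scale = 2, seed = 5,
                     spec = model_spec("custom", baseline_df = 3),
                     lt = synthetic_life_table()) {
  s <- simulate_cohort(params_const_pi(n, pi, shape, scale, seed), lt)
  list(fit = suppressWarnings(fit_excess_model(s$cohort, lt, spec)),
       cohort = s$cohort, lt = lt)
}

test_that("likelihood matches the closed form when eta = ln t", {
  lt0 <- flat_life_table(0)
  co <- data.frame(sex = "male", age_at_diagnosis = 70,
                   diagnosis_date = as.Date("2000-01-01"),
                   time_years = c(1, 2), status = 1L)
  des <- build_excess_design(co, lt0, model_spec("custom", baseline_df = 1))
  # theta = (0, 1): eta = u, Lambda_E = t, lambda_E = 1
  # l = [ln 1 - 1] + [ln 1 - 2] = -3
  expect_equal(as.numeric(excess_loglik(c(0, 1), des)), -3, tolerance = 1e-12)
})

test_that("with all subjects censored the likelihood rises to 0 as the
           excess hazard vanishes", {
  lt0 <- flat_life_table(0)
  co <- data.frame(sex = "male", age_at_diagnosis = 70,
                   diagnosis_date = as.Date("2000-01-01"),
                   time_years = c(1, 2, 3), status = 0L)
  des <- build_excess_design(
    co, lt0, model_spec("custom", baseline_df = 1),
    time_knots = spline_spec(c(log(0.5), log(3))))
  lls <- vapply(c(-2, -5, -10, -20), function(ic)
    as.numeric(excess_loglik(c(ic, 1), des)), numeric(1))
  expect_true(all(diff(lls) > 0))
  expect_lt(abs(lls[4]), 1e-6)
})

test_that("analytic gradient matches central differences on the full model", {
  lt <- synthetic_life_table()
  s <- simulate_cohort(sim_params(n = 500, weibull_scale = 1.5, seed = 5), lt)
  des <- build_excess_design(s$cohort, lt, model_spec("full"))
  start <- amlcure:::.excess_start(des)
  cn <- pmax(sqrt(colMeans(des$X^2)), 1)
  set.seed(1)
  for (r in 1:20) {
    th <- start + rnorm(length(start), 0, 0.05) / cn
    g <- attr(excess_loglik(th, des), "gradient")
    gn <- vapply(seq_along(th), function(j) {
      h <- 1e-6 / cn[j]
      e <- replace(numeric(length(th)), j, h)
      (as.numeric(excess_loglik(th + e, des)) -
          as.numeric(excess_loglik(th - e, des))) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(g - gn) / pmax(1, abs(gn))), 1e-5)
  }
})

test_that("an exponential excess hazard is recovered", {
  m <- make_fit(n = 2000, pi = 0, shape = 1, scale = 2, seed = 12,
                lt = flat_life_table(0.005))
  pr <- predict_ns(m$fit, times = 1)
  se_ns <- (pr$hi - pr$lo) / (2 * qnorm(0.975))
  expect_lt(abs(pr$ns - exp(-0.5)), 3 * se_ns)
})

test_that("a cohort with no excess mortality predicts net survival near 1", {
  lt <- synthetic_life_table()
  s <- simulate_cohort(sim_params(n = 2000, cure_intercept = -20,
                                  cure_age_coef = 0, cure_male_coef = 0,
                                  seed = 13), lt)
  fit <- suppressWarnings(
    fit_excess_model(s$cohort, lt, model_spec("custom", baseline_df = 2)))
  pr <- predict_ns(fit, times = 5)
  se_ns <- (pr$hi - pr$lo) / (2 * qnorm(0.975))
  expect_lt(abs(pr$ns - 1), 3 * se_ns + 0.01)
})

test_that("padding a proportional fit with zero time-dependent terms leaves
           the likelihood unchanged", {
  lt <- synthetic_life_table()
  s <- simulate_cohort(sim_params(n = 400, seed = 14), lt)
  spec_ph <- model_spec("custom", baseline_df = 3, age_df = 2, td_df = 0)
  spec_td <- model_spec("custom", baseline_df = 3, age_df = 2, td_df = 2)
  des_ph <- build_excess_design(s$cohort, lt, spec_ph)
  des_td <- build_excess_design(s$cohort, lt, spec_td)
  th <- amlcure:::.excess_start(des_ph)
  th_pad <- c(th, numeric(ncol(des_td$X) - length(th)))
  expect_equal(as.numeric(excess_loglik(th_pad, des_td)),
               as.numeric(excess_loglik(th, des_ph)), tolerance = 1e-6)
})

test_that("a duplicated covariate column is rejected at design build", {
  lt <- synthetic_life_table()
  s <- simulate_cohort(sim_params(n = 300, age_sd = 0, seed = 15), lt)
  # exactly constant age degenerates the centred age column
  expect_error(
    build_excess_design(s$cohort, lt,
                        model_spec("custom", baseline_df = 2, age_df = 1)),
    "rank deficient")
})

test_that("predictions transform eta correctly and stay inside (0,1)", {
  m <- make_fit(n = 400, seed = 16)
  fit0 <- m$fit
  fit0$theta[] <- 0                       # eta identically 0
  expect_equal(predict_ns(fit0, times = 1)$ns, exp(-1), tolerance = 1e-12)
  set.seed(2)
  draws <- amlcure:::.theta_draws(m$fit, 100)
  for (r in 1:100) {
    f <- m$fit
    f$theta <- m$fit$theta + 2 * (draws[r, ] - m$fit$theta)
    pr <- predict_ns(f, times = c(0.5, 2, 8))
    expect_true(all(pr$lo > 0 & pr$hi < 1 & pr$lo <= pr$hi))
  }
})

test_that("EMR predictions match the unit-hazard model and flag negativity", {
  m <- make_fit(n = 400, seed = 17)
  fit0 <- m$fit
  # eta = u: Lambda = t, EMR = 1 at all t
  fit0$theta[] <- 0
  fit0$theta[1:2] <- c(0, 1)
  pr <- predict_emr(fit0, times = c(0.5, 1, 3))
  expect_equal(pr$emr, rep(1, 3), tolerance = 1e-12)
  expect_false(any(pr$negative))
  # decreasing eta flags a negative excess hazard rather than clipping
  fit0$theta[2] <- -1
  pr <- predict_emr(fit0, times = 1)
  expect_true(pr$negative && pr$emr < 0 && is.na(pr$lo))
})

test_that("marginal net survival averages individual predictions", {
  lt <- synthetic_life_table()
  s <- simulate_cohort(sim_params(n = 500, seed = 18), lt)
  fit <- suppressWarnings(fit_excess_model(
    s$cohort, lt, model_spec("custom", baseline_df = 3, age_df = 2)))
  one <- s$cohort[7, , drop = FALSE]
  expect_equal(marginal_ns(fit, one, times = 5)$ns,
               predict_ns(fit, one$age_at_diagnosis, times = 5)$ns,
               tolerance = 1e-12)
  two <- s$cohort[c(7, 300), , drop = FALSE]
  expect_equal(marginal_ns(fit, two, times = 5)$ns,
               mean(vapply(two$age_at_diagnosis, function(a)
                 predict_ns(fit, a, times = 5)$ns, numeric(1))),
               tolerance = 1e-12)
})

test_that("the fit agrees with an independent implementation of the same
           model (flexsurv, expected-hazard offset)", {
  skip_if_not_installed("flexsurv")
  m <- make_fit(n = 800, pi = 0, shape = 0.9, scale = 1.5, seed = 5)
  co <- m$cohort; lt <- m$lt; fit <- m$fit
  y0 <- decimal_year(co$diagnosis_date)
  bh <- expected_hazard(lt, co$sex, co$age_at_diagnosis + co$time_years,
                        y0 + co$time_years)
  k <- fit$time_spec$knots
  fs <- flexsurv::flexsurvspline(
    survival::Surv(time_years, status) ~ 1, data = co, bhazard = bh,
    knots = k[-c(1, length(k))], bknots = k[c(1, length(k))])
  expect_equal(fit$loglik, fs$loglik, tolerance = 1e-6)
  tt <- c(0.5, 1, 2, 5, 9)
  fsv <- summary(fs, t = tt, type = "survival", ci = FALSE)[[1]]$est
  expect_lt(max(abs(predict_ns(fit, times = tt)$ns - fsv)), 1e-4)
})

test_that("net survival at 5 years is estimated without bias and with
           nominal interval coverage across replicates", {
  lt <- synthetic_life_table()
  truth5 <- exp(-(5 / 2)^0.8)
  res <- vapply(1:50, function(i) {
    s <- simulate_cohort(params_const_pi(2000, 0, shape = 0.8, scale = 2,
                                         seed = 500 + i), lt)
    fit <- suppressWarnings(
      fit_excess_model(s$cohort, lt, model_spec("custom", baseline_df = 3)))
    pr <- predict_ns(fit, times = 5)
    c(err = pr$ns - truth5, cover = pr$lo <= truth5 && truth5 <= pr$hi)
  }, numeric(2))
  expect_lt(abs(mean(res["err", ])), 0.01)
  cov <- mean(res["cover", ])
  expect_gte(cov, 0.92)
  expect_lte(cov, 0.98)
})
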