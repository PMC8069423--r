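# Registry-like cohort simulation with known net-survival and cure truth.
#
# The generating model is a classical mixture-cure process on top of
# life-table background mortality: each patient is cured with probability
# pi(x) (inverse complementary-log-log of a linear predictor in age and
# sex); uncured patients draw an excess (disease-related) death time from a
# Weibull distribution; everyone draws an independent background death time
# from the life table; the observed time is the earliest of excess death,
# background death and censoring. Cause of exit is recorded in a separate
# truth table only — estimators never see it, which is the net-survival
# setting.

#' Simulation parameters for a synthetic registry cohort
#'
#' Defaults emulate a French AML registry cohort: diagnoses 1995--2015,
#' vital status followed to the earlier of 10 years after diagnosis and an
#' administrative cutoff of 2018-06-30, loss to follow-up below 1%, ages
#' truncated-normal with support starting at 15 years (registry inclusion
#' age), a slight male excess, and a cure fraction declining with age.
#'
#' @param n Cohort size.
#' @param age_mean,age_sd,age_min,age_max Truncated-normal age-at-diagnosis
#'   distribution (years).
#' @param male_prob Probability of male sex.
#' @param date_start,date_end Diagnosis-date window (uniform).
#' @param cure_intercept Intercept of the cloglog-scale linear predictor:
#'   `pi(x) = exp(-exp(eta))`, `eta = cure_intercept +
#'   cure_age_coef * (age - 70)/10 + cure_male_coef * I(male)`. The default
#'   intercept gives `pi = 0.4` at the reference (age 70).
#' @param cure_age_coef Cure log-log slope per decade of age (positive
#'   means older patients are less often cured).
#' @param cure_male_coef Male contrast on the same scale.
#' @param weibull_shape,weibull_scale Weibull excess-time distribution of
#'   uncured patients (scale in years).
#' @param ltfu_prob Probability of loss to follow-up (uniform censoring
#'   over the administrative follow-up window).
#' @param cutoff Administrative cutoff date.
#' @param cap Follow-up cap in years.
#' @param stratum Stratum label stamped on every record.
#' @param seed Integer seed; `simulate_cohort()` is reproducible given it.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n = 1000,
                       age_mean = 70, age_sd = 13, age_min = 15, age_max = 95,
                       male_prob = 0.53,
                       date_start = as.Date("1995-01-01"),
                       date_end = as.Date("2015-12-31"),
                       cure_intercept = log(-log(0.4)),
                       cure_age_coef = 0.25,
                       cure_male_coef = 0.1,
                       weibull_shape = 1, weibull_scale = 1,
                       ltfu_prob = 0.005,
                       cutoff = as.Date("2018-06-30"),
                       cap = 10,
                       stratum = "SIM",
                       seed = 1L) {
  p <- as.list(environment())
  if (p$n < 1) stop("n must be >= 1")
  if (p$weibull_shape <= 0 || p$weibull_scale <= 0)
    stop("Weibull shape and scale must be > 0")
  if (p$cap <= 0) stop("follow-up cap must be > 0")
  if (p$ltfu_prob < 0 || p$ltfu_prob >= 1) stop("ltfu_prob must be in [0,1)")
  if (p$age_min < 15) stop("inclusion requires age >= 15")
  class(p) <- "sim_params"
  p
}

# cloglog-scale linear predictor -> cure probability
.sim_pi <- function(params, age, male) {
  eta <- params$cure_intercept +
    params$cure_age_coef * (age - 70) / 10 +
    params$cure_male_coef * as.numeric(male)
  exp(-exp(eta))
}

#' Simulate a registry cohort with known cure truth
#'
#' @param params A [sim_params()] object.
#' @param lt A [life_table()] covering the simulated sexes, ages and years.
#' @return A list with elements `cohort` (data frame: `id`, `sex`,
#'   `age_at_diagnosis`, `diagnosis_date`, `stratum`, `time_years`,
#'   `status` 0/1), `truth` (per-subject latent state: cured flag, latent
#'   background/excess times, cause of exit) and `params`. The truth table
#'   is deliberately separate so estimators cannot read it accidentally.
#' @export
simulate_cohort <- function(params, lt) {
  stopifnot(inherits(params, "sim_params"), inherits(lt, "life_table"))
  set.seed(params$seed)
  n <- params$n
  # truncated normal ages by inverse transform
  plo <- stats::pnorm(params$age_min, params$age_mean, params$age_sd)
  phi <- stats::pnorm(params$age_max, params$age_mean, params$age_sd)
  age <- stats::qnorm(stats::runif(n, plo, phi), params$age_mean, params$age_sd)
  male <- stats::runif(n) < params$male_prob
  sex <- ifelse(male, "male", "female")
  span <- as.numeric(params$date_end - params$date_start)
  date_dx <- params$date_start + round(stats::runif(n, 0, span))
  pi_x <- .sim_pi(params, age, male)
  cured <- stats::runif(n) < pi_x
  t_exc <- ifelse(cured, Inf,
                  stats::rweibull(n, shape = params$weibull_shape,
                                  scale = params$weibull_scale))
  e_bg <- stats::rexp(n)
  t_bg <- vapply(seq_len(n), function(i)
    .lt_sample_background(lt, sex[i], age[i], date_dx[i], e_bg[i]), numeric(1))
  admin <- pmin(params$cap,
                as.numeric(params$cutoff - date_dx) / 365.25)
  t_cens <- admin
  ltfu <- stats::runif(n) < params$ltfu_prob
  t_cens[ltfu] <- stats::runif(sum(ltfu), 0, admin[ltfu])
  t_death <- pmin(t_exc, t_bg)
  time <- pmin(t_death, t_cens)
  status <- as.integer(t_death <= t_cens)
  # registry follow-up is date arithmetic: day resolution, minimum one day
  time <- pmax(round(time * 365.25) / 365.25, 1 / 365.25)
  cause <- ifelse(status == 0L, "censored",
                  ifelse(t_exc <= t_bg, "excess", "background"))
  cohort <- data.frame(
    id = seq_len(n), sex = sex, age_at_diagnosis = age,
    diagnosis_date = date_dx, stratum = params$stratum,
    time_years = time, status = status, stringsAsFactors = FALSE)
  truth <- data.frame(
    id = seq_len(n), cured = cured, pi = pi_x,
    t_background = t_bg, t_excess = t_exc, cause = cause,
    stringsAsFactors = FALSE)
  list(cohort = cohort, truth = truth, params = params)
}

#' Closed-form net survival of the generating mixture-cure process
#'
#' \eqn{R(t|x) = \pi(x) + (1-\pi(x)) \exp(-(t/\lambda)^k)}.
#'
#' @param params A [sim_params()].
#' @param age,male Covariate profile (scalar age; `male` logical).
#' @param t Times in years.
#' @return Numeric vector of net survival values.
#' @export
truth_net_survival <- function(params, age, male, t) {
  if (any(t < 0)) stop("t must be >= 0")
  p <- .sim_pi(params, age, male)
  p + (1 - p) * exp(-(t / params$weibull_scale)^params$weibull_shape)
}

#' Closed-form cure indicators of the generating process
#'
#' Exact oracles for the three cure indicators under the mixture-cure
#' truth: cure proportion \eqn{\pi(x)}; time to cure, the first time the
#' conditional probability of cure \eqn{P(t) = \pi/R(t)} reaches the
#' threshold (0 when \eqn{\pi \ge} threshold, infinite when the plateau
#' never reaches it); and the median survival of the uncured, the Weibull
#' median \eqn{\lambda (\ln 2)^{1/k}}, in months.
#'
#' @inheritParams truth_net_survival
#' @param threshold Conditional-cure threshold (default 0.95).
#' @return A list with `pi`, `ttc_years`, `meds_months`.
#' @export
truth_cure_indicators <- function(params, age, male, threshold = 0.95) {
  p <- .sim_pi(params, age, male)
  k <- params$weibull_shape; lam <- params$weibull_scale
  if (p >= threshold) {
    ttc <- 0
  } else {
    # P(t) = threshold  <=>  S_u(t) = (1-threshold) p / (threshold (1-p))
    q <- (1 - threshold) * p / (threshold * (1 - p))
    ttc <- lam * (-log(q))^(1 / k)
  }
  meds <- lam * log(2)^(1 / k) * 12
  list(pi = p, ttc_years = ttc, meds_months = meds)
}

#' Exact mixture-cure truth as a cure-model-like object
#'
#' Wraps the generating parameters so the generic cure-indicator solvers
#' ([time_to_cure()], [median_surv_uncured()], [conditional_cure_prob()])
#' can run against the exact closed-form model instead of a fitted one.
#'
#' @param pi Cure fraction in (0, 1).
#' @param shape,scale Weibull parameters of the uncured excess-time
#'   distribution.
#' @return An object of class `cure_truth`.
#' @export
cure_truth <- function(pi, shape = 1, scale = 1) {
  stopifnot(pi >= 0, pi < 1, shape > 0, scale > 0)
  structure(list(pi = pi, shape = shape, scale = scale),
            class = "cure_truth")
}

#' Synthetic period life table with Gompertz age structure
#'
#' A smooth stand-in for a national all-cause period life table:
#' `rate = a * exp(b * age)` with a modest female advantage and a slow
#' secular decline, capped at 0.7/year. Used by simulations and worked
#' examples; it reproduces the broad shape of adult background mortality,
#' not any particular country's table.
#'
#' @param ages,years Grid (defaults 0--110, 1990--2020).
#' @param a,b Gompertz level and slope.
#' @param female_factor Multiplier on female rates.
#' @param annual_decline Multiplicative decline per calendar year after
#'   2005.
#' @return A [life_table()] with sexes `male`, `female`.
#' @export
synthetic_life_table <- function(ages = 0:110, years = 1990:2020,
                                 a = 5e-5, b = 0.095,
                                 female_factor = 0.55,
                                 annual_decline = 0.997) {
  grid <- expand.grid(sex = c("female", "male"), age = ages, year = years,
                      stringsAsFactors = FALSE)
  base <- a * exp(b * grid$age) * annual_decline^(grid$year - 2005)
  base[grid$sex == "female"] <- base[grid$sex == "female"] * female_factor
  grid$rate <- pmin(base, 0.7)
  life_table(grid)
}

#' Write a simulated cohort, its truth and a run manifest to CSV
#'
#' @param sim Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("cohort.csv", "truth.csv", "manifest.csv"))
  utils::write.csv(sim$cohort, paths[1L], row.names = FALSE)
  utils::write.csv(sim$truth, paths[2L], row.names = FALSE)
  p <- sim$params
  manifest <- data.frame(param = names(p),
                         value = vapply(p, function(v) paste(format(v), collapse = ";"),
                                        character(1)))
  utils::write.csv(manifest, paths[3L], row.names = FALSE)
  invisible(paths)
}

#' Read a cohort CSV written by [write_cohort()]
#'
#' @param path Path to the cohort CSV.
#' @return Cohort data frame with `diagnosis_date` parsed as `Date`.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "sex", "age_at_diagnosis", "diagnosis_date", "stratum",
            "time_years", "status")
  if (!all(need %in% names(df)))
    stop("cohort file must have columns: ", paste(need, collapse = ", "))
  df$diagnosis_date <- as.Date(df$diagnosis_date)
  df
}
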