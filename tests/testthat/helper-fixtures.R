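# Shared fixtures: small life tables and mixture-cure simulation presets.

# constant-hazard life table over both sexes
flat_life_table <- function(rate, ages = 0:110, years = 1990:2025) {
  grid <- expand.grid(sex = c("female", "male"), age = ages, year = years,
                      stringsAsFactors = FALSE)
  grid$rate <- rate
  life_table(grid)
}

# simulation preset with a constant cure fraction pi (no age/sex effect);
# pi = 0 is approximated by a large cloglog intercept
params_const_pi <- function(n, pi, shape = 1, scale = 1, seed = 1,
                            ...) {
  ic <- if (pi <= 0) 10 else log(-log(pi))
  sim_params(n = n, cure_intercept = ic, cure_age_coef = 0,
             cure_male_coef = 0, weibull_shape = shape,
             weibull_scale = scale, seed = seed, ...)
}

# homogeneous-age preset: isolates the baseline time course
params_homog <- function(n, pi, shape = 1, scale = 1, seed = 1, age = 65,
                         ...) {
  params_const_pi(n, pi, shape, scale, seed,
                  age_mean = age, age_sd = 0.01, ...)
}
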