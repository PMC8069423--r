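# Life-table reading, lookup clamping and exact trajectory integration.

test_that("a single long_csv row expands to a constant table under nearest fill", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sex,age,year,rate", "male,60,2000,0.02"), f)
  lt <- read_life_table(f, "long_csv", ages = 15:100, years = 1990:2020,
                        fill = "nearest")
  expect_equal(unname(range(lt$rate)), c(0.02, 0.02))
  ch <- expected_cum_hazard(lt, "male", 60, as.Date("2000-06-01"), c(0, 5))
  expect_equal(ch$cumhaz, c(0, 0.1))
  expect_equal(ch$surv, c(1, exp(-0.1)))
})

test_that("hmd_period dialect clamps the open 110+ age group to one row", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Year Age mx",
               paste(2000, 0:109, 0.01),
               "2000 110+ 0.5"), f)
  lt <- read_life_table(f, "hmd_period", sex = "female")
  expect_equal(max(lt$ages), 110)
  expect_equal(unname(lt$rate["female", "110", "2000"]), 0.5)
  # clamping: ages beyond the top row reuse it
  expect_equal(expected_hazard(lt, "female", 118, 2000), 0.5)
  expect_equal(expected_hazard(lt, "female", 118, 2035), 0.5)
})

test_that("missing cells and negative rates are hard errors naming the cell", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- expand.grid(sex = "female", age = 69:71, year = 2004:2006,
                    stringsAsFactors = FALSE)
  df$rate <- 0.01
  write.csv(df[!(df$age == 70 & df$year == 2005), ], f, row.names = FALSE)
  expect_error(read_life_table(f, "long_csv"),
               "sex=female, age=70, year=2005")
  df$rate[1] <- -0.01
  write.csv(df, f, row.names = FALSE)
  expect_error(read_life_table(f, "long_csv"), "finite and >= 0")
})

test_that("integration splits exactly at integer attained-age boundaries", {
  grid <- expand.grid(sex = "male", age = 15:100, year = 1995:2005,
                      stringsAsFactors = FALSE)
  grid$rate <- ifelse(grid$age <= 60, 0.01, 0.03)
  lt <- life_table(grid)
  # diagnosis at exact age 60: one year at 0.01, one at 0.03
  ch <- expected_cum_hazard(lt, "male", 60, as.Date("2000-01-01"), 2)
  expect_equal(ch$cumhaz, 0.04, tolerance = 1e-10)
  # fractional age: 0.5 y at 0.01 then 1.5 y at 0.03
  ch <- expected_cum_hazard(lt, "male", 60.5, as.Date("2000-01-01"), 2)
  expect_equal(ch$cumhaz, 0.5 * 0.01 + 1.5 * 0.03, tolerance = 1e-10)
  expect_error(expected_cum_hazard(lt, "male", 60, as.Date("2000-01-01"), -1),
               ">= 0")
})

test_that("cumulative hazard matches independent segment-sum quadrature", {
  lt <- synthetic_life_table()
  age0 <- 63.37
  d0 <- as.Date("2003-04-17")
  y0 <- decimal_year(d0)
  ts <- seq(0, 10, length.out = 1000)
  got <- expected_cum_hazard(lt, "female", age0, d0, ts)
  # independent oracle: split [0, t] at all integer age/year crossings and
  # sum rate * length with midpoint lookups
  oracle_one <- function(t) {
    if (t == 0) return(0)
    cuts <- sort(unique(c(
      t,
      (ceiling(age0) - age0) + 0:ceiling(t),
      (ceiling(y0) - y0) + 0:ceiling(t))))
    cuts <- cuts[cuts > 0 & cuts <= t]
    lo <- c(0, head(cuts, -1))
    mid <- (lo + cuts) / 2
    sum(expected_hazard(lt, "female", age0 + mid, y0 + mid) * (cuts - lo))
  }
  exp_ch <- vapply(ts, oracle_one, numeric(1))
  expect_lt(max(abs(got$cumhaz - exp_ch)), 1e-8)
  expect_true(all(diff(got$cumhaz) >= 0))
  expect_equal(got$surv, exp(-got$cumhaz))
})

test_that("background death-time sampling inverts the cumulative hazard", {
  lt <- flat_life_table(0.05)
  e <- c(0.01, 0.1, 1, 3)
  t <- amlcure:::.lt_sample_background(lt, "male", 70, as.Date("2000-01-01"), e)
  expect_equal(t, e / 0.05, tolerance = 1e-9)
  # zero hazard: never dies within the horizon
  lt0 <- flat_life_table(0)
  expect_equal(
    amlcure:::.lt_sample_background(lt0, "male", 70, as.Date("2000-01-01"), 1),
    Inf)
})
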