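# Population life tables: expected (background) mortality surfaces indexed by
# sex, attained age (integer years) and calendar year, with exact
# piecewise-constant integration along a patient's follow-up trajectory.

#' Construct a population life table
#'
#' A life table stores the expected mortality hazard (per person-year) of the
#' general population on a grid of sex, integer age and calendar year. It is
#' the reference surface from which expected survival and expected cumulative
#' hazard are computed in all net-survival estimators of this package.
#'
#' @param rate A 3-dimensional numeric array of hazards with dimensions
#'   (sex, age, year), or a long data frame with columns `sex`, `age`,
#'   `year`, `rate` covering every cell of the implied grid.
#' @param sexes Character vector of sex labels (dimension 1), ignored when
#'   `rate` is a data frame.
#' @param ages Integer vector of ages, contiguous with step 1.
#' @param years Integer vector of calendar years, contiguous with step 1.
#'
#' @return An object of class `life_table` with elements `rate` (array),
#'   `sexes`, `ages`, `years`.
#'
#' @details All rates must be finite and non-negative, and every
#'   (sex, age, year) cell of the declared grid must be present; a missing
#'   cell is a hard error naming the first absent combination. Lookups for
#'   ages or years outside the grid are clamped to the nearest boundary row,
#'   the standard registry convention for very old patients and long
#'   follow-up.
#'
#' @examples
#' lt <- life_table(array(0.02, dim = c(1, 86, 31),
#'                        dimnames = list("male", 15:100, 1990:2020)),
#'                  sexes = "male", ages = 15:100, years = 1990:2020)
#' expected_cum_hazard(lt, sex = "male", age_dx = 60,
#'                     date_dx = as.Date("2000-06-01"), t = 5)
#' @export
life_table <- function(rate, sexes = NULL, ages = NULL, years = NULL) {
  if (is.data.frame(rate)) {
    need <- c("sex", "age", "year", "rate")
    if (!all(need %in% names(rate)))
      stop("life-table data frame needs columns sex, age, year, rate")
    df <- rate
    sexes <- sort(unique(as.character(df$sex)))
    ages <- sort(unique(as.integer(df$age)))
    years <- sort(unique(as.integer(df$year)))
    arr <- array(NA_real_, dim = c(length(sexes), length(ages), length(years)),
                 dimnames = list(sexes, ages, years))
    arr[cbind(match(as.character(df$sex), sexes),
              match(as.integer(df$age), ages),
              match(as.integer(df$year), years))] <- df$rate
    rate <- arr
  } else {
    if (is.null(sexes) || is.null(ages) || is.null(years))
      stop("sexes, ages and years must be given with an array rate")
    dimnames(rate) <- list(sexes, ages, years)
  }
  ages <- as.integer(ages); years <- as.integer(years)
  if (length(ages) > 1L && any(diff(ages) != 1L))
    stop("age grid must be contiguous with step 1")
  if (length(years) > 1L && any(diff(years) != 1L))
    stop("year grid must be contiguous with step 1")
  miss <- which(is.na(rate), arr.ind = TRUE)
  if (nrow(miss) > 0L) {
    m <- miss[1L, ]
    stop(sprintf("life table missing cell (sex=%s, age=%d, year=%d)",
                 sexes[m[1L]], ages[m[2L]], years[m[3L]]))
  }
  if (any(!is.finite(rate)) || any(rate < 0))
    stop("life-table rates must be finite and >= 0")
  structure(list(rate = rate, sexes = sexes, ages = ages, years = years),
            class = "life_table")
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("Population life table: %d sex(es) [%s], ages %d-%d, years %d-%d\n",
              length(x$sexes), paste(x$sexes, collapse = ", "),
              min(x$ages), max(x$ages), min(x$years), max(x$years)))
  invisible(x)
}

#' Read a life table from text
#'
#' Reads either a long CSV (`sex,age,year,rate`) or an HMD-style period
#' table (whitespace-separated columns `Year`, `Age`, `mx`, with the open
#' top age written `110+`). The HMD dialect carries one sex per file, named
#' by `sex`.
#'
#' @param source Path to a file, or a connection/text readable by
#'   [read.csv()] / [read.table()].
#' @param dialect `"long_csv"` or `"hmd_period"`.
#' @param sex Sex label to assign to an HMD-style table (default
#'   `"total"`).
#' @param ages,years Optional declared grids. When given with
#'   `fill = "nearest"`, cells absent from the source are filled from the
#'   nearest available cell (age first, then year), e.g. a single-row file
#'   expands to a constant table.
#' @param fill `"none"` (missing cells are an error) or `"nearest"`.
#' @return A [life_table()].
#' @export
read_life_table <- function(source,
                            dialect = c("long_csv", "hmd_period"),
                            sex = "total",
                            ages = NULL, years = NULL,
                            fill = c("none", "nearest")) {
  dialect <- match.arg(dialect)
  fill <- match.arg(fill)
  if (dialect == "long_csv") {
    df <- utils::read.csv(source, stringsAsFactors = FALSE)
    need <- c("sex", "age", "year", "rate")
    if (!all(need %in% names(df)))
      stop("long_csv life table needs columns sex, age, year, rate")
  } else {
    raw <- utils::read.table(source, header = TRUE, stringsAsFactors = FALSE,
                             check.names = FALSE)
    names(raw) <- tolower(names(raw))
    if (!all(c("year", "age", "mx") %in% names(raw)))
      stop("hmd_period life table needs columns Year, Age, mx")
    age_chr <- as.character(raw$age)
    open <- grepl("\\+$", age_chr)
    age_num <- suppressWarnings(as.integer(sub("\\+$", "", age_chr)))
    if (any(is.na(age_num))) stop("unparseable Age value in HMD table")
    df <- data.frame(sex = sex, age = age_num, year = as.integer(raw$year),
                     rate = as.numeric(raw$mx))
    # "110+" clamps to a single top row; drop duplicates beyond it
    df <- df[!duplicated(df[c("sex", "age", "year")]), , drop = FALSE]
    if (any(open)) df <- df[df$age <= max(df$age[open]), , drop = FALSE]
  }
  if (any(!is.finite(df$rate)) || any(df$rate < 0))
    stop("life-table rates must be finite and >= 0")
  if (is.null(ages)) ages <- seq(min(df$age), max(df$age))
  if (is.null(years)) years <- seq(min(df$year), max(df$year))
  sexes <- sort(unique(as.character(df$sex)))
  full <- expand.grid(sex = sexes, age = as.integer(ages),
                      year = as.integer(years), stringsAsFactors = FALSE)
  key <- function(s, a, y) paste(s, a, y, sep = "\r")
  idx <- match(key(full$sex, full$age, full$year),
               key(df$sex, df$age, df$year))
  full$rate <- df$rate[idx]
  if (anyNA(full$rate)) {
    if (fill == "none") {
      m <- full[which(is.na(full$rate))[1L], ]
      stop(sprintf("life table missing cell (sex=%s, age=%d, year=%d)",
                   m$sex, m$age, m$year))
    }
    # nearest-cell fill: within sex, nearest provided age, then nearest year
    for (s in sexes) {
      sub <- df[df$sex == s, , drop = FALSE]
      if (nrow(sub) == 0L)
        stop(sprintf("life table has no rows for sex=%s", s))
      sel <- full$sex == s & is.na(full$rate)
      if (!any(sel)) next
      a_near <- vapply(full$age[sel], function(a)
        sub$age[which.min(abs(sub$age - a))], integer(1))
      r <- vapply(seq_len(sum(sel)), function(i) {
        cand <- sub[sub$age == a_near[i], , drop = FALSE]
        cand$rate[which.min(abs(cand$year - full$year[sel][i]))]
      }, numeric(1))
      full$rate[sel] <- r
    }
  }
  life_table(full)
}

# clamped (row, col) indices into the rate array
.lt_sex_index <- function(lt, sex) {
  i <- match(as.character(sex), lt$sexes)
  if (anyNA(i))
    stop(sprintf("sex label(s) not in life table: %s",
                 paste(unique(sex[is.na(i)]), collapse = ", ")))
  i
}

#' Expected mortality hazard for given profiles
#'
#' Looks up the life-table hazard at floor(age) and floor(year), clamping
#' both to the table boundaries. Vectorised over `sex`, `age`, `year`.
#'
#' @param lt A [life_table()].
#' @param sex,age,year Profile coordinates (age and year may be fractional).
#' @return Numeric vector of hazards (per person-year).
#' @export
expected_hazard <- function(lt, sex, age, year) {
  n <- max(length(sex), length(age), length(year))
  sex <- rep_len(sex, n); age <- rep_len(age, n); year <- rep_len(year, n)
  ai <- pmin(pmax(floor(age), min(lt$ages)), max(lt$ages)) - min(lt$ages) + 1L
  yi <- pmin(pmax(floor(year), min(lt$years)), max(lt$years)) - min(lt$years) + 1L
  si <- .lt_sex_index(lt, sex)
  lt$rate[cbind(si, ai, yi)]
}

#' Convert a Date to a decimal calendar year
#'
#' Uses a 365.25-day year; the sub-day misalignment of calendar-year
#' boundaries in leap years is negligible at annual life-table resolution.
#' @param date A `Date` vector (or numeric, returned unchanged).
#' @return Numeric decimal years.
#' @export
decimal_year <- function(date) {
  if (is.numeric(date)) return(as.numeric(date))
  y <- as.integer(format(date, "%Y"))
  y + as.numeric(date - as.Date(paste0(y, "-01-01"))) / 365.25
}

# Breakpoints (in follow-up time) where the attained integer age or the
# calendar year changes, out to t_max. Returns segment ends and the constant
# hazard on each segment.
.lt_trajectory <- function(lt, sex, age_dx, date_dx, t_max) {
  y0 <- decimal_year(date_dx)
  eps <- 1e-12
  seq_to <- function(from, to) if (from > to) numeric(0) else seq(from, to, by = 1)
  brk_age <- seq_to(ceiling(age_dx + eps) - age_dx, t_max)
  brk_year <- seq_to(ceiling(y0 + eps) - y0, t_max)
  ends <- sort(unique(c(brk_age, brk_year, t_max)))
  ends <- ends[ends > 0 & ends <= t_max + eps]
  if (length(ends) == 0L || ends[length(ends)] < t_max - eps)
    ends <- c(ends, t_max)
  mids <- (c(0, ends[-length(ends)]) + ends) / 2
  list(ends = ends,
       rate = expected_hazard(lt, sex, age_dx + mids, y0 + mids))
}

#' Expected cumulative hazard and survival along follow-up
#'
#' Integrates the piecewise-constant life-table hazard along the patient's
#' attained-age / calendar-year trajectory (both advance with follow-up
#' time), splitting the integral exactly at every integer age and calendar
#' year boundary.
#'
#' @param lt A [life_table()].
#' @param sex Sex label of the patient.
#' @param age_dx Age at diagnosis in years (may be fractional).
#' @param date_dx Diagnosis date (`Date` or decimal year).
#' @param t Follow-up times in years (vector, all `>= 0`).
#' @return A data frame with columns `t`, `cumhaz` (expected cumulative
#'   hazard) and `surv` (expected survival `exp(-cumhaz)`).
#' @export
expected_cum_hazard <- function(lt, sex, age_dx, date_dx, t) {
  if (any(t < 0)) stop("t must be >= 0")
  t_max <- max(t, 0)
  if (t_max == 0) {
    return(data.frame(t = t, cumhaz = 0, surv = 1))
  }
  tr <- .lt_trajectory(lt, sex, age_dx, date_dx, t_max)
  starts <- c(0, tr$ends[-length(tr$ends)])
  cum_ends <- cumsum(tr$rate * (tr$ends - starts))
  # piecewise-linear interpolation of the cumulative hazard
  ch <- stats::approx(x = c(0, tr$ends), y = c(0, cum_ends), xout = t,
                      method = "linear", rule = 2)$y
  # beyond t_max cannot occur (t_max = max(t)); rule=2 guards rounding
  data.frame(t = t, cumhaz = ch, surv = exp(-ch))
}

# Inverse-transform sampling of a background (other-cause) death time from
# the life-table hazard: draws E ~ Exp(1) and solves Lambda*(T) = E along
# the trajectory; Inf when the cumulative hazard never reaches E before
# `t_max` (treated as surviving the horizon).
.lt_sample_background <- function(lt, sex, age_dx, date_dx, e, t_max = 120) {
  tr <- .lt_trajectory(lt, sex, age_dx, date_dx, t_max)
  starts <- c(0, tr$ends[-length(tr$ends)])
  cum_ends <- cumsum(tr$rate * (tr$ends - starts))
  cum_starts <- c(0, cum_ends[-length(cum_ends)])
  i <- findInterval(e, cum_ends) + 1L
  out <- rep(Inf, length(e))
  ok <- i <= length(cum_ends)
  j <- i[ok]
  out[ok] <- starts[j] + (e[ok] - cum_starts[j]) / tr$rate[j]
  out
}
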