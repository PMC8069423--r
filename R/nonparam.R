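# Model-free net-survival benchmarks: the Pohar Perme inverse-expected-
# survival-weighted estimator and an interval (step-function) excess
# mortality rate. Both serve as validation references for the parametric
# fits.

# Per-subject expected survival weights w_i(tau) = 1/S*_i(tau) at a vector
# of times; returns the full vector including tau = 0 (w = 1).
.pp_weights <- function(lt, row, taus) {
  ch <- expected_cum_hazard(lt, row$sex, row$age_at_diagnosis,
                            row$diagnosis_date, taus)$cumhaz
  exp(ch)
}

#' Pohar Perme net-survival estimator
#'
#' Weights each subject's event and at-risk process by the inverse of its
#' expected (life-table) survival, subtracts the weighted expected hazard
#' increment, and accumulates the excess hazard over the distinct exit
#' times. The continuous expected part is integrated exactly between exit
#' times (the at-risk set is constant there, so the integral is a log
#' ratio of weighted risk-set sizes); net survival uses a product-limit
#' form for the discrete event jumps, so with a zero life table and no
#' censoring it reduces exactly to the empirical all-cause survival.
#'
#' @param cohort Data frame with columns `sex`, `age_at_diagnosis`,
#'   `diagnosis_date`, `time_years`, `status` (1 = death of any cause).
#' @param lt A [life_table()] covering every record.
#' @param grid Optional evaluation times; defaults to the distinct exit
#'   times.
#' @return A data frame of class `net_survival_curve` with columns `time`,
#'   `ns`, `se`, `cumhaz_excess`, `var_cumhaz`. Non-parametric net
#'   survival may locally rise or exceed 1. The curve is truncated (with a
#'   warning) if the weighted risk set empties before the last grid time.
#' @export
pohar_perme <- function(cohort, lt, grid = NULL) {
  stopifnot(all(c("sex", "age_at_diagnosis", "diagnosis_date",
                  "time_years", "status") %in% names(cohort)))
  n <- nrow(cohort)
  taus <- sort(unique(cohort$time_years))
  taus <- taus[taus > 0]
  M <- length(taus)
  W_now <- numeric(M)    # sum of w_i(tau_m) over subjects at risk at tau_m
  W_prev <- numeric(M)   # sum of w_i(tau_{m-1}) over the same risk set
  J_num <- numeric(M)    # sum of w_i(tau_m) over deaths at tau_m
  V_num <- numeric(M)    # sum of w_i(tau_m)^2 over deaths at tau_m
  tau0 <- c(0, taus[-M])
  for (i in seq_len(n)) {
    ti <- cohort$time_years[i]
    mi <- findInterval(ti, taus)     # number of taus <= ti
    if (mi == 0L) next
    w_at <- .pp_weights(lt, cohort[i, ], taus[seq_len(mi)])
    w_at0 <- c(1, w_at[-mi])   # w_i at tau_{m-1}; tau_0 = 0 has weight 1
    W_now[seq_len(mi)] <- W_now[seq_len(mi)] + w_at
    W_prev[seq_len(mi)] <- W_prev[seq_len(mi)] + w_at0
    if (cohort$status[i] == 1L) {
      J_num[mi] <- J_num[mi] + w_at[mi]
      V_num[mi] <- V_num[mi] + w_at[mi]^2
    }
  }
  alive <- W_now > 0
  if (!all(alive)) {
    keep <- seq_len(which(!alive)[1L] - 1L)
    warning("weighted risk set empty before end of follow-up; curve truncated")
    taus <- taus[keep]; W_now <- W_now[keep]; W_prev <- W_prev[keep]
    J_num <- J_num[keep]; V_num <- V_num[keep]; M <- length(keep)
  }
  jump <- J_num / W_now                    # weighted event increment
  pop <- log(W_now) - log(W_prev)          # exact expected increment
  cumhaz <- cumsum(jump - pop)
  ns <- cumprod(1 - jump) * exp(cumsum(pop))
  v <- cumsum(V_num / W_now^2)
  out <- data.frame(time = taus, ns = ns, se = ns * sqrt(v),
                    cumhaz_excess = cumhaz, var_cumhaz = v)
  if (!is.null(grid)) {
    # the estimate is a step function, constant after the last exit; allow
    # one day of slack (registry date resolution) before truncating
    beyond <- grid > max(taus) + 1 / 365.25
    if (any(beyond)) {
      warning("grid extends beyond the last observed exit; curve truncated")
      grid <- grid[!beyond]
    }
    idx <- findInterval(grid, taus)
    out <- data.frame(time = grid,
                      ns = ifelse(idx == 0L, 1, out$ns[pmax(idx, 1L)]),
                      se = ifelse(idx == 0L, 0, out$se[pmax(idx, 1L)]),
                      cumhaz_excess = ifelse(idx == 0L, 0,
                                             out$cumhaz_excess[pmax(idx, 1L)]),
                      var_cumhaz = ifelse(idx == 0L, 0,
                                          out$var_cumhaz[pmax(idx, 1L)]))
  }
  class(out) <- c("net_survival_curve", "data.frame")
  out
}

#' Interval-based (step-function) excess mortality rate
#'
#' Per interval, `EMR = (observed deaths - expected deaths) / person-time`,
#' with expected deaths accumulated as each subject's expected cumulative
#' hazard increment over its exposure inside the interval, and exposure
#' counted exactly up to exit (no actuarial half-interval convention).
#'
#' @param cohort As in [pohar_perme()].
#' @param lt A [life_table()].
#' @param breaks Increasing interval boundaries starting at 0 (default
#'   annual over 0--10 years).
#' @return Data frame with one row per interval: `start`, `end`, `mid`,
#'   `deaths`, `expected`, `person_time`, `emr` (`NA` with
#'   `undefined = TRUE` when an interval has no person-time).
#' @export
emr_step <- function(cohort, lt, breaks = 0:10) {
  if (breaks[1L] != 0 || any(diff(breaks) <= 0))
    stop("breaks must be increasing and start at 0")
  L <- length(breaks) - 1L
  deaths <- numeric(L); pt <- numeric(L); expd <- numeric(L)
  for (i in seq_len(nrow(cohort))) {
    ti <- cohort$time_years[i]
    if (ti <= 0) next
    hi <- pmin(ti, breaks[-1L])
    lo <- pmin(ti, breaks[-(L + 1L)])
    expo <- pmax(hi - lo, 0)
    act <- expo > 0
    pt <- pt + expo
    if (any(act)) {
      pts <- sort(unique(c(lo[act], hi[act])))
      ch <- expected_cum_hazard(lt, cohort$sex[i], cohort$age_at_diagnosis[i],
                                cohort$diagnosis_date[i], pts)$cumhaz
      expd[act] <- expd[act] + ch[match(hi[act], pts)] - ch[match(lo[act], pts)]
    }
    if (cohort$status[i] == 1L) {
      j <- findInterval(ti, breaks, left.open = TRUE, rightmost.closed = TRUE)
      if (j >= 1L && j <= L) deaths[j] <- deaths[j] + 1
    }
  }
  emr <- ifelse(pt > 0, (deaths - expd) / pt, NA_real_)
  data.frame(start = breaks[-(L + 1L)], end = breaks[-1L],
             mid = (breaks[-(L + 1L)] + breaks[-1L]) / 2,
             deaths = deaths, expected = expd, person_time = pt,
             emr = emr, undefined = pt <= 0)
}
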