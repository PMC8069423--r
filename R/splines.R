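# Restricted cubic spline bases on the log-time axis.
#
# Two constructions are used throughout the package:
#   * "standard": the usual restricted cubic spline (linear term plus
#     truncated-cubic terms restricted to linearity beyond both boundary
#     knots) used to model the log cumulative excess hazard.
#   * "backward": the same non-linear terms built on the reversed axis with
#     the linear term excluded, so every basis function (and its derivative)
#     is identically zero at and beyond the last knot. A log cumulative
#     hazard built on this basis is structurally constant after the last
#     knot, which is exactly the statistical-cure constraint.

#' Spline specification
#'
#' @param knots Strictly increasing numeric vector (log-time axis),
#'   length >= 2.
#' @param kind `"standard"` or `"backward"`.
#' @return An object of class `spline_spec`.
#' @export
spline_spec <- function(knots, kind = c("standard", "backward")) {
  kind <- match.arg(kind)
  knots <- as.numeric(knots)
  if (length(knots) < 2L) stop("need at least 2 knots")
  if (any(diff(knots) <= 0)) stop("knots must be strictly increasing")
  if (kind == "backward" && length(knots) < 3L)
    stop("backward basis needs at least 3 knots")
  structure(list(knots = knots, kind = kind), class = "spline_spec")
}

#' @export
print.spline_spec <- function(x, ...) {
  cat(sprintf("%s restricted cubic spline, %d knots: %s\n", x$kind,
              length(x$knots), paste(signif(x$knots, 4), collapse = ", ")))
  invisible(x)
}

#' Place knots from observed event times
#'
#' Boundary knots at the minimum and maximum of the (log) event times,
#' `df - 1` interior knots at equally spaced centiles — the usual default
#' of flexible parametric survival models.
#'
#' @param event_log_times Log event times of uncensored subjects.
#' @param df Degrees of freedom (number of baseline basis columns for the
#'   standard kind); `df = 1` gives boundary knots only.
#' @param kind Passed to [spline_spec()]. The backward kind needs
#'   `df + 1 >= 3` knots.
#' @return A [spline_spec()] with `df + 1` knots.
#' @export
place_knots <- function(event_log_times, df, kind = "standard") {
  if (df < 1L) stop("df must be >= 1")
  x <- sort(unique(event_log_times[is.finite(event_log_times)]))
  if (length(x) < df + 1L)
    stop(sprintf(paste("only %d distinct event times for df=%d (need >= %d):",
                       "reduce model complexity (lower tier)"),
                 length(x), df, df + 1L))
  if (df == 1L) {
    k <- range(x)
  } else {
    probs <- seq_len(df - 1L) / df
    k <- c(min(x), stats::quantile(x, probs, names = FALSE, type = 7), max(x))
  }
  k <- unique(k)
  if (length(k) < 2L) stop("degenerate knot placement")
  spline_spec(k, kind = kind)
}

# truncated cube and its derivative
.tc <- function(x) ifelse(x > 0, x^3, 0)
.tcd <- function(x) ifelse(x > 0, 3 * x^2, 0)

#' Evaluate a restricted cubic spline basis and its derivative
#'
#' For the standard kind with knots \eqn{k_1 < \dots < k_K} the columns are
#' \eqn{u} and, for \eqn{j = 1, \dots, K-2},
#' \deqn{v_j(u) = (u-k_j)_+^3 - \phi_j (u-k_1)_+^3 - (1-\phi_j)(u-k_K)_+^3,}
#' with \eqn{\phi_j = (k_K-k_j)/(k_K-k_1)}; the function is linear beyond
#' both boundary knots. The backward kind evaluates the non-linear columns
#' on the reversed axis (no linear term), so every column is 0 with zero
#' derivative for \eqn{u \ge k_K}.
#'
#' @param spec A [spline_spec()].
#' @param u Numeric vector of evaluation points (log time).
#' @return List with matrices `b` (basis values) and `db` (first
#'   derivatives with respect to `u`), one column per basis function.
#' @export
rcs_basis <- function(spec, u) {
  stopifnot(inherits(spec, "spline_spec"))
  k <- spec$knots
  K <- length(k)
  u <- as.numeric(u)
  if (spec$kind == "standard") {
    ncols <- K - 1L
    b <- matrix(0, length(u), ncols)
    db <- matrix(0, length(u), ncols)
    b[, 1L] <- u
    db[, 1L] <- 1
    if (K > 2L) {
      for (j in seq_len(K - 2L)) {
        kj <- k[j + 1L]                       # interior knot
        phi <- (k[K] - kj) / (k[K] - k[1L])
        b[, j + 1L] <- .tc(u - kj) - phi * .tc(u - k[1L]) -
          (1 - phi) * .tc(u - k[K])
        db[, j + 1L] <- .tcd(u - kj) - phi * .tcd(u - k[1L]) -
          (1 - phi) * .tcd(u - k[K])
      }
    }
  } else {
    # reversed axis: w = -u with knots -rev(k); non-linear terms only
    w <- -u
    m <- -rev(k)
    ncols <- K - 2L
    b <- matrix(0, length(u), ncols)
    db <- matrix(0, length(u), ncols)
    for (j in seq_len(K - 2L)) {
      mj <- m[j + 1L]                         # interior knot (reversed axis)
      phi <- (m[K] - mj) / (m[K] - m[1L])
      b[, j] <- .tc(w - mj) - phi * .tc(w - m[1L]) -
        (1 - phi) * .tc(w - m[K])
      db[, j] <- -(.tcd(w - mj) - phi * .tcd(w - m[1L]) -
                     (1 - phi) * .tcd(w - m[K]))
    }
  }
  list(b = b, db = db)
}
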