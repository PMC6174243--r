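# Locally weighted polynomial regression with a fixed-width tricube
# kernel. Unlike span-based smoothers, the kernel has hard support of
# `bandwidth` months around each query age (with a nearest-neighbour
# fallback in sparse regions), which is what the age-normative curves
# require.

#' Fit a fixed-bandwidth local polynomial curve
#'
#' At every query age the curve value is a weighted polynomial fit of
#' `degree` using tricube weights
#' `w_i = (1 - (|age_i - a| / bandwidth)^3)^3` for points within the
#' bandwidth and zero outside. If fewer than `degree + 2` points fall
#' inside the window, the window expands to the nearest `degree + 2`
#' points so the fit stays defined. Near-singular local designs (e.g.
#' all weight on one duplicated age) fall back to a tiny ridge.
#'
#' @param ages Training ages in months (>= 5 points).
#' @param values Training metric values (same length).
#' @param bandwidth Kernel half-width in months (> 0, default 24, i.e. a
#'   2-year smoothing kernel).
#' @param degree Local polynomial degree, 1 or 2 (default 1).
#' @param clip If `TRUE`, clip each local prediction to the range of the
#'   positively weighted training values (used for scale curves, which
#'   must not collapse below locally observed dispersion).
#'
#' @return A `loess_curve` object; evaluate it with `predict()`.
#' @export
loess_curve <- function(ages, values, bandwidth = 24, degree = 1,
                        clip = FALSE) {
  if (length(ages) != length(values)) abort("lengths differ")
  if (length(ages) < 5) abort("need at least 5 training points")
  if (bandwidth <= 0) abort("`bandwidth` must be positive")
  if (!degree %in% c(1, 2)) abort("`degree` must be 1 or 2")
  keep <- is.finite(ages) & is.finite(values)
  structure(
    list(ages = as.numeric(ages[keep]), values = as.numeric(values[keep]),
         bandwidth = bandwidth, degree = degree, clip = clip),
    class = "loess_curve")
}

tricube <- function(d, bw) {
  w <- numeric(length(d))
  inside <- abs(d) < bw
  w[inside] <- (1 - (abs(d[inside]) / bw)^3)^3
  w
}

# weighted polynomial fit at a single query age; returns fitted value
loess_point <- function(obj, a) {
  d <- obj$ages - a
  w <- tricube(d, obj$bandwidth)
  k <- obj$degree + 2
  if (sum(w > 0) < k) {
    # nearest-neighbour fallback: widen to the k nearest points
    bw_local <- sort(abs(d))[k] * (1 + 1e-8) + 1e-12
    w <- tricube(d, bw_local)
  }
  X <- outer(d, 0:obj$degree, `^`)
  xw <- X * w
  XtWX <- crossprod(X, xw)
  XtWy <- crossprod(xw, obj$values)
  beta <- tryCatch(solve(XtWX, XtWy), error = function(e) NULL)
  if (is.null(beta) || any(!is.finite(beta))) {
    ridge <- diag(c(0, rep(1e-8 * max(diag(XtWX), 1), obj$degree)),
                  nrow = obj$degree + 1)
    beta <- solve(XtWX + ridge, XtWy)
  }
  est <- beta[1]                             # design centred at the query
  if (isTRUE(obj$clip)) {
    # no extrapolation beyond the locally observed values: a prediction
    # outside the hull of the positively weighted points is fit noise
    est <- min(max(est, min(obj$values[w > 0])), max(obj$values[w > 0]))
  }
  est
}

#' @param object A `loess_curve`.
#' @param newages Ages at which to evaluate the curve.
#' @param ... Unused.
#' @rdname loess_curve
#' @export
predict.loess_curve <- function(object, newages, ...) {
  vapply(newages, function(a) loess_point(object, a), numeric(1))
}

#' @export
print.loess_curve <- function(x, ...) {
  cat(sprintf("<loess_curve> degree %d, bandwidth %g months, %d points\n",
              x$degree, x$bandwidth, length(x$ages)))
  invisible(x)
}
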