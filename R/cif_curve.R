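#' Construct a cumulative incidence curve
#'
#' A right-continuous step function on `[0, 1]`, starting at 0 at
#' `origin_age`, with optional pointwise standard errors and confidence
#' bands.
#'
#' @param times Sorted ages (years) at which the curve is recorded.
#' @param values CIF estimates in `[0, 1]`, non-decreasing.
#' @param se Optional pointwise standard errors.
#' @param lower,upper Optional confidence-band limits in `[0, 1]`.
#' @param origin_age Conditioning age `s` (0 for the unconditional curve).
#' @param conf_level Confidence level of the bands, if present.
#' @return Object of class `cif_curve`: a data.frame with columns `time`,
#'   `cif` and optionally `se`, `lower`, `upper`.
#' @export
cif_curve <- function(times, values, se = NULL, lower = NULL, upper = NULL,
                      origin_age = 0, conf_level = NULL) {
  if (is.unsorted(times)) {
    o <- order(times)
    times <- times[o]; values <- values[o]
    if (!is.null(se)) se <- se[o]
    if (!is.null(lower)) lower <- lower[o]
    if (!is.null(upper)) upper <- upper[o]
  }
  if (any(values < -1e-12 | values > 1 + 1e-12))
    stop_validation("CIF values must lie in [0, 1]")
  if (any(diff(values) < -1e-12))
    stop_validation("CIF values must be non-decreasing in time")
  values <- pmin(pmax(values, 0), 1)
  out <- data.frame(time = as.numeric(times), cif = as.numeric(values))
  if (!is.null(se)) out$se <- as.numeric(se)
  if (!is.null(lower)) out$lower <- pmin(pmax(as.numeric(lower), 0), 1)
  if (!is.null(upper)) out$upper <- pmin(pmax(as.numeric(upper), 0), 1)
  attr(out, "origin_age") <- origin_age
  attr(out, "conf_level") <- conf_level
  class(out) <- c("cif_curve", "data.frame")
  out
}

#' Evaluate a CIF curve at arbitrary ages
#'
#' Step interpolation: the value at `t` is the estimate at the last recorded
#' time `<= t`, and 0 before the first recorded time (the curve starts at 0
#' at its origin age).
#'
#' @param curve A [cif_curve()].
#' @param t Numeric vector of ages.
#' @return Numeric vector of CIF values.
#' @export
cif_at <- function(curve, t) {
  idx <- findInterval(t, curve$time)
  c(0, curve$cif)[idx + 1L]
}

#' Number of jumps of a CIF curve
#'
#' Recorded time points where the estimate strictly increases.
#'
#' @param curve A [cif_curve()].
#' @param tol Increases below `tol` are not counted.
#' @return Integer jump count.
#' @export
n_jumps <- function(curve, tol = 1e-12) {
  sum(diff(c(0, curve$cif)) > tol)
}

#' Exact sup-norm distance between two CIF step curves
#'
#' Both curves are step functions, so the supremum over the shared window is
#' attained on the union of their jump times plus the window endpoints.
#'
#' @param a,b [cif_curve()] objects with a common origin age.
#' @return Scalar `max |a(t) - b(t)|`.
#' @export
sup_distance <- function(a, b) {
  grid <- sort(unique(c(attr(a, "origin_age"), a$time, b$time)))
  if (!length(grid)) return(0)
  max(abs(cif_at(a, grid) - cif_at(b, grid)))
}

#' @export
print.cif_curve <- function(x, ...) {
  cat(sprintf("CIF curve: %d time points on (%.3g, %.3g], final value %.4f\n",
              nrow(x), attr(x, "origin_age"),
              if (nrow(x)) max(x$time) else attr(x, "origin_age"),
              if (nrow(x)) x$cif[nrow(x)] else 0))
  if (!is.null(x$lower))
    cat(sprintf("with %.0f%% pointwise confidence band\n",
                100 * (attr(x, "conf_level") %||% 0.95)))
  invisible(x)
}

#' @export
plot.cif_curve <- function(x, add = FALSE, col = 1, lty = 1,
                           xlab = "Age (years)",
                           ylab = "Cumulative incidence", ...) {
  t0 <- attr(x, "origin_age")
  tt <- c(t0, x$time)
  vv <- c(0, x$cif)
  if (!add)
    graphics::plot(tt, vv, type = "s", ylim = c(0, 1), col = col, lty = lty,
                   xlab = xlab, ylab = ylab, ...)
  else graphics::lines(tt, vv, type = "s", col = col, lty = lty, ...)
  if (!is.null(x$lower)) {
    graphics::lines(c(t0, x$time), c(0, x$lower), type = "s", col = col,
                    lty = 3)
    graphics::lines(c(t0, x$time), c(0, x$upper), type = "s", col = col,
                    lty = 3)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
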