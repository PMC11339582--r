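# Time-varying arrival intensity lambda(t), in events per minute.
#
# The canonical representation is a monotone piecewise-cubic Hermite
# interpolant (Fritsch-Carlson) through (time, rate) knots: it passes through
# the knots exactly and cannot overshoot below zero between positive knots,
# which keeps thinning-based sampling well defined. Rates are floored at
# RATE_FLOOR so the dominating rate is always positive.

RATE_FLOOR <- 1e-9

#' Construct a rate function from knots
#'
#' Builds a monotone-preserving piecewise-cubic Hermite interpolant through
#' `(time, rate)` knots, clipped below at a small positive floor. Outside the
#' knot range the nearest knot value is held constant.
#'
#' @param times knot positions, minutes, strictly increasing.
#' @param rates intensities at the knots, events per minute, finite and
#'   nonnegative.
#' @param t_max end of the evaluation domain in minutes (default: last knot);
#'   the dominating rate `max_rate` is audited on a 1-minute grid over
#'   `[0, t_max]`.
#' @param periodic if `TRUE`, knots are interpreted modulo their span
#'   (e.g. a 24-hour diurnal profile reused every day).
#' @return An object of class `rate_function`: callable via [rate_at()], with
#'   fields `knots`, `rates`, `max_rate`, `t_max`.
#' @export
rate_function <- function(times, rates, t_max = max(times), periodic = FALSE) {
  if (length(times) < 2) stop_domain("rate_function needs at least 2 knots")
  if (any(!is.finite(times)) || any(!is.finite(rates))) {
    stop_domain("rate_function knots must be finite")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop_domain("rate_function knot times must be strictly increasing")
  }
  if (any(rates < 0)) stop_domain("rate_function rates must be nonnegative")
  f <- stats::splinefun(times, rates, method = "monoH.FC")
  span <- max(times) - min(times)
  t0 <- min(times)
  eval_fn <- if (periodic) {
    function(t) pmax(f(t0 + (t - t0) %% span), RATE_FLOOR)
  } else {
    function(t) pmax(f(pmin(pmax(t, min(times)), max(times))), RATE_FLOOR)
  }
  grid <- seq(0, t_max, by = 1)
  vals <- eval_fn(grid)
  # 1% headroom covers the slight overshoot the monotone-filtered cubic can
  # exhibit between audit-grid points; a conservative dominating rate only
  # costs a few extra thinning candidates
  structure(
    list(fn = eval_fn, knots = times, rates = rates,
         max_rate = 1.01 * max(vals, eval_fn(times)), t_max = t_max,
         periodic = periodic),
    class = "rate_function"
  )
}

#' Constant arrival rate
#'
#' @param rate events per minute, `>= 0`.
#' @param t_max nominal end of domain in minutes.
#' @return A `rate_function` with `lambda(t) == max(rate, floor)` everywhere.
#' @export
constant_rate <- function(rate, t_max = Inf) {
  if (!is.finite(rate) || rate < 0) stop_domain("rate must be finite and nonnegative")
  r <- max(rate, RATE_FLOOR)
  structure(
    list(fn = function(t) rep(r, length(t)), knots = c(0, 1), rates = c(rate, rate),
         max_rate = r, t_max = t_max, periodic = FALSE),
    class = "rate_function"
  )
}

#' Rate function from an arbitrary intensity
#'
#' Wraps a vectorised function of time (minutes); the dominating rate is
#' taken as the maximum over a 1-minute audit grid.
#'
#' @param f vectorised function minutes -> events/minute.
#' @param t_max end of domain, minutes.
#' @return A `rate_function`.
#' @export
as_rate_function <- function(f, t_max) {
  grid <- seq(0, t_max, by = 1)
  vals <- f(grid)
  if (any(!is.finite(vals)) || any(vals < -1e-12)) {
    stop_domain("intensity must be finite and nonnegative on the domain")
  }
  eval_fn <- function(t) pmax(f(t), RATE_FLOOR)
  structure(
    list(fn = eval_fn, knots = range(grid), rates = range(vals),
         max_rate = 1.01 * max(vals, RATE_FLOOR), t_max = t_max,
         periodic = FALSE),
    class = "rate_function"
  )
}

#' Evaluate a rate function
#'
#' @param rf a `rate_function`.
#' @param t times in minutes.
#' @return Intensities, events per minute.
#' @export
rate_at <- function(rf, t) {
  stopifnot(inherits(rf, "rate_function"))
  rf$fn(t)
}

#' Diurnal arrival profile from hourly rates
#'
#' Builds a periodic (24-hour) rate function through hour-of-day knots,
#' reused every simulated day.
#'
#' @param hourly_rates 24 intensities (events/minute) at hours 0..23.
#' @param t_max evaluation horizon in minutes.
#' @return A periodic `rate_function`.
#' @export
diurnal_rate <- function(hourly_rates, t_max = MINUTES_PER_DAY) {
  if (length(hourly_rates) != 24) stop_domain("need 24 hourly rates")
  # close the cycle so interpolation wraps smoothly at midnight
  times <- seq(0, MINUTES_PER_DAY, by = 60)
  rate_function(times, c(hourly_rates, hourly_rates[1]),
                t_max = t_max, periodic = TRUE)
}

#' @export
print.rate_function <- function(x, ...) {
  cat(sprintf("<rate_function> max %.4g/min over [0, %s] min%s\n",
              x$max_rate, format(x$t_max), if (x$periodic) " (periodic)" else ""))
  invisible(x)
}
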