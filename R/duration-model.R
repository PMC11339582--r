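# Service-duration and patience model objects shared by the estimators,
# the synthetic-log generator, and the simulator.

#' Scaled-beta duration model from moments
#'
#' Chat durations (minutes) are modelled as `scale * Beta(alpha, beta)`.
#' Given a target mean and SD on `[0, scale]`, the shape parameters follow
#' by method of moments:
#' `alpha = m(m(1-m)/v - 1)`, `beta = (1-m)(m(1-m)/v - 1)` with
#' `m = mean/scale`, `v = (sd/scale)^2`. The implied mean
#' `scale * alpha/(alpha+beta)` equals `mean_minutes` exactly.
#'
#' @param mean_minutes,sd_minutes target moments in minutes.
#' @param scale support upper bound in minutes. Default `mean + 4*sd`, wide
#'   enough to cover the IQR-trimmed range of the strongly right-skewed
#'   durations seen in practice.
#' @param n_used sample size behind the moments (bookkeeping only).
#' @return An object of class `duration_model`.
#' @export
duration_model_from_moments <- function(mean_minutes, sd_minutes,
                                        scale = mean_minutes + 4 * sd_minutes,
                                        n_used = NA_integer_) {
  if (mean_minutes <= 0 || sd_minutes <= 0) {
    stop_domain("mean and sd must be positive")
  }
  if (scale <= mean_minutes) stop_domain("scale must exceed the mean")
  m <- mean_minutes / scale
  v <- (sd_minutes / scale)^2
  if (v >= m * (1 - m)) {
    stop_domain("variance too large for a beta on [0, scale]; increase scale")
  }
  common <- m * (1 - m) / v - 1
  structure(
    list(dist = "beta", alpha = m * common, beta = (1 - m) * common,
         scale = scale, mean_minutes = mean_minutes, sd_minutes = sd_minutes,
         n_used = n_used),
    class = "duration_model"
  )
}

#' Exponential duration model
#'
#' Memoryless service durations; used mainly to set up configurations whose
#' queueing behaviour has a closed-form stationary benchmark.
#'
#' @param mean_minutes mean duration, minutes.
#' @return An object of class `duration_model`.
#' @export
exp_duration_model <- function(mean_minutes) {
  if (mean_minutes <= 0) stop_domain("mean must be positive")
  structure(
    list(dist = "exp", mean_minutes = mean_minutes, sd_minutes = mean_minutes,
         n_used = NA_integer_),
    class = "duration_model"
  )
}

#' Draw service durations
#'
#' @param model a `duration_model`.
#' @param n number of draws.
#' @param scale_factor multiplier applied to every draw (scenario lever for
#'   shortened average processing time).
#' @return `n` durations in minutes.
#' @export
rduration <- function(model, n, scale_factor = 1) {
  stopifnot(inherits(model, "duration_model"))
  x <- switch(model$dist,
    beta = model$scale * stats::rbeta(n, model$alpha, model$beta),
    exp = stats::rexp(n, rate = 1 / model$mean_minutes),
    stop_domain("unknown duration distribution")
  )
  x * scale_factor
}

#' @export
print.duration_model <- function(x, ...) {
  if (x$dist == "beta") {
    cat(sprintf("<duration_model> %.2f * Beta(%.3f, %.3f) min (mean %.2f, sd %.2f, n=%s)\n",
                x$scale, x$alpha, x$beta, x$mean_minutes, x$sd_minutes,
                format(x$n_used)))
  } else {
    cat(sprintf("<duration_model> Exponential(mean %.2f min)\n", x$mean_minutes))
  }
  invisible(x)
}

#' Exponential patience model
#'
#' Time a queued user will wait before abandoning. `Inf` disables reneging
#' (infinitely patient users, the classical Erlang-C regime).
#'
#' @param mean_minutes exponential mean in minutes, `> 0` (may be `Inf`).
#' @param se_minutes standard error of the mean (bookkeeping).
#' @param n_events,n_censored counts behind a fitted model (bookkeeping).
#' @return An object of class `patience_model`.
#' @export
patience_model <- function(mean_minutes, se_minutes = NA_real_,
                           n_events = NA_integer_, n_censored = NA_integer_) {
  if (!(mean_minutes > 0)) stop_domain("patience mean must be positive")
  structure(
    list(mean_minutes = mean_minutes, se_minutes = se_minutes,
         n_events = n_events, n_censored = n_censored),
    class = "patience_model"
  )
}

#' Draw patience times
#'
#' @param model a [patience_model()].
#' @param n number of draws.
#' @return `n` patience times in minutes (`Inf` under infinite patience).
#' @export
rpatience <- function(model, n) {
  stopifnot(inherits(model, "patience_model"))
  if (is.infinite(model$mean_minutes)) return(rep(Inf, n))
  stats::rexp(n, rate = 1 / model$mean_minutes)
}

#' @export
print.patience_model <- function(x, ...) {
  cat(sprintf("<patience_model> Exponential(mean %.4f min, se %.4f; events %s, censored %s)\n",
              x$mean_minutes, x$se_minutes, format(x$n_events), format(x$n_censored)))
  invisible(x)
}
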