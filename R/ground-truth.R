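# Ground-truth parameter sets: everything the synthetic-log generator and
# the simulator need to describe one service operation.

#' Ground-truth parameters for synthetic log generation
#'
#' Bundles all generative ingredients of the service model: the TOS
#' acceptance probability, the nonrepeat/repeat user mix, per-type risk
#' mixes, per-stratum scaled-beta duration models, per-type exponential
#' patience, and the time-varying arrival intensity.
#'
#' @param tos_p probability a visitor accepts the terms of service.
#' @param user_type_p probability an accepted user is a nonrepeat user.
#' @param risk_mix named list (`nonrepeat`, `repeat`) of probability vectors
#'   over risk levels `low`, `medium`, `high_crisis`, each summing to 1.
#' @param durations named list (`nonrepeat`, `repeat`) of named lists over
#'   risk levels, each a [duration_model_from_moments()] object.
#' @param patience named list (`nonrepeat`, `repeat`) of [patience_model()]s.
#' @param rate_fn a [rate_function()], events per minute.
#' @return An object of class `ground_truth_params`.
#' @export
ground_truth_params <- function(tos_p, user_type_p, risk_mix, durations,
                                patience, rate_fn) {
  chk_prob <- function(p, what) {
    if (!is.numeric(p) || p < 0 || p > 1) stop_domain(what, " must lie in [0, 1]")
  }
  chk_prob(tos_p, "tos_p")
  chk_prob(user_type_p, "user_type_p")
  for (ut in USER_TYPE_LEVELS) {
    mix <- risk_mix[[ut]]
    if (is.null(mix) || length(mix) != 3 || abs(sum(mix) - 1) > 1e-8 || any(mix < 0)) {
      stop_domain("risk_mix$", ut, " must be 3 nonnegative probabilities summing to 1")
    }
    if (!inherits(patience[[ut]], "patience_model")) {
      stop_domain("patience$", ut, " must be a patience_model")
    }
    for (rl in RISK_LEVELS) {
      if (!inherits(durations[[ut]][[rl]], "duration_model")) {
        stop_domain("durations$", ut, "$", rl, " must be a duration_model")
      }
    }
  }
  stopifnot(inherits(rate_fn, "rate_function"))
  structure(
    list(tos_p = tos_p, user_type_p = user_type_p, risk_mix = risk_mix,
         durations = durations, patience = patience, rate_fn = rate_fn),
    class = "ground_truth_params"
  )
}

#' Default ground truth calibrated to the studied service operation
#'
#' TOS acceptance 0.7478 and a 71.08% nonrepeat share; per-stratum duration
#' moments (e.g. pooled low-risk mean 50.21, SD 31.65 minutes) converted to
#' scaled betas by method of moments; exponential patience means 3.4550
#' (nonrepeat) and 5.2895 (repeat) minutes; and a stylised diurnal arrival
#' profile averaging about 0.21 requests/minute (roughly 9,200 visitors per
#' 30 days) with a late-evening peak and an early-morning trough.
#'
#' @param rate_fn optionally override the arrival intensity.
#' @return A [ground_truth_params()] object.
#' @export
default_ground_truth <- function(rate_fn = default_rate_profile()) {
  dm <- duration_model_from_moments
  ground_truth_params(
    tos_p = 0.7478,
    user_type_p = 0.7108,
    risk_mix = list(
      nonrepeat = c(low = 0.8905, medium = 0.1033, high_crisis = 0.0062),
      `repeat` = c(low = 0.8880, medium = 0.1042, high_crisis = 0.0078)
    ),
    durations = list(
      nonrepeat = list(
        low = dm(50.07, 30.97, n_used = 24266L),
        medium = dm(70.85, 36.80, n_used = 2815L),
        high_crisis = dm(89.45, 44.18, n_used = 168L)
      ),
      `repeat` = list(
        low = dm(51.20, 34.49, n_used = 6932L),
        medium = dm(75.25, 45.78, n_used = 813L),
        high_crisis = dm(121.29, 83.30, n_used = 61L)
      )
    ),
    patience = list(
      nonrepeat = patience_model(3.4550, 0.0351),
      `repeat` = patience_model(5.2895, 0.0765)
    ),
    rate_fn = rate_fn
  )
}

#' Stylised diurnal arrival intensity
#'
#' A smooth 24-hour profile with its trough in the early morning (~0.10/min
#' around 5 AM) and its peak in the late evening (~0.32/min around 9:30 PM),
#' averaging 0.2124 requests/minute -- the traffic level of a busy month with
#' roughly 9,200 visitors over 30 days.
#'
#' @param t_max horizon in minutes over which the profile will be evaluated.
#' @return A periodic `rate_function`.
#' @export
default_rate_profile <- function(t_max = 30 * MINUTES_PER_DAY) {
  hours <- 0:23
  rates <- 0.2124 + 0.107 * cos(2 * pi * (hours - 21.5) / 24)
  diurnal_rate(rates, t_max = t_max)
}
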