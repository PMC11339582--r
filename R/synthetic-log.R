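# Synthetic event-log generator: produces chat logs with known ground-truth
# parameters so every estimator can be tested without access to any real
# service database.

#' Generate a synthetic chat event log
#'
#' Arrivals are an NHPP realisation of `params$rate_fn` (Lewis-Shedler
#' thinning); TOS decisions are i.i.d. Bernoulli(`tos_p`); user types, risk
#' levels and durations follow the stated categorical/beta models; reneges
#' follow exponential patience under a deliberately simple first-in-first-out
#' occupancy emulation with `n_counselors` single-chat servers, no shifts and
#' no breaks. The emulation exists to exercise the estimators, not to mimic
#' operations (the discrete-event engine does that).
#'
#' @param params a [ground_truth_params()] object.
#' @param horizon_minutes simulated span in minutes, `> 0`.
#' @param n_counselors number of always-on single-chat servers.
#' @param seed integer seed; output is deterministic given the seed.
#' @param origin calendar time of minute 0.
#' @return A validated [chat_log()] with timestamps at 1-second resolution.
#' @export
generate_synthetic_log <- function(params, horizon_minutes, n_counselors = 8,
                                   seed = NULL, origin = SIM_ORIGIN) {
  stopifnot(inherits(params, "ground_truth_params"))
  if (!is.finite(horizon_minutes) || horizon_minutes <= 0) {
    stop_domain("horizon_minutes must be positive")
  }
  with_seed(seed, {
    stream <- sample_nhpp(params$rate_fn, horizon_minutes)
    n <- nrow(stream)
    if (n == 0) return(chat_log())
    arrival <- stream$time
    channel <- sample(CHANNEL_LEVELS, n, replace = TRUE,
                      prob = c(0.70, 0.15, 0.08, 0.04, 0.03))
    tos <- stats::runif(n) < params$tos_p

    user_type <- rep(NA_character_, n)
    risk <- rep(NA_character_, n)
    dur <- rep(NA_real_, n)
    pat <- rep(NA_real_, n)
    acc <- which(tos)
    if (length(acc)) {
      ut <- ifelse(stats::runif(length(acc)) < params$user_type_p,
                   "nonrepeat", "repeat")
      user_type[acc] <- ut
      for (t in USER_TYPE_LEVELS) {
        i <- acc[ut == t]
        if (!length(i)) next
        risk[i] <- sample(RISK_LEVELS, length(i), replace = TRUE,
                          prob = params$risk_mix[[t]])
        pat[i] <- rpatience(params$patience[[t]], length(i))
      }
      for (t in USER_TYPE_LEVELS) {
        for (r in RISK_LEVELS) {
          i <- acc[user_type[acc] == t & risk[acc] == r]
          if (length(i)) dur[i] <- rduration(params$durations[[t]][[r]], length(i))
        }
      }
    }

    # FIFO occupancy emulation (Lindley recursion over n identical servers):
    # a case is picked up at max(arrival, earliest free server) unless its
    # patience runs out first.
    pickup <- rep(NA_real_, n)
    endt <- rep(NA_real_, n)
    renege <- rep(NA_real_, n)
    cid <- rep(NA_character_, n)
    avail <- rep(0, n_counselors)
    for (i in acc) {
      j <- which.min(avail)
      t_pick <- max(arrival[i], avail[j])
      if (t_pick - arrival[i] > pat[i]) {
        renege[i] <- arrival[i] + pat[i]
      } else {
        pickup[i] <- t_pick
        endt[i] <- t_pick + dur[i]
        cid[i] <- sprintf("c%02d", j)
        avail[j] <- endt[i]
      }
    }

    chat_log(
      user_id = stream$identity,
      channel = channel,
      arrival_ts = minutes_to_ts(arrival, origin),
      tos_accepted = tos,
      user_type = user_type,
      pickup_ts = minutes_to_ts(pickup, origin),
      end_ts = minutes_to_ts(endt, origin),
      renege_ts = minutes_to_ts(renege, origin),
      # risk is a counselor rating: observed only on picked-up cases
      risk_level = ifelse(!is.na(pickup), risk, NA_character_),
      counselor_id = cid
    )
  })
}
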