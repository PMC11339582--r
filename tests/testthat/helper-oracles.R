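# Analytic queueing oracles and shared fixtures, built in code.

# Erlang-C mean waiting time for an M/M/c queue (stationary, rho < 1).
erlang_c_wq <- function(lambda, mu, c) {
  a <- lambda / mu
  rho <- a / c
  stopifnot(rho < 1)
  inv <- sum(a^(0:(c - 1)) / factorial(0:(c - 1)))
  pc <- a^c / factorial(c)
  p_wait <- pc / ((1 - rho) * inv + pc)
  p_wait / (c * mu - lambda)
}

# Stationary abandonment probability of an M/M/c+M queue, from the truncated
# birth-death chain (death rate min(n,c)*mu + max(n-c,0)*theta).
mmcm_abandon <- function(lambda, mu, c, theta, K = 600) {
  lp <- cumsum(c(0, log(lambda) - log(pmin(1:K, c) * mu + pmax(1:K - c, 0) * theta)))
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  theta * sum(pmax(0:K - c, 0) * p) / lambda
}

# Degenerate single-stratum parameter set: every accepted case is a
# nonrepeat/low case with exponential service and common patience.
oracle_params <- function(mean_service, patience_mean) {
  dm <- exp_duration_model(mean_service)
  one_type <- list(low = dm, medium = dm, high_crisis = dm)
  list(
    tos_p = 1, user_type_p = 1,
    risk_mix = list(nonrepeat = c(low = 1, medium = 0, high_crisis = 0),
                    `repeat` = c(low = 1, medium = 0, high_crisis = 0)),
    durations = list(nonrepeat = one_type, `repeat` = one_type),
    patience = list(nonrepeat = patience_model(patience_mean),
                    `repeat` = patience_model(patience_mean))
  )
}

# Always-on station with `capacity` concurrent slots fed by a constant
# Poisson stream: the M/M/c(+M) benchmark configuration.
oracle_config <- function(rate, capacity, mean_service, patience_mean,
                          horizon) {
  role <- switch(as.character(capacity), "1" = "duty_officer",
                 "2" = "volunteer", "3" = "full_time", "full_time")
  scenario_config(
    shifts = list(shift(0, 24, list(counselor_spec(role)))),
    arrivals = arrivals_nhpp(constant_rate(rate)),
    params = oracle_params(mean_service, patience_mean),
    horizon_minutes = horizon, zero_wait_window_s = 0, survey_minutes = 0,
    zombie_eviction = TRUE, replications = 1, seed = 1
  )
}

# Minimal chat log wrapping a vector of arrival minutes.
stream_log <- function(minutes, ids = sprintf("u%07d", seq_along(minutes))) {
  chat_log(user_id = ids, channel = "web",
           arrival_ts = minutes_to_minsec(minutes), tos_accepted = TRUE)
}

minutes_to_minsec <- function(m) {
  as.POSIXct(round(m * 60), origin = as.POSIXct("2020-11-01", tz = "UTC"),
             tz = "UTC")
}

# Inversion (time-rescaling) sampler for a linearly increasing intensity
# lambda(t) = a + b t: the independent oracle for the thinning sampler.
nhpp_inversion_linear <- function(a, b, t_end) {
  Lmax <- a * t_end + b * t_end^2 / 2
  s <- cumsum(rexp(ceiling(Lmax + 6 * sqrt(Lmax) + 10)))
  s <- s[s <= Lmax]
  if (b == 0) return(s / a)
  (-a + sqrt(a^2 + 2 * b * s)) / b
}

# Compact scenario used by structural-invariant tests: the reconstructed
# base schedule under a few days of diurnal traffic.
short_base_config <- function(days = 5, zombie_eviction = FALSE,
                              replications = 1, seed = 1) {
  horizon <- days * 1440
  scenario_config(
    shifts = base_case_schedule(),
    arrivals = arrivals_nhpp(default_rate_profile(t_max = horizon)),
    params = default_ground_truth(),
    horizon_minutes = horizon, zombie_eviction = zombie_eviction,
    replications = replications, seed = seed
  )
}
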