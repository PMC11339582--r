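# Decision surfaces computed from simulation results: conversion
# decompositions, hourly queue/wait probability profiles and service-pledge
# conformity, dropout densities, counselor vacancy, cost-effectiveness
# curves, the repeat-share estimate and contingency-table proportions.

#' Conversion decomposition from known fractions
#'
#' Builds the decomposition directly from the funnel fractions -- e.g. from a
#' published breakdown -- computing the overall conversion as
#' `p_tos * (frac_immediate + frac_queued_served)`.
#'
#' @param p_tos TOS acceptance probability.
#' @param frac_immediate,frac_queued_served,frac_reneged,frac_in_system
#'   fractions of accepted users (zero-wait pickups, queued-then-served,
#'   reneged, still in system).
#' @return An object of class `conversion_decomposition`.
#' @export
conversion_decomposition <- function(p_tos, frac_immediate, frac_queued_served,
                                     frac_reneged = NA_real_,
                                     frac_in_system = NA_real_) {
  for (v in c(p_tos, frac_immediate, frac_queued_served)) {
    if (v < 0 || v > 1) stop_domain("fractions must lie in [0, 1]")
  }
  structure(
    list(p_tos = p_tos, frac_immediate = frac_immediate,
         frac_queued_served = frac_queued_served, frac_reneged = frac_reneged,
         frac_in_system = frac_in_system,
         overall_conversion = p_tos * (frac_immediate + frac_queued_served)),
    class = "conversion_decomposition"
  )
}

#' Decompose the overall conversion rate
#'
#' Splits the visitor-to-case funnel into the TOS acceptance probability and,
#' among accepters, the zero-wait, queued-then-served, reneged and
#' still-in-system fractions. The overall conversion rate is the product
#' `p_tos * (frac_immediate + frac_queued_served)`.
#'
#' @param x a `sim_result`, a `sim_run`, a named tally vector/list with
#'   elements `arrivals`, `tos_accepted`, `served_immediately`,
#'   `served_after_queue`, `reneged`, `in_system_at_horizon`, or a
#'   [chat_log()] (recomputed from raw events).
#' @param zero_wait_window_min when `x` is a log: pickups at or below this
#'   wait count as immediate.
#' @return An object of class `conversion_decomposition` with fields `p_tos`,
#'   `frac_immediate`, `frac_queued_served`, `frac_reneged`,
#'   `frac_in_system`, `overall_conversion`.
#' @export
decompose_conversion <- function(x, zero_wait_window_min = ZERO_WAIT_WINDOW_MIN) {
  if (inherits(x, "sim_result")) {
    t <- colSums(x$tallies[, c("arrivals", "tos_accepted", "served_immediately",
                               "served_after_queue", "reneged",
                               "in_system_at_horizon")])
  } else if (inherits(x, "sim_run")) {
    t <- x$tallies
  } else if (inherits(x, "chat_log")) {
    t <- log_tallies(x, zero_wait_window_min)
  } else {
    t <- unlist(x)
  }
  if (is.na(t["arrivals"]) || t[["arrivals"]] <= 0) {
    stop_domain("conversion undefined: no arrivals")
  }
  acc <- t[["tos_accepted"]]
  p_tos <- acc / t[["arrivals"]]
  frac <- function(k) if (acc > 0) t[[k]] / acc else 0
  out <- list(
    p_tos = p_tos,
    frac_immediate = frac("served_immediately"),
    frac_queued_served = frac("served_after_queue"),
    frac_reneged = frac("reneged"),
    frac_in_system = frac("in_system_at_horizon")
  )
  out$overall_conversion <- p_tos * (out$frac_immediate + out$frac_queued_served)
  structure(out, class = "conversion_decomposition")
}

# Independent tally pass over a raw event log (second code path used to
# cross-check the simulator's own counters).
log_tallies <- function(log, zero_wait_window_min = ZERO_WAIT_WINDOW_MIN) {
  m <- log_minutes(log)
  acc <- log$tos_accepted
  zombie <- !is.na(m$renege) & !is.na(m$pickup)
  served <- acc & !is.na(m$pickup) & !zombie
  reneged <- acc & !is.na(m$renege)
  wait <- m$pickup - m$arrival
  c(
    arrivals = nrow(log),
    tos_accepted = sum(acc),
    served_immediately = sum(served & wait <= zero_wait_window_min),
    served_after_queue = sum(served & wait > zero_wait_window_min),
    reneged = sum(reneged),
    in_system_at_horizon = sum(acc & !served & !reneged)
  )
}

#' @export
print.conversion_decomposition <- function(x, ...) {
  cat(sprintf(
    "conversion: %.2f%% = %.2f%% TOS x (%.2f%% immediate + %.2f%% queued)\n",
    100 * x$overall_conversion, 100 * x$p_tos, 100 * x$frac_immediate,
    100 * x$frac_queued_served))
  cat(sprintf("  reneged %.2f%%, in system at horizon %.2f%% (of accepted)\n",
              100 * x$frac_reneged, 100 * x$frac_in_system))
  invisible(x)
}

#' Hourly queue-length and waiting-time probability profiles
#'
#' Empirical `P(queue length <= k)` per hour of day (queue length sampled
#' every simulated minute, pooled over replications) and
#' `P(wait <= w)` per hour of day among queued users who were eventually
#' served.
#'
#' @param result a `sim_result`.
#' @param k queue-length thresholds.
#' @param w waiting-time thresholds, minutes.
#' @return List of two data frames, `queue` (`hour`, `k`, `prob`) and `wait`
#'   (`hour`, `w`, `prob`, `n`).
#' @export
hourly_queue_profiles <- function(result, k = c(0, 1, 2, 5, 10),
                                  w = c(1, 2, 5, 10, 15, 30)) {
  qc <- result$hourly$queue_counts
  if (is.null(qc) || sum(qc) == 0) stop_domain("no hourly series present")
  lens <- as.integer(colnames(qc))
  queue <- do.call(rbind, lapply(0:23, function(h) {
    tot <- sum(qc[h + 1, ])
    data.frame(hour = h, k = k,
               prob = vapply(k, function(kk) sum(qc[h + 1, lens <= kk]) / tot,
                             numeric(1)))
  }))
  waits <- result$hourly$waits
  wait <- do.call(rbind, lapply(0:23, function(h) {
    ww <- waits$wait[waits$hour == h]
    data.frame(hour = h, w = w,
               prob = if (length(ww)) {
                 vapply(w, function(x) mean(ww <= x), numeric(1))
               } else rep(NA_real_, length(w)),
               n = length(ww))
  }))
  list(queue = queue, wait = wait)
}

#' Service-pledge conformity by hour
#'
#' Flags, for every hour of day, whether the simulated operation meets the
#' two service pledges: at least an 85% chance that counseling is no more
#' than 10 minutes away, and an 85% chance that no more than one person is
#' waiting in line.
#'
#' @param result a `sim_result`.
#' @param wait_minutes,queue_max pledge thresholds.
#' @param prob required probability (default 0.85).
#' @return Data frame with `hour`, `p_wait`, `p_queue`, `wait_ok`,
#'   `queue_ok`. Hours with no queued-served users pass the wait pledge
#'   vacuously.
#' @export
pledge_check <- function(result, wait_minutes = 10, queue_max = 1,
                         prob = 0.85) {
  prof <- hourly_queue_profiles(result, k = queue_max, w = wait_minutes)
  p_wait <- prof$wait$prob
  p_queue <- prof$queue$prob
  data.frame(
    hour = 0:23,
    p_wait = p_wait,
    p_queue = p_queue,
    wait_ok = is.na(p_wait) | p_wait >= prob,
    queue_ok = p_queue >= prob
  )
}

#' Hourly dropout probability density
#'
#' All reneged cases pooled across replications, expressed as a discrete
#' probability density over the 24 hours of the day, plus cumulative
#' probabilities over requested windows.
#'
#' @param result a `sim_result`.
#' @param windows named list of `c(start_hour, end_hour)` half-open windows.
#' @return List: `density` (data frame `hour`, `p`), `mean_p`, `sd_p`,
#'   `n_reneged`, and `windows` (data frame with cumulative probability and
#'   the window's hourly mean/SD).
#' @export
dropout_density <- function(result,
                            windows = list(afternoon = c(14, 17),
                                           evening = c(19, 24))) {
  counts <- result$hourly$dropout_counts
  n <- sum(counts)
  if (n == 0) stop_domain("no reneged cases: dropout density undefined")
  p <- counts / n
  win <- do.call(rbind, lapply(names(windows), function(nm) {
    w <- windows[[nm]]
    hrs <- seq(w[1], w[2] - 1)
    data.frame(window = nm, start = w[1], end = w[2],
               cumulative = sum(p[hrs + 1]),
               hourly_mean = mean(p[hrs + 1]), hourly_sd = stats::sd(p[hrs + 1]))
  }))
  list(density = data.frame(hour = 0:23, p = p),
       mean_p = mean(p), sd_p = stats::sd(p), n_reneged = n, windows = win)
}

#' Hourly distribution of unused counseling capacity
#'
#' Unused capacity (scheduled on-duty slots minus occupied slots) is sampled
#' every simulated minute; this summarises its distribution per hour of day.
#'
#' @param result a `sim_result`.
#' @return List: `distribution` (data frame `hour`, `vacancy`, `prob`) and
#'   `by_hour` (data frame `hour`, `mean_vacancy`, `modal_vacancy`).
#' @export
vacancy_distribution <- function(result) {
  vc <- result$hourly$vacancy_counts
  vals <- as.integer(colnames(vc))
  dist <- do.call(rbind, lapply(0:23, function(h) {
    tot <- sum(vc[h + 1, ])
    data.frame(hour = h, vacancy = vals, prob = vc[h + 1, ] / tot)
  }))
  by_hour <- do.call(rbind, lapply(0:23, function(h) {
    row <- vc[h + 1, ]
    data.frame(hour = h,
               mean_vacancy = sum(vals * row) / sum(row),
               modal_vacancy = vals[which.max(row)])
  }))
  rownames(dist) <- NULL
  list(distribution = dist, by_hour = by_hour)
}

#' Cost-effectiveness point for a staffing scenario
#'
#' @param label scenario name.
#' @param shifts list of [shift()]s (cost and capacity are tallied from the
#'   scheduled staff) -- or pass `total_cost`/`total_capacity` directly.
#' @param failure_rate `1 - overall conversion rate` for the scenario.
#' @param total_cost,total_capacity direct values when no schedule is given.
#' @return An object of class `cost_effectiveness_point`.
#' @export
cost_effectiveness_point <- function(label, failure_rate, shifts = NULL,
                                     total_cost = NULL, total_capacity = NULL) {
  if (!is.null(shifts)) {
    s <- staffing_summary(shifts)
    total_cost <- s$total_cost
    total_capacity <- s$total_capacity
  }
  if (is.null(total_cost) || is.null(total_capacity) ||
      total_cost <= 0 || total_capacity <= 0) {
    stop_domain("staffed scenarios need positive cost and capacity")
  }
  structure(list(label = label, total_cost = total_cost,
                 total_capacity = total_capacity, failure_rate = failure_rate),
            class = "cost_effectiveness_point")
}

#' Cost and effectiveness curves with their intersection
#'
#' Both series are min-max normalised to a shared `[0, 1]` axis over the
#' evaluated capacity range (they carry unlike units), interpolated
#' piecewise-linearly over capacity, and the intersection of the rising cost
#' curve with the falling failure-rate curve is located by root finding on
#' the difference. The optimal worker combination sits at the intersection.
#'
#' @param points list of [cost_effectiveness_point()]s with distinct
#'   capacities (at least 2).
#' @return List: `curves` (data frame `capacity`, `cost`, `failure_rate`,
#'   `cost_norm`, `failure_norm`), `intersection_capacity` (`NA` if the
#'   curves never cross in range), `nearest` (label of the closest evaluated
#'   scenario).
#' @export
cost_effectiveness_curves <- function(points) {
  if (length(points) < 2) stop_domain("need at least 2 scenarios")
  df <- data.frame(
    label = vapply(points, `[[`, character(1), "label"),
    capacity = vapply(points, `[[`, numeric(1), "total_capacity"),
    cost = vapply(points, `[[`, numeric(1), "total_cost"),
    failure_rate = vapply(points, `[[`, numeric(1), "failure_rate")
  )
  if (anyDuplicated(df$capacity)) stop_domain("capacities must be distinct")
  df <- df[order(df$capacity), ]
  norm <- function(x) {
    if (max(x) == min(x)) rep(0.5, length(x)) else (x - min(x)) / (max(x) - min(x))
  }
  df$cost_norm <- norm(df$cost)
  df$failure_norm <- norm(df$failure_rate)
  fc <- stats::approxfun(df$capacity, df$cost_norm)
  ff <- stats::approxfun(df$capacity, df$failure_norm)
  g <- function(x) fc(x) - ff(x)
  xs <- df$capacity
  intersection <- NA_real_
  # a genuine trade-off crossing needs an interior sign change; shared
  # endpoints created by the normalisation itself do not count
  for (i in seq_len(nrow(df) - 1)) {
    g1 <- g(xs[i]); g2 <- g(xs[i + 1])
    if (is.na(g1) || is.na(g2)) next
    if (g1 == 0 && i > 1) { intersection <- xs[i]; break }
    if (g1 * g2 < 0) {
      intersection <- stats::uniroot(g, c(xs[i], xs[i + 1]))$root
      break
    }
  }
  nearest <- if (is.na(intersection)) NA_character_ else {
    df$label[which.min(abs(df$capacity - intersection))]
  }
  list(curves = df, intersection_capacity = intersection, nearest = nearest)
}

#' Repeat-user share of traffic
#'
#' When a demand forecast purges self-excited re-contacts, the excess of
#' observed arrivals over the forecast estimates the share of traffic
#' generated by repeat users: `(actual - forecast)/actual`.
#'
#' @param actual_arrivals observed arrival count, `> 0`.
#' @param forecast_expected forecast expected arrivals, `>= 0`.
#' @return List with `share` and `status` (`"ok"`, or
#'   `"forecast_exceeds_actual"` with a warning when the share is negative).
#' @export
repeat_share <- function(actual_arrivals, forecast_expected) {
  if (actual_arrivals <= 0) stop_domain("actual arrivals must be positive")
  if (forecast_expected < 0) stop_domain("forecast must be nonnegative")
  share <- (actual_arrivals - forecast_expected) / actual_arrivals
  status <- "ok"
  if (share < 0) {
    status <- "forecast_exceeds_actual"
    warning("forecast exceeds actual arrivals; repeat share is negative")
  }
  list(share = share, status = status)
}

#' Column percentages of a contingency table
#'
#' @param table matrix of nonnegative counts (rows = categories, columns =
#'   groups).
#' @param digits decimals for half-up rounding at the reporting boundary.
#' @return List: `percent` (rounded column percentages), `exact` (full
#'   precision), `undefined_columns` (zero-total columns, flagged).
#' @export
contingency_proportions <- function(table, digits = 2) {
  m <- as.matrix(table)
  if (any(m < 0)) stop_domain("counts must be nonnegative")
  tot <- colSums(m)
  undef <- which(tot == 0)
  exact <- sweep(m, 2, ifelse(tot == 0, NA, tot), "/") * 100
  list(percent = round_half_up(exact, digits), exact = exact,
       undefined_columns = colnames(m)[undef] %||% undef)
}

#' Saturation flag for a scenario ladder
#'
#' Scenarios sorted by capacity are scanned for the point beyond which the
#' failure rate improves by less than `threshold` percentage points per added
#' counselor -- further hires mostly add idle capacity.
#'
#' @param points list of [cost_effectiveness_point()]s.
#' @param counselors number of counselors per scenario (same order).
#' @param threshold percentage points per counselor (default 0.5).
#' @return Data frame per scenario with `saturated` flags (first scenario
#'   `NA`).
#' @export
saturation_flags <- function(points, counselors, threshold = 0.5) {
  df <- data.frame(
    label = vapply(points, `[[`, character(1), "label"),
    capacity = vapply(points, `[[`, numeric(1), "total_capacity"),
    failure_rate = vapply(points, `[[`, numeric(1), "failure_rate"),
    counselors = counselors
  )
  df <- df[order(df$capacity), ]
  gain <- c(NA, -diff(df$failure_rate) * 100 / pmax(diff(df$counselors), 1))
  df$improvement_pp_per_counselor <- gain
  df$saturated <- !is.na(gain) & gain < threshold
  df
}
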