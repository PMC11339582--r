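# The discrete-event simulator of the counseling floor: FIFO case queue with
# reneging, multi-role overlapping shifts with per-counselor simultaneous-chat
# capacity, risk-dependent beta durations, zero-wait accounting, zombie
# semantics, post-chat survey overhead and bootstrap replication.

#' Round-robin arrival times from an empirical interarrival list
#'
#' Cumulative sums cycle through the (optionally reshuffled) interarrival
#' list until the running clock first reaches the horizon; events strictly
#' beyond the horizon are excluded. This recycling tops up the stream with a
#' few extra cases so a 30-day empirical sample exactly covers the 43,200
#' simulated minutes.
#'
#' @param interarrivals positive interarrival times in minutes.
#' @param horizon_minutes simulation span.
#' @param shuffle permute the list first (default `FALSE`; the bootstrap
#'   shuffles per replication).
#' @return Arrival times in minutes, the last one `>= horizon` only if equal
#'   to it.
#' @export
empirical_roundrobin_arrivals <- function(interarrivals, horizon_minutes,
                                          shuffle = FALSE) {
  if (!length(interarrivals) || any(interarrivals <= 0)) {
    stop_domain("interarrivals must be positive")
  }
  ia <- if (shuffle) sample(interarrivals) else interarrivals
  total <- sum(ia)
  n_cycles <- ceiling(horizon_minutes / total) + 1
  t <- cumsum(rep.int(ia, n_cycles))
  cut <- which(t >= horizon_minutes)[1]
  t <- t[seq_len(if (is.na(cut)) length(t) else cut)]
  t[t <= horizon_minutes]
}

# Draw arrival times for one replication from the configured source.
draw_arrivals <- function(config) {
  src <- config$arrivals
  switch(src$type,
    nhpp = sample_nhpp(src$rate_fn, config$horizon_minutes)$time,
    empirical_roundrobin = empirical_roundrobin_arrivals(
      src$interarrivals, config$horizon_minutes, shuffle = src$shuffle %||% TRUE),
    hawkes = sample_hawkes(src$base_fn, src$kernel, config$horizon_minutes)$time,
    stop_domain("unknown arrival source: ", src$type)
  )
}

#' Run one simulation replication
#'
#' Event-driven execution: arrivals enter from the configured source;
#' TOS-rejecting visitors exit immediately; accepters join a single FIFO case
#' queue; a free on-duty counselor slot always dequeues the head case. A case
#' picked up within the zero-wait window counts as served immediately.
#' Queued users renege after an exponential patience draw; with
#' `zombie_eviction = FALSE` the reneged case *remains in the case queue* and,
#' when eventually assigned, consumes only the post-chat survey time; with
#' eviction it vanishes. Served cases draw a risk level, then a beta duration
#' for their (user type, risk) stratum scaled by `duration_scale`, followed
#' by the survey overhead. Counselors respect concurrent capacity, shift and
#' break windows (no new assignments off duty; in-progress chats finish).
#' Simultaneous events are resolved service-completion first, then reneges,
#' then arrivals. Deterministic given `seed`.
#'
#' @param config a [scenario_config()].
#' @param seed integer replication seed.
#' @param keep_log also return the replication event log as a [chat_log()].
#' @return An object of class `sim_run`: `tallies` (named vector:
#'   `arrivals`, `tos_accepted`, `served_immediately`, `served_after_queue`,
#'   `reneged`, `in_system_at_horizon`), `hourly` aggregates, and optionally
#'   `log`.
#' @export
run_replication <- function(config, seed = config$seed, keep_log = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  roster <- expand_roster(config$shifts, config$horizon_minutes)
  with_seed(seed, sim_one(config, roster, keep_log = keep_log))
}

sim_one <- function(config, roster, keep_log = FALSE) {
  horizon <- config$horizon_minutes
  window_min <- config$zero_wait_window_s / 60
  survey <- config$survey_minutes
  evict <- config$zombie_eviction

  arr_all <- draw_arrivals(config)
  n_all <- length(arr_all)
  tos <- stats::runif(n_all) < config$tos_p

  a <- arr_all[tos]
  n <- length(a)
  utypes <- USER_TYPE_LEVELS
  user_type <- ifelse(stats::runif(n) < config$user_type_p, "nonrepeat", "repeat")
  risk <- character(n)
  dur <- numeric(n)
  pat <- numeric(n)
  for (t in utypes) {
    i <- which(user_type == t)
    if (!length(i)) next
    risk[i] <- sample(RISK_LEVELS, length(i), replace = TRUE,
                      prob = config$risk_mix[[t]])
    pat[i] <- rpatience(config$patience[[t]], length(i))
    for (r in RISK_LEVELS) {
      j <- i[risk[i] == r]
      if (length(j)) {
        dur[j] <- rduration(config$durations[[t]][[r]], length(j),
                            scale_factor = config$duration_scale)
      }
    }
  }
  renege_at <- a + pat

  # counselor state
  nc <- length(roster)
  cap <- vapply(roster, `[[`, numeric(1), "capacity")
  active <- integer(nc)
  on <- logical(nc)
  # boundary events: (time, counselor, +1/-1)
  bt <- numeric(0); bc <- integer(0); bd <- integer(0)
  for (ci in seq_len(nc)) {
    iv <- roster[[ci]]$intervals
    bt <- c(bt, iv[, 1], iv[, 2])
    bc <- c(bc, rep.int(ci, 2 * nrow(iv)))
    bd <- c(bd, rep.int(1L, nrow(iv)), rep.int(-1L, nrow(iv)))
  }
  ob <- order(bt, bd)  # per-counselor flags are independent; off first at ties
  bt <- bt[ob]; bc <- bc[ob]; bd <- bd[ob]
  nB <- length(bt)

  # pending slot releases (bounded by total concurrent capacity)
  K <- sum(cap) + 1L
  rel_t <- rep(Inf, K)
  rel_c <- integer(K)

  # case state
  pickup <- rep(NA_real_, n)
  zombie <- logical(n)
  csl <- rep(NA_integer_, n)
  queue <- integer(n)
  qhead <- 1L; qtail <- 0L

  ia <- 1L; ib <- 1L
  repeat {
    ta <- if (ia <= n) a[ia] else Inf
    tr <- min(rel_t)
    tb <- if (ib <= nB) bt[ib] else Inf
    now <- min(ta, tr, tb)
    if (now > horizon || now == Inf) break
    # service completions first
    while (min(rel_t) <= now) {
      j <- which.min(rel_t)
      active[rel_c[j]] <- active[rel_c[j]] - 1L
      rel_t[j] <- Inf
    }
    while (ib <= nB && bt[ib] <= now) {
      on[bc[ib]] <- bd[ib] > 0L
      ib <- ib + 1L
    }
    while (ia <= n && a[ia] <= now) {
      qtail <- qtail + 1L
      queue[qtail] <- ia
      ia <- ia + 1L
    }
    # assign from the head of the FIFO case queue while slots are free
    while (qhead <= qtail) {
      i <- queue[qhead]
      if (evict && renege_at[i] <= now) {
        qhead <- qhead + 1L
        next
      }
      avail <- which(on & active < cap)
      if (!length(avail)) break
      c_pick <- avail[which.min(active[avail])]
      qhead <- qhead + 1L
      pickup[i] <- now
      csl[i] <- c_pick
      active[c_pick] <- active[c_pick] + 1L
      slot <- which.max(rel_t)  # an Inf (free) slot always exists
      rel_c[slot] <- c_pick
      if (renege_at[i] <= now) {
        zombie[i] <- TRUE   # user already gone: survey filing only
        rel_t[slot] <- now + survey
      } else {
        rel_t[slot] <- now + dur[i] + survey
      }
    }
  }

  served <- !is.na(pickup) & !zombie
  reneged <- zombie | (is.na(pickup) & renege_at <= horizon)
  in_system <- !served & !reneged
  wait <- pickup - a
  # classify on the 1-second system clock so serialized logs reproduce the
  # same zero-wait split exactly
  wait_clock <- (round(pickup * 60) - round(a * 60)) / 60
  served_imm <- served & wait_clock <= window_min
  served_q <- served & !served_imm

  tallies <- c(
    arrivals = n_all,
    tos_accepted = n,
    served_immediately = sum(served_imm),
    served_after_queue = sum(served_q),
    reneged = sum(reneged),
    in_system_at_horizon = sum(in_system)
  )

  hourly <- hourly_aggregates(a, pickup, renege_at, served, reneged, zombie,
                              wait, served_q, csl, dur, roster, cap, horizon,
                              survey)

  out <- list(tallies = tallies, hourly = hourly,
              horizon = horizon, n_counselors = nc)
  if (keep_log) {
    endt <- rep(NA_real_, n)
    endt[served] <- pickup[served] + dur[served]
    endt[zombie] <- pickup[zombie]
    ren <- rep(NA_real_, n)
    ren[reneged] <- renege_at[reneged]
    acc_idx <- which(tos)
    full <- function(x, default = NA_real_) {
      v <- rep(default, n_all); v[acc_idx] <- x; v
    }
    out$log <- chat_log(
      user_id = sprintf("u%07d", seq_len(n_all)),
      channel = rep("web", n_all),
      arrival_ts = minutes_to_ts(arr_all),
      tos_accepted = tos,
      user_type = full(user_type, NA_character_),
      pickup_ts = minutes_to_ts(full(pickup)),
      end_ts = minutes_to_ts(full(endt)),
      renege_ts = minutes_to_ts(full(ren)),
      risk_level = full(ifelse(served, risk, NA_character_), NA_character_),
      counselor_id = full(ifelse(is.na(csl), NA_character_,
                                 sprintf("c%02d", csl)), NA_character_),
      validate = FALSE
    )
    out$case_detail <- data.frame(
      arrival = a, pickup = pickup, wait = wait, renege_at = renege_at,
      served = served, zombie = zombie, user_type = user_type, risk = risk
    )
  }
  class(out) <- "sim_run"
  out
}

# Per-replication hour-of-day aggregates sampled on the 1-minute grid.
hourly_aggregates <- function(a, pickup, renege_at, served, reneged, zombie,
                              wait, served_q, csl, dur, roster, cap, horizon,
                              survey) {
  # sample at the start of each minute: [0, horizon), matching the
  # half-open [start, end) duty windows
  grid <- 0:(horizon - 1)
  hour_of <- function(t) floor((t %% MINUTES_PER_DAY) / 60)
  grid_hour <- hour_of(grid)

  # user queue length: accepted users waiting (not yet picked up / reneged)
  exits <- ifelse(served, pickup, ifelse(reneged, renege_at, horizon + 1))
  qlen <- findInterval(grid, sort(a)) - findInterval(grid, sort(exits))
  QCAP <- 80L
  qlen <- pmin(qlen, QCAP)
  queue_counts <- matrix(0L, 24, QCAP + 1,
                         dimnames = list(0:23, 0:QCAP))
  tb <- table(factor(grid_hour, 0:23), factor(qlen, 0:QCAP))
  queue_counts[] <- queue_counts + unclass(tb)

  # unused on-duty capacity, sampled each minute
  occ <- matrix(0L, horizon, length(roster))
  starts <- pickup[!is.na(pickup)]
  ends <- ifelse(zombie, pickup + survey, pickup + dur + survey)[!is.na(pickup)]
  who <- csl[!is.na(pickup)]
  for (ci in unique(who)) {
    s <- sort(starts[who == ci])
    e <- sort(ends[who == ci])
    occ[, ci] <- findInterval(grid, s) - findInterval(grid, e)
  }
  vac <- numeric(horizon)
  for (ci in seq_along(roster)) {
    iv <- roster[[ci]]$intervals
    on <- findInterval(grid, iv[, 1]) - findInterval(grid, iv[, 2])
    vac <- vac + on * pmax(cap[ci] - occ[, ci], 0)
  }
  VCAP <- as.integer(sum(cap))
  vacancy_counts <- matrix(0L, 24, VCAP + 1, dimnames = list(0:23, 0:VCAP))
  tb <- table(factor(grid_hour, 0:23), factor(pmin(vac, VCAP), 0:VCAP))
  vacancy_counts[] <- vacancy_counts + unclass(tb)

  dropout_counts <- as.integer(table(factor(hour_of(renege_at[reneged]), 0:23)))

  qw <- which(served_q)
  waits <- data.frame(hour = hour_of(a[qw]), wait = wait[qw])

  list(queue_counts = queue_counts, vacancy_counts = vacancy_counts,
       dropout_counts = dropout_counts, waits = waits)
}

#' Bootstrap a scenario
#'
#' Runs `replications` independent replications with seeds derived from the
#' master seed, collecting per-replication tallies and pooling the hourly
#' aggregates. For each statistic the mean and a 2.5/97.5 percentile envelope
#' (lower/average/upper bound) across replications are reported.
#'
#' @param config a [scenario_config()].
#' @param replications overrides `config$replications`.
#' @param seed overrides `config$seed`.
#' @param keep_first_log retain the event log of the first replication.
#' @return An object of class `sim_result` with `tallies` (one row per
#'   replication, including the overall conversion rate), `summary`
#'   (mean/lower/upper per statistic), pooled `hourly` aggregates, and the
#'   config.
#' @export
run_bootstrap <- function(config, replications = config$replications,
                          seed = config$seed, keep_first_log = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  roster <- expand_roster(config$shifts, config$horizon_minutes)
  seeds <- derive_seeds(seed, replications)
  tal <- matrix(0, replications, 6)
  colnames(tal) <- c("arrivals", "tos_accepted", "served_immediately",
                     "served_after_queue", "reneged", "in_system_at_horizon")
  queue_counts <- NULL
  vacancy_counts <- NULL
  dropout_counts <- rep(0L, 24)
  waits <- vector("list", replications)
  first_log <- NULL
  for (r in seq_len(replications)) {
    run <- with_seed(seeds[r],
                     sim_one(config, roster, keep_log = keep_first_log && r == 1))
    tal[r, ] <- run$tallies
    h <- run$hourly
    queue_counts <- if (is.null(queue_counts)) h$queue_counts else queue_counts + h$queue_counts
    vacancy_counts <- if (is.null(vacancy_counts)) h$vacancy_counts else vacancy_counts + h$vacancy_counts
    dropout_counts <- dropout_counts + h$dropout_counts
    waits[[r]] <- h$waits
    if (keep_first_log && r == 1) first_log <- run$log
  }
  tal <- as.data.frame(tal)
  tal$conversion <- (tal$served_immediately + tal$served_after_queue) /
    pmax(tal$arrivals, 1)
  stats_cols <- names(tal)
  summ <- do.call(rbind, lapply(stats_cols, function(s) {
    x <- tal[[s]]
    data.frame(statistic = s, mean = mean(x),
               lower = unname(stats::quantile(x, 0.025)),
               upper = unname(stats::quantile(x, 0.975)))
  }))
  structure(
    list(tallies = tal, summary = summ,
         hourly = list(queue_counts = queue_counts,
                       vacancy_counts = vacancy_counts,
                       dropout_counts = dropout_counts,
                       waits = do.call(rbind, waits)),
         config = config, replications = replications,
         horizon = config$horizon_minutes, first_log = first_log),
    class = "sim_result"
  )
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d replications x %s min\n", x$replications,
              format(x$horizon)))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
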