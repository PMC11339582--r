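# Scenario configuration: staffing roles, shifts, behavioural switches and
# arrival sources for the discrete-event simulator.

ROLE_DEFAULTS <- list(
  duty_officer = list(capacity = 1L, cost = 3),
  full_time = list(capacity = 3L, cost = 2),
  volunteer = list(capacity = 2L, cost = 1.5)
)

#' Counselor specification
#'
#' @param role `"duty_officer"`, `"full_time"` or `"volunteer"`. Defaults per
#'   role: concurrent capacity 1/3/2 and cost weight 3/2/1.5 (duty officers
#'   oversee the floor and take at-risk users one at a time; full-timers run
#'   several chats concurrently; volunteers sit in between).
#' @param capacity max simultaneous chats, `>= 1` (default per role).
#' @param cost decimal cost weight (default per role).
#' @return An object of class `counselor_spec`.
#' @export
counselor_spec <- function(role = c("duty_officer", "full_time", "volunteer"),
                           capacity = NULL, cost = NULL) {
  role <- match.arg(role)
  capacity <- as.integer(capacity %||% ROLE_DEFAULTS[[role]]$capacity)
  cost <- cost %||% ROLE_DEFAULTS[[role]]$cost
  if (capacity < 1) stop_domain("capacity must be >= 1")
  structure(list(role = role, capacity = capacity, cost = cost),
            class = "counselor_spec")
}

#' Work shift
#'
#' A daily recurring staffed window. Shifts may overlap and may wrap past
#' midnight (`end_hour <= start_hour`). During a break a counselor accepts no
#' new cases; chats in progress always run to completion.
#'
#' @param start_hour,end_hour shift window, fractional hours of day in
#'   `[0, 24]`.
#' @param staff list of [counselor_spec()]s.
#' @param breaks optional list, one element per staff member, each a list of
#'   `c(start_hour, end_hour)` break windows (or `NULL`).
#' @return An object of class `shift`.
#' @export
shift <- function(start_hour, end_hour, staff, breaks = NULL) {
  if (start_hour < 0 || start_hour > 24 || end_hour < 0 || end_hour > 24) {
    stop_domain("shift hours must lie in [0, 24]")
  }
  if (!length(staff)) stop_domain("a shift needs at least one staff member")
  if (!all(vapply(staff, inherits, logical(1), "counselor_spec"))) {
    stop_domain("staff must be counselor_spec objects")
  }
  if (!is.null(breaks) && length(breaks) != length(staff)) {
    stop_domain("breaks must have one entry (possibly NULL) per staff member")
  }
  structure(list(start_hour = start_hour, end_hour = end_hour, staff = staff,
                 breaks = breaks),
            class = "shift")
}

#' Total staffing cost and capacity of a schedule
#'
#' Cost is the sum of cost weights over all scheduled staff; capacity is the
#' total maximum number of simultaneous chat processes across the shifts.
#'
#' @param shifts list of [shift()]s.
#' @return List with `n_counselors`, `total_cost`, `total_capacity`.
#' @export
staffing_summary <- function(shifts) {
  staff <- unlist(lapply(shifts, `[[`, "staff"), recursive = FALSE)
  list(
    n_counselors = length(staff),
    total_cost = sum(vapply(staff, `[[`, numeric(1), "cost")),
    total_capacity = sum(vapply(staff, `[[`, numeric(1), "capacity"))
  )
}

#' Reconstructed base-case schedule
#'
#' A documented reconstruction of the studied operation's four-shift,
#' 15-counselor roster (the published account states the head count and the
#' at-least-8 shift-wide capacity but not the timetable): overnight
#' 00:00-09:00 and day 09:00-14:00 shifts of one duty officer, one full-time
#' counselor and two volunteers each (capacity 8); a day-shift meal window
#' with staggered 11:00-11:30/11:30-12:00 breaks; an afternoon 14:00-19:00
#' shift whose two volunteers start at the 17:00 handover; and an evening
#' 19:00-24:00 shift of three full-time counselors (capacity 9), one of whom
#' assumes the duty-officer role. Fully overridable: build your own list of
#' [shift()]s to replace it.
#'
#' @return A list of [shift()]s.
#' @export
base_case_schedule <- function() {
  d <- counselor_spec("duty_officer")
  f <- counselor_spec("full_time")
  v <- counselor_spec("volunteer")
  list(
    shift(0, 9, list(d, f, v, v)),
    shift(9, 14, list(d, f, v, v),
          breaks = list(list(c(11.5, 12)), list(c(11, 11.5)),
                        list(c(11, 11.5)), list(c(11.5, 12)))),
    shift(14, 19, list(d, f)),
    shift(17, 19, list(v, v)),
    shift(19, 24, list(f, f, f))
  )
}

#' Scenario configuration for the simulator
#'
#' @param shifts list of [shift()]s.
#' @param arrivals arrival source: one of [arrivals_nhpp()],
#'   [arrivals_roundrobin()], [arrivals_hawkes()].
#' @param params a [ground_truth_params()] or fitted `parameter_set`
#'   supplying `tos_p`, `user_type_p`, `risk_mix`, `durations`, `patience`.
#' @param horizon_minutes simulated span (default 43,200 = 30 days).
#' @param duration_scale multiplier on all service durations (default 1;
#'   e.g. `40 / fitted low-risk mean` models a standardized 40-minute basic
#'   service time).
#' @param zombie_eviction if `FALSE` (default) a reneged case stays in the
#'   case queue and, once assigned, consumes only the post-chat survey time;
#'   if `TRUE` reneged cases vanish from the queue.
#' @param zero_wait_window_s pickups within this window count as zero-wait
#'   (default 60 seconds).
#' @param survey_minutes post-chat survey overhead per handled case
#'   (default 5).
#' @param replications bootstrap replications (default 1500).
#' @param seed master seed.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(shifts, arrivals, params,
                            horizon_minutes = 43200, duration_scale = 1,
                            zombie_eviction = FALSE, zero_wait_window_s = 60,
                            survey_minutes = 5, replications = 1500,
                            seed = 1L) {
  if (horizon_minutes <= 0) stop_domain("horizon_minutes must be positive")
  if (duration_scale <= 0) stop_domain("duration_scale must be positive")
  if (replications < 1) stop_domain("replications must be >= 1")
  if (!length(shifts)) stop_domain("at least one staffed shift is required")
  tos_p <- params$tos_p %||% params$tos$p
  structure(
    list(shifts = shifts, arrivals = arrivals,
         tos_p = tos_p, user_type_p = params$user_type_p,
         risk_mix = params$risk_mix, durations = params$durations,
         patience = params$patience,
         horizon_minutes = horizon_minutes, duration_scale = duration_scale,
         zombie_eviction = zombie_eviction,
         zero_wait_window_s = zero_wait_window_s,
         survey_minutes = survey_minutes, replications = replications,
         seed = seed),
    class = "scenario_config"
  )
}

#' Arrival sources
#'
#' `arrivals_nhpp()` draws a fresh nonhomogeneous Poisson realisation per
#' replication; `arrivals_roundrobin()` recycles an empirical interarrival
#' list (reshuffled per replication); `arrivals_hawkes()` layers
#' self-excited repeat re-contacts on an NHPP base.
#'
#' @param rate_fn,base_fn a [rate_function()].
#' @param interarrivals positive interarrival times in minutes.
#' @param kernel a [hawkes_kernel()].
#' @param shuffle reshuffle the empirical list each replication (default).
#' @return An arrival-source descriptor.
#' @name arrival_sources
NULL

#' @rdname arrival_sources
#' @export
arrivals_nhpp <- function(rate_fn) {
  stopifnot(inherits(rate_fn, "rate_function"))
  list(type = "nhpp", rate_fn = rate_fn)
}

#' @rdname arrival_sources
#' @export
arrivals_roundrobin <- function(interarrivals, shuffle = TRUE) {
  if (!length(interarrivals) || any(interarrivals <= 0)) {
    stop_domain("interarrivals must be a nonempty positive vector")
  }
  list(type = "empirical_roundrobin", interarrivals = interarrivals,
       shuffle = shuffle)
}

#' @rdname arrival_sources
#' @export
arrivals_hawkes <- function(base_fn, kernel) {
  stopifnot(inherits(base_fn, "rate_function"), inherits(kernel, "hawkes_kernel"))
  list(type = "hawkes", base_fn = base_fn, kernel = kernel)
}

#' Write a staffing/scenario configuration to a structured text file
#'
#' Serialises the schedule and behavioural switches (not the fitted
#' distributions, which live in a parameter-set file, nor the arrival
#' source, which is data). Schema: top-level scalars `horizon_minutes`,
#' `duration_scale`, `zombie_eviction`, `zero_wait_window_s`,
#' `survey_minutes`, `replications`, `seed`, and `shifts`, a list of
#' `{start_hour, end_hour, staff: [{role, capacity, cost}], breaks}` entries.
#'
#' @param config a [scenario_config()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  ser_shift <- function(sh) {
    list(
      start_hour = sh$start_hour, end_hour = sh$end_hour,
      staff = lapply(sh$staff, function(s) {
        list(role = s$role, capacity = s$capacity, cost = s$cost)
      }),
      breaks = if (is.null(sh$breaks)) NULL else {
        lapply(sh$breaks, function(b) {
          if (is.null(b)) list() else lapply(b, as.numeric)
        })
      }
    )
  }
  obj <- list(
    horizon_minutes = config$horizon_minutes,
    duration_scale = config$duration_scale,
    zombie_eviction = config$zombie_eviction,
    zero_wait_window_s = config$zero_wait_window_s,
    survey_minutes = config$survey_minutes,
    replications = config$replications,
    seed = config$seed,
    shifts = lapply(config$shifts, ser_shift)
  )
  yaml::write_yaml(obj, path, precision = 12)
  invisible(path)
}

#' Read a scenario configuration file
#'
#' Inverse of [write_scenario_config()]. The arrival source and parameter
#' set are supplied separately (they are data, not configuration).
#'
#' @param path YAML path written by [write_scenario_config()].
#' @param arrivals an arrival source (see [arrival_sources]).
#' @param params a [ground_truth_params()] or fitted `parameter_set`.
#' @return A [scenario_config()].
#' @export
read_scenario_config <- function(path, arrivals, params) {
  obj <- yaml::read_yaml(path)
  shifts <- lapply(obj$shifts, function(sh) {
    staff <- lapply(sh$staff, function(s) {
      counselor_spec(s$role, capacity = s$capacity, cost = s$cost)
    })
    breaks <- if (is.null(sh$breaks)) NULL else {
      lapply(sh$breaks, function(b) {
        if (!length(b)) NULL else lapply(b, function(w) as.numeric(unlist(w)))
      })
    }
    shift(sh$start_hour, sh$end_hour, staff, breaks = breaks)
  })
  scenario_config(
    shifts = shifts, arrivals = arrivals, params = params,
    horizon_minutes = obj$horizon_minutes %||% 43200,
    duration_scale = obj$duration_scale %||% 1,
    zombie_eviction = obj$zombie_eviction %||% FALSE,
    zero_wait_window_s = obj$zero_wait_window_s %||% 60,
    survey_minutes = obj$survey_minutes %||% 5,
    replications = obj$replications %||% 1500,
    seed = obj$seed %||% 1L
  )
}

# --- roster expansion -------------------------------------------------------

# Daily on-duty windows (minutes of day) for one staff slot: the shift window
# minus breaks; windows wrapping midnight are split.
daily_windows <- function(start_hour, end_hour, breaks) {
  s <- start_hour * 60
  e <- end_hour * 60
  wins <- if (e > s) list(c(s, e)) else list(c(s, MINUTES_PER_DAY), c(0, e))
  if (!is.null(breaks)) {
    for (b in breaks) {
      bs <- b[1] * 60; be <- b[2] * 60
      out <- list()
      for (w in wins) {
        if (be <= w[1] || bs >= w[2]) { out <- c(out, list(w)); next }
        if (bs > w[1]) out <- c(out, list(c(w[1], bs)))
        if (be < w[2]) out <- c(out, list(c(be, w[2])))
      }
      wins <- out
    }
  }
  wins
}

# Expand the schedule over the horizon: one entry per counselor with on-duty
# interval matrix [start, end) in simulation minutes.
expand_roster <- function(shifts, horizon) {
  n_days <- ceiling(horizon / MINUTES_PER_DAY)
  roster <- list()
  cid <- 0
  for (sh in shifts) {
    for (k in seq_along(sh$staff)) {
      cid <- cid + 1
      spec <- sh$staff[[k]]
      wins <- daily_windows(sh$start_hour, sh$end_hour,
                            if (is.null(sh$breaks)) NULL else sh$breaks[[k]])
      iv <- do.call(rbind, lapply(seq_len(n_days) - 1, function(d) {
        do.call(rbind, lapply(wins, function(w) w + d * MINUTES_PER_DAY))
      }))
      iv <- iv[iv[, 1] < horizon, , drop = FALSE]
      iv[, 2] <- pmin(iv[, 2], horizon)
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      # merge contiguous windows (e.g. a 24h shift rolling over midnight)
      if (nrow(iv) > 1) {
        keep_s <- iv[1, 1]; merged <- NULL; cur <- iv[1, ]
        for (r in 2:nrow(iv)) {
          if (iv[r, 1] <= cur[2]) {
            cur[2] <- max(cur[2], iv[r, 2])
          } else {
            merged <- rbind(merged, cur)
            cur <- iv[r, ]
          }
        }
        iv <- unname(rbind(merged, cur))
      }
      roster[[cid]] <- list(id = sprintf("c%02d", cid), role = spec$role,
                            capacity = spec$capacity, cost = spec$cost,
                            intervals = iv)
    }
  }
  roster
}

# Scheduled total concurrent capacity at each minute mark 0..horizon-1.
scheduled_capacity <- function(roster, horizon) {
  grid <- 0:(horizon - 1)
  cap <- numeric(horizon)
  for (r in roster) {
    on <- findInterval(grid, r$intervals[, 1]) - findInterval(grid, r$intervals[, 2])
    cap <- cap + r$capacity * on
  }
  cap
}
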