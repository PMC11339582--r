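# Stochastic arrival-stream generators: nonhomogeneous Poisson sampling by
# thinning, Bernoulli TOS splitting, and a self-exciting (Hawkes) cluster
# process for repeat-user re-contacts.

new_arrival_stream <- function(time = numeric(), identity = character(),
                               lineage = character(), parent_time = numeric()) {
  data.frame(time = time, identity = identity, lineage = lineage,
             parent_time = parent_time, stringsAsFactors = FALSE)
}

#' Sample a nonhomogeneous Poisson process by thinning
#'
#' Lewis-Shedler thinning: candidate points are generated from a homogeneous
#' Poisson process at the dominating rate `lambda* = max(lambda(t))` and each
#' candidate at time `t` is retained independently with probability
#' `lambda(t)/lambda*`. The retained points are an exact NHPP realisation of
#' the target intensity.
#'
#' @param rate_fn a [rate_function()] giving `lambda(t)` per minute.
#' @param t_end horizon in minutes, `> 0`.
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @return An arrival stream: data frame with columns `time` (minutes),
#'   `identity`, `lineage` (all `"immigrant"`), `parent_time` (`NA`).
#' @export
sample_nhpp <- function(rate_fn, t_end, seed = NULL) {
  stopifnot(inherits(rate_fn, "rate_function"))
  if (!is.finite(t_end) || t_end <= 0) stop_domain("t_end must be positive and finite")
  lam_star <- rate_fn$max_rate
  if (!is.finite(lam_star)) stop_domain("dominating rate must be finite")
  with_seed(seed, {
    times <- thin_candidates(rate_fn, lam_star, t_end)
    new_arrival_stream(
      time = times,
      identity = sprintf("u%07d", seq_along(times)),
      lineage = rep("immigrant", length(times)),
      parent_time = rep(NA_real_, length(times))
    )
  })
}

# Candidate generation + acceptance; chunked so long horizons do not draw
# one exponential at a time.
thin_candidates <- function(rate_fn, lam_star, t_end) {
  if (lam_star <= RATE_FLOOR * (1 + 1e-9)) {
    # intensity is (numerically) zero everywhere
    vals <- rate_at(rate_fn, seq(0, t_end, length.out = 257))
    if (max(vals) <= RATE_FLOOR * (1 + 1e-9)) return(numeric())
  }
  times <- numeric()
  t <- 0
  expected <- lam_star * t_end
  repeat {
    n_chunk <- max(64L, ceiling(expected - lam_star * t) + 4L *
                     ceiling(sqrt(expected + 1)))
    gaps <- stats::rexp(n_chunk, rate = lam_star)
    cand <- t + cumsum(gaps)
    u <- stats::runif(n_chunk)
    done <- cand > t_end
    if (any(done)) {
      keep <- which(!done)
      cand <- cand[keep]
      u <- u[keep]
      lam <- rate_at(rate_fn, cand)
      if (any(lam > lam_star * (1 + 1e-8))) {
        stop("internal error: intensity exceeds the dominating rate")
      }
      times <- c(times, cand[u < lam / lam_star])
      return(times)
    }
    lam <- rate_at(rate_fn, cand)
    if (any(lam > lam_star * (1 + 1e-8))) {
      stop("internal error: intensity exceeds the dominating rate")
    }
    times <- c(times, cand[u < lam / lam_star])
    t <- cand[length(cand)]
  }
}

#' Split an arrival stream by the terms-of-service gate
#'
#' Marks each arrival with an independent Bernoulli(`p`) TOS decision. By the
#' thinning property of the Poisson process, the accepted substream is itself
#' an NHPP with intensity `p * lambda(t)`.
#'
#' @param events an arrival stream (data frame with a `time` column).
#' @param p acceptance probability in `[0, 1]`.
#' @param seed integer seed or `NULL`.
#' @return `events` with a logical `tos_accepted` column added.
#' @export
split_tos <- function(events, p, seed = NULL) {
  if (!is.numeric(p) || p < 0 || p > 1) stop_domain("p must lie in [0, 1]")
  with_seed(seed, {
    events$tos_accepted <- stats::runif(nrow(events)) < p
    events
  })
}

#' Hawkes memory kernel
#'
#' Exponential self-excitation kernel
#' `phi(u) = branching_ratio * decay_rate * exp(-decay_rate * u)`, whose
#' integral equals the branching ratio (expected offspring per event).
#' Subcriticality (`branching_ratio < 1`) keeps the cluster cascade finite.
#'
#' @param branching_ratio expected offspring per event, in `[0, 1)`.
#' @param decay_rate kernel decay per minute, `> 0`.
#' @return An object of class `hawkes_kernel`.
#' @export
hawkes_kernel <- function(branching_ratio, decay_rate) {
  if (branching_ratio < 0 || branching_ratio >= 1) {
    stop_domain("branching_ratio must lie in [0, 1): the process must be subcritical")
  }
  if (decay_rate <= 0) stop_domain("decay_rate must be positive")
  structure(list(branching_ratio = branching_ratio, decay_rate = decay_rate),
            class = "hawkes_kernel")
}

#' Sample a Hawkes process by cluster construction
#'
#' Immigrants are drawn from the nonhomogeneous base intensity via
#' [sample_nhpp()]; every event then spawns `Poisson(branching_ratio)`
#' offspring at independent exponential forward lags, recursively, until the
#' cascade dies out. Offspring inherit the identifier of their root
#' immigrant, emulating repeat re-contacts from the same user. Events beyond
#' `t_end` are discarded.
#'
#' @param base_fn a [rate_function()]: immigrant intensity `lambda_0(t)`.
#' @param kernel a [hawkes_kernel()].
#' @param t_end horizon in minutes.
#' @param seed integer seed or `NULL`.
#' @return An arrival stream sorted by time with `lineage` in
#'   `{"immigrant","offspring"}` and `parent_time` set for offspring.
#' @export
sample_hawkes <- function(base_fn, kernel, t_end, seed = NULL) {
  stopifnot(inherits(kernel, "hawkes_kernel"))
  with_seed(seed, {
    stream <- sample_nhpp(base_fn, t_end)
    gen_time <- stream$time
    gen_root <- stream$identity
    all <- stream
    while (length(gen_time) > 0) {
      n_off <- stats::rpois(length(gen_time), kernel$branching_ratio)
      if (all(n_off == 0)) break
      parent <- rep(seq_along(gen_time), n_off)
      lag <- stats::rexp(sum(n_off), rate = kernel$decay_rate)
      child_time <- gen_time[parent] + lag
      keep <- child_time <= t_end
      child_time <- child_time[keep]
      parent <- parent[keep]
      if (!length(child_time)) break
      children <- new_arrival_stream(
        time = child_time,
        identity = gen_root[parent],
        lineage = rep("offspring", length(child_time)),
        parent_time = gen_time[parent]
      )
      all <- rbind(all, children)
      gen_time <- child_time
      gen_root <- children$identity
    }
    all[order(all$time), , drop = FALSE]
  })
}

#' Purge offspring from a Hawkes stream
#'
#' Removes self-excited (offspring) events, restoring the independent
#' increment property: the remaining immigrants are an NHPP realisation of
#' the base intensity, which is what capacity planning needs.
#'
#' @param events an arrival stream with a `lineage` column.
#' @return The immigrant-only substream.
#' @export
purge_offspring <- function(events) {
  if (is.null(events$lineage) || anyNA(events$lineage)) {
    stop_domain("events must carry immigrant/offspring lineage labels")
  }
  events[events$lineage == "immigrant", , drop = FALSE]
}
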