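# Estimators that turn an event log into simulator inputs: TOS probability,
# IQR-filtered beta duration models, censored-survival patience, interarrival
# aggregation, Box-Cox utilities and the valid-case tally.

ZERO_WAIT_WINDOW_MIN <- 1  # 60-second pickup window treated as "did not queue"

#' Estimate the TOS acceptance probability
#'
#' TOS acceptance is modelled as a Bernoulli process; the point estimate is
#' the accepted fraction, with an exact (Clopper-Pearson) binomial 95% CI.
#'
#' @param log a [chat_log()] with at least one record.
#' @return List with `p`, `lower`, `upper`, `n_accepted`, `n`.
#' @export
estimate_tos_probability <- function(log) {
  n <- nrow(log)
  if (n == 0) stop_domain("cannot estimate TOS probability from an empty log")
  k <- sum(log$tos_accepted)
  ci <- stats::binom.test(k, n)$conf.int
  list(p = k / n, lower = ci[1], upper = ci[2], n_accepted = k, n = n)
}

# Completed counseling chats (picked up, ended, not reneged) in a stratum.
completed_durations <- function(log, user_type = NULL, risk_level = NULL) {
  keep <- !is.na(log$pickup_ts) & !is.na(log$end_ts) & is.na(log$renege_ts)
  if (!is.null(user_type)) keep <- keep & !is.na(log$user_type) & log$user_type == user_type
  if (!is.null(risk_level)) keep <- keep & !is.na(log$risk_level) & log$risk_level == risk_level
  as.numeric(difftime(log$end_ts[keep], log$pickup_ts[keep], units = "mins"))
}

# Tukey fence filter iterated to a fixed point: re-applying the fences to an
# already-filtered sample removes nothing, so the filter is idempotent (a
# single pass is not, because trimming shifts the quartiles).
iqr_filter <- function(x, k = 1.5) {
  repeat {
    q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
    iqr <- q[2] - q[1]
    keep <- x >= q[1] - k * iqr & x <= q[2] + k * iqr
    if (all(keep)) return(x)
    x <- x[keep]
  }
}

#' Fit a scaled-beta service-duration model
#'
#' Removes durations outside the Tukey fences `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`
#' and fits a beta on `[0, scale]` by method of moments to the retained
#' sample, so the implied mean `scale * alpha/(alpha+beta)` reproduces the
#' sample mean exactly.
#'
#' @param log a [chat_log()].
#' @param user_type,risk_level optional stratum filters (`NULL` pools).
#' @param scale support upper bound in minutes; `NULL` (default) uses the
#'   maximum retained duration, preserving the observed range.
#' @param min_n smallest stratum size accepted.
#' @return A `duration_model` with `n_used`, fitted moments and shapes.
#' @export
fit_duration_model <- function(log, user_type = NULL, risk_level = NULL,
                               scale = NULL, min_n = 10) {
  x <- completed_durations(log, user_type, risk_level)
  if (length(x) < min_n) {
    stop_domain("stratum too small (", length(x), " completed chats); ",
                "pool across user types or risk levels")
  }
  if (stats::IQR(x) <= 0) {
    stop_domain("degenerate sample: IQR is zero, moments cannot identify a beta")
  }
  x <- iqr_filter(x)
  m <- mean(x)
  s <- stats::sd(x)
  if (s <= 0) stop_domain("degenerate sample after outlier removal")
  sc <- scale %||% max(x)
  if (sc <= m) sc <- m + 4 * s  # guard: all-mass-at-max pathologies
  model <- duration_model_from_moments(m, s, scale = sc, n_used = length(x))
  model
}

#' Fit exponential patience or virtual waiting time by censored survival
#'
#' Queue waits are only partially observed: a renege reveals the user's
#' patience but censors the virtual waiting time, while a pickup reveals the
#' virtual wait and censors patience. The exponential maximum-likelihood
#' estimate under right censoring is `sum(all observed times) / n_events`.
#' Pickups within the 60-second zero-wait window never queued and are
#' excluded.
#'
#' @param log a [chat_log()] containing both picked-up and reneged cases.
#' @param user_type optional stratum filter (`NULL` pools both types).
#' @param censoring `"patience"` (reneges are events, pickups censored) or
#'   `"virtual_wait"` (the reverse).
#' @param zero_wait_window_min pickup waits at or below this are dropped.
#' @return A [patience_model()] with mean, SE (`mean/sqrt(n_events)`) and
#'   event/censoring counts.
#' @export
fit_patience <- function(log, user_type = NULL,
                         censoring = c("patience", "virtual_wait"),
                         zero_wait_window_min = ZERO_WAIT_WINDOW_MIN) {
  censoring <- match.arg(censoring)
  w <- queue_waits(log, user_type, zero_wait_window_min)
  if (nrow(w) == 0) stop_domain("no queued cases to analyse")
  event <- if (censoring == "patience") w$reneged else !w$reneged
  n_events <- sum(event)
  if (n_events == 0) {
    stop_domain("no observed events in ", censoring,
                " mode: the exponential MLE is undefined")
  }
  mean_hat <- sum(w$time) / n_events
  patience_model(mean_hat, se_minutes = mean_hat / sqrt(n_events),
                 n_events = n_events, n_censored = sum(!event))
}

# One wait observation per queued case: reneges end at renege_ts, pickups at
# pickup_ts (for zombie cases the renege, which precedes the pickup, is the
# user-side termination and wins).
queue_waits <- function(log, user_type = NULL,
                        zero_wait_window_min = ZERO_WAIT_WINDOW_MIN) {
  keep <- log$tos_accepted & (!is.na(log$pickup_ts) | !is.na(log$renege_ts))
  if (!is.null(user_type)) keep <- keep & !is.na(log$user_type) & log$user_type == user_type
  sub <- log[keep, , drop = FALSE]
  reneged <- !is.na(sub$renege_ts)
  end <- sub$pickup_ts
  end[reneged] <- sub$renege_ts[reneged]
  time <- as.numeric(difftime(end, sub$arrival_ts, units = "mins"))
  out <- data.frame(time = time, reneged = reneged)
  # picked up within the zero-wait window => never queued
  out[!(!out$reneged & out$time <= zero_wait_window_min), , drop = FALSE]
}

#' Two-group log-rank test on censored waits
#'
#' Standard log-rank comparison of two right-censored waiting-time samples;
#' used to decide whether repeat and nonrepeat users need separate patience
#' models.
#'
#' @param time_a,time_b waiting times in minutes.
#' @param event_a,event_b logical event indicators (`TRUE` = observed,
#'   `FALSE` = censored).
#' @return List with `chisq` (1 df) and `p_value`.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (!length(time_a) || !length(time_b)) stop_domain("both groups must be nonempty")
  if (!any(event_a) && !any(event_b)) stop_domain("no observed events in either group")
  df <- data.frame(
    time = c(time_a, time_b),
    event = as.integer(c(event_a, event_b)),
    group = rep(c("a", "b"), c(length(time_a), length(time_b)))
  )
  fit <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  list(chisq = fit$chisq, p_value = stats::pchisq(fit$chisq, df = 1, lower.tail = FALSE))
}

#' Aggregate arrivals into a binned interarrival-rate series
#'
#' Arrivals are deduplicated to the first instance per identifier per bin (a
#' proxy for purging self-excited re-contacts), successive interarrival gaps
#' are computed on the deduplicated stream, and each gap is assigned to the
#' bin containing its later arrival. Bins without any gap are imputed by
#' linear interpolation between neighbouring valid bins and flagged.
#'
#' @param log a [chat_log()] with at least two arrivals.
#' @param bin_width_min bin width in minutes (default 120 = 2 hours).
#' @param origin calendar time of minute 0.
#' @return A data frame of class `rate_series`: `bin_start` (minutes),
#'   `mean_interarrival` (minutes), `n_arrivals`, `imputed`; attributes
#'   `bin_width` and `boxcox_lambda` (profile-ML estimate).
#' @export
aggregate_interarrivals <- function(log, bin_width_min = 120,
                                    origin = SIM_ORIGIN) {
  t <- ts_to_minutes(log$arrival_ts, origin)
  o <- order(t)
  t <- t[o]
  id <- log$user_id[o]
  bin <- floor(t / bin_width_min)
  keep <- !duplicated(data.frame(id, bin))
  t <- t[keep]
  bin <- bin[keep]
  if (length(t) < 2) stop_domain("need at least 2 arrivals to form interarrivals")
  gaps <- diff(t)
  gap_bin <- bin[-1]  # bin of the later arrival
  bins <- seq(min(bin), max(bin))
  mean_ia <- vapply(bins, function(b) {
    g <- gaps[gap_bin == b]
    if (length(g)) mean(g) else NA_real_
  }, numeric(1))
  n_arr <- vapply(bins, function(b) sum(bin == b), numeric(1))
  imputed <- is.na(mean_ia)
  if (any(imputed)) {
    ok <- which(!imputed)
    if (length(ok) < 2) stop_domain("too few populated bins to impute")
    mean_ia[imputed] <- stats::approx(ok, mean_ia[ok], xout = which(imputed),
                                      rule = 2)$y
  }
  out <- data.frame(
    bin_start = bins * bin_width_min,
    mean_interarrival = mean_ia,
    n_arrivals = n_arr,
    imputed = imputed
  )
  class(out) <- c("rate_series", "data.frame")
  attr(out, "bin_width") <- bin_width_min
  attr(out, "boxcox_lambda") <- boxcox_lambda(out$mean_interarrival)
  out
}

#' Box-Cox transform
#'
#' `(x^lambda - 1)/lambda` for `lambda != 0`, `log(x)` at `lambda = 0`.
#'
#' @param x positive values.
#' @param lambda transform parameter.
#' @return Transformed values.
#' @export
boxcox <- function(x, lambda) {
  if (any(x <= 0)) stop_domain("Box-Cox requires strictly positive input")
  if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
}

#' Bias-adjusted inverse Box-Cox
#'
#' Back-transforms a forecast mean and variance to an *expected value* on the
#' original scale rather than a median. At `lambda = 0` the lognormal mean
#' `exp(m + v/2)` is exact; otherwise the second-order correction
#' `(lambda m + 1)^(1/lambda) * [1 + v (1 - lambda) / (2 (lambda m + 1)^2)]`
#' is applied. With zero variance this reduces to the plain inverse.
#'
#' @param mean,variance forecast mean and variance on the transformed scale.
#' @param lambda transform parameter.
#' @return Expected value on the original scale.
#' @export
inverse_boxcox_bias_adjusted <- function(mean, variance, lambda) {
  if (any(variance < 0)) stop_domain("variance must be nonnegative")
  if (abs(lambda) < 1e-12) {
    exp(mean + variance / 2)
  } else {
    base <- lambda * mean + 1
    if (any(base <= 0)) stop_domain("mean outside the invertible Box-Cox domain")
    base^(1 / lambda) * (1 + variance * (1 - lambda) / (2 * base^2))
  }
}

#' Profile-maximum-likelihood Box-Cox parameter
#'
#' Maximises the Gaussian profile log-likelihood (including the Jacobian
#' term) of the transformed sample over `lambda` in `[-2, 2]`.
#'
#' @param x positive values.
#' @return The estimated `lambda`.
#' @export
boxcox_lambda <- function(x) {
  if (any(x <= 0)) stop_domain("Box-Cox requires strictly positive input")
  if (stats::sd(x) == 0) return(1)
  n <- length(x)
  slx <- sum(log(x))
  prof <- function(l) {
    z <- boxcox(x, l)
    v <- stats::var(z) * (n - 1) / n
    -n / 2 * log(v) + (l - 1) * slx
  }
  stats::optimize(prof, c(-2, 2), maximum = TRUE)$maximum
}

#' Tally valid cases
#'
#' Counts picked-up cases whose chat lasted at least `threshold_min` minutes
#' (boundary inclusive) -- a ballpark for the operational "valid case" notion
#' that cannot itself be simulated.
#'
#' @param log a [chat_log()].
#' @param threshold_min duration cutoff in minutes (default 7.5).
#' @return Integer count.
#' @export
tally_valid_cases <- function(log, threshold_min = 7.5) {
  ok <- !is.na(log$pickup_ts) & !is.na(log$end_ts)
  dur <- as.numeric(difftime(log$end_ts[ok], log$pickup_ts[ok], units = "mins"))
  sum(dur >= threshold_min)
}

#' Fit the full simulator parameter set from an event log
#'
#' Convenience wrapper running every estimator: TOS probability, user-type
#' share, per-type risk mixes, per-stratum duration models (pooling a stratum
#' upward when it is too small), and per-type patience.
#'
#' @param log a [chat_log()].
#' @param min_stratum_n smallest duration stratum fitted separately.
#' @return A named list of class `parameter_set`.
#' @export
fit_parameter_set <- function(log, min_stratum_n = 30) {
  tos <- estimate_tos_probability(log)
  acc <- log[log$tos_accepted, , drop = FALSE]
  ut <- acc$user_type[!is.na(acc$user_type)]
  user_type_p <- mean(ut == "nonrepeat")
  risk_mix <- lapply(stats::setNames(USER_TYPE_LEVELS, USER_TYPE_LEVELS), function(t) {
    r <- acc$risk_level[!is.na(acc$risk_level) & acc$user_type == t]
    p <- prop.table(table(factor(r, levels = RISK_LEVELS)))
    stats::setNames(as.numeric(p), RISK_LEVELS)
  })
  durations <- lapply(stats::setNames(USER_TYPE_LEVELS, USER_TYPE_LEVELS), function(t) {
    lapply(stats::setNames(RISK_LEVELS, RISK_LEVELS), function(r) {
      # pool upward when a stratum is thin: drop the user-type split first,
      # then the risk split
      for (stratum in list(list(t, r), list(NULL, r), list(t, NULL),
                           list(NULL, NULL))) {
        fit <- tryCatch(
          fit_duration_model(log, stratum[[1]], stratum[[2]],
                             min_n = min_stratum_n),
          error = function(e) NULL
        )
        if (!is.null(fit)) return(fit)
      }
      fit_duration_model(log, NULL, NULL, min_n = 10)
    })
  })
  patience <- lapply(stats::setNames(USER_TYPE_LEVELS, USER_TYPE_LEVELS), function(t) {
    fit_patience(log, t, "patience")
  })
  structure(
    list(tos = tos, user_type_p = user_type_p, risk_mix = risk_mix,
         durations = durations, patience = patience),
    class = "parameter_set"
  )
}

#' Write a fitted parameter set to a structured text file
#'
#' @param params a `parameter_set` (or [ground_truth_params()]).
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_parameter_set <- function(params, path) {
  ser_dur <- function(d) {
    if (d$dist == "beta") {
      list(dist = "beta", alpha = d$alpha, beta = d$beta, scale = d$scale,
           mean_minutes = d$mean_minutes, sd_minutes = d$sd_minutes,
           n_used = if (is.na(d$n_used)) NULL else d$n_used)
    } else {
      list(dist = "exp", mean_minutes = d$mean_minutes)
    }
  }
  ser_pat <- function(p) {
    list(mean_minutes = p$mean_minutes,
         se_minutes = if (is.na(p$se_minutes)) NULL else p$se_minutes,
         n_events = if (is.na(p$n_events)) NULL else p$n_events,
         n_censored = if (is.na(p$n_censored)) NULL else p$n_censored)
  }
  obj <- list(
    tos_p = if (!is.null(params$tos)) params$tos$p else params$tos_p,
    user_type_p = params$user_type_p,
    risk_mix = lapply(params$risk_mix, as.list),
    durations = lapply(params$durations, function(x) lapply(x, ser_dur)),
    patience = lapply(params$patience, ser_pat)
  )
  yaml::write_yaml(obj, path, precision = 12)
  invisible(path)
}

#' Read a parameter set written by [write_parameter_set()]
#'
#' @param path YAML path.
#' @return A `parameter_set` list with model objects reconstructed.
#' @export
read_parameter_set <- function(path) {
  obj <- yaml::read_yaml(path)
  de_dur <- function(d) {
    if (d$dist == "beta") {
      duration_model_from_moments(d$mean_minutes, d$sd_minutes, scale = d$scale,
                                  n_used = d$n_used %||% NA_integer_)
    } else {
      exp_duration_model(d$mean_minutes)
    }
  }
  de_pat <- function(p) {
    patience_model(p$mean_minutes, p$se_minutes %||% NA_real_,
                   p$n_events %||% NA_integer_, p$n_censored %||% NA_integer_)
  }
  structure(
    list(
      tos = list(p = obj$tos_p),
      tos_p = obj$tos_p,
      user_type_p = obj$user_type_p,
      risk_mix = lapply(obj$risk_mix, function(x) unlist(x)),
      durations = lapply(obj$durations, function(x) lapply(x, de_dur)),
      patience = lapply(obj$patience, de_pat)
    ),
    class = "parameter_set"
  )
}
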