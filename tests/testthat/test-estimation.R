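test_that("TOS probability is the accepted fraction, with exact CI", {
  # the studied service's headline split: 62,081 accepted of 83,013
  log <- chat_log(user_id = sprintf("u%d", 1:83013), channel = "web",
                  arrival_ts = minutes_to_minsec(1:83013),
                  tos_accepted = rep(c(TRUE, FALSE), c(62081, 20932)),
                  validate = FALSE)
  est <- estimate_tos_probability(log)
  expect_equal(round(est$p, 4), 0.7478)
  expect_lt(est$lower, est$p)
  expect_gt(est$upper, est$p)

  log4 <- chat_log(user_id = sprintf("u%d", 1:4), channel = "web",
                   arrival_ts = minutes_to_minsec(1:4),
                   tos_accepted = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(estimate_tos_probability(log4)$p, 0.75)
  log4$tos_accepted <- TRUE
  expect_equal(estimate_tos_probability(log4)$p, 1)
  expect_error(estimate_tos_probability(chat_log()), "empty")
})

served_log <- function(durations, user_type = "nonrepeat", risk = "low") {
  n <- length(durations)
  arr <- seq(0, by = 200, length.out = n)
  chat_log(user_id = sprintf("u%d", 1:n), channel = "web",
           arrival_ts = minutes_to_minsec(arr), tos_accepted = TRUE,
           user_type = user_type, pickup_ts = minutes_to_minsec(arr),
           end_ts = minutes_to_minsec(arr + durations), risk_level = risk)
}

test_that("beta duration fit recovers known shapes and satisfies the mean identity", {
  set.seed(1)
  x <- rbeta(5000, 2, 5) * 180
  log <- served_log(x)
  fit <- fit_duration_model(log, "nonrepeat", "low", scale = 180)
  expect_lt(abs(fit$alpha - 2) / 2, 0.10)
  expect_lt(abs(fit$beta - 5) / 5, 0.10)
  # moment identity: implied mean equals the retained sample mean exactly
  expect_equal(fit$scale * fit$alpha / (fit$alpha + fit$beta),
               fit$mean_minutes, tolerance = 1e-9)
  expect_lt(fit$n_used, 5000)

  # default support: the maximum retained duration (durations live on the
  # log's 1-second clock)
  fit2 <- fit_duration_model(log, "nonrepeat", "low")
  expect_equal(fit2$scale, max(crisisim:::iqr_filter(round(x * 60) / 60)))
})

test_that("degenerate and undersized duration strata are rejected", {
  expect_error(fit_duration_model(served_log(rep(42, 50))), "degenerate")
  expect_error(fit_duration_model(served_log(c(10, 20, 30))), "too small")
})

test_that("the outlier filter is idempotent", {
  set.seed(4)
  for (x in list(rexp(2000) * 30, rbeta(3000, 2, 5) * 180, rlnorm(1000))) {
    once <- crisisim:::iqr_filter(x)
    expect_identical(crisisim:::iqr_filter(once), once)
  }
})

renege_log <- function(waits, user_type = "nonrepeat") {
  n <- length(waits)
  arr <- seq(0, by = 50, length.out = n)
  chat_log(user_id = sprintf("u%d", 1:n), channel = "web",
           arrival_ts = minutes_to_minsec(arr), tos_accepted = TRUE,
           user_type = user_type, renege_ts = minutes_to_minsec(arr + waits))
}

test_that("with no censoring the patience MLE is the sample mean of waits", {
  waits <- c(2, 4, 6, 8, 10)
  fit <- fit_patience(renege_log(waits), censoring = "patience")
  expect_equal(fit$mean_minutes, mean(waits))
  expect_identical(fit$n_events, length(waits))
  expect_identical(fit$n_censored, 0L)
  # the reverse scheme has no events at all
  expect_error(fit_patience(renege_log(waits), censoring = "virtual_wait"),
               "undefined")
})

test_that("zero-wait pickups are excluded from the survival fits", {
  arr <- c(0, 100, 200, 300, 400)
  log <- chat_log(
    user_id = sprintf("u%d", 1:5), channel = "web",
    arrival_ts = minutes_to_minsec(arr), tos_accepted = TRUE,
    user_type = "nonrepeat",
    pickup_ts = minutes_to_minsec(arr + c(0.5, 0.8, 5, NA, NA)),
    renege_ts = minutes_to_minsec(arr + c(NA, NA, NA, 3, 7))
  )
  fit <- fit_patience(log, censoring = "patience")
  # two reneges observed, one censored pickup at 5 min; the two sub-minute
  # pickups never queued
  expect_identical(fit$n_events, 2L)
  expect_identical(fit$n_censored, 1L)
  expect_equal(fit$mean_minutes, (3 + 7 + 5) / 2)
})

test_that("censored patience estimation recovers generator truth at scale", {
  gt <- default_ground_truth(rate_fn = constant_rate(0.25))
  log <- generate_synthetic_log(gt, 90 * 1440, n_counselors = 5, seed = 42)
  for (ut in c("nonrepeat", "repeat")) {
    fit <- fit_patience(log, ut, "patience")
    truth <- gt$patience[[ut]]$mean_minutes
    expect_gt(fit$n_events, 1000)
    expect_lt(abs(fit$mean_minutes - truth), 2 * fit$se_minutes,
              label = paste(ut, "patience bias"))
  }
  # virtual waiting time: the reverse censoring scheme still yields a
  # positive, finite mean with both events and censorings
  vw <- fit_patience(log, "nonrepeat", "virtual_wait")
  expect_gt(vw$n_events, 1000)
  expect_gt(vw$mean_minutes, 0)
})

test_that("patience estimator bias shrinks as the sample grows", {
  gt <- default_ground_truth(rate_fn = constant_rate(0.25))
  truth <- gt$patience$nonrepeat$mean_minutes
  sizes <- c(7, 45, 270) * 1440  # increasing horizons = increasing n
  err <- vapply(sizes, function(h) {
    log <- generate_synthetic_log(gt, h, n_counselors = 5, seed = 11)
    fit <- fit_patience(log, "nonrepeat", "patience")
    c(abs(fit$mean_minutes - truth), fit$se_minutes)
  }, numeric(2))
  # standard errors shrink and the largest-sample estimate is within 2 SE
  expect_true(all(diff(err[2, ]) < 0))
  expect_lt(err[1, 3], 2 * err[2, 3])
})

test_that("log-rank separates the two user types' patience at scale", {
  set.seed(8)
  reject <- vapply(1:30, function(s) {
    n <- 2000
    t_a <- rexp(n, 1 / 3.455); t_b <- rexp(n, 1 / 5.290)
    cens_a <- runif(n) < 0.3; cens_b <- runif(n) < 0.3
    # censoring at a fraction of the drawn time
    obs_a <- ifelse(cens_a, t_a * runif(n), t_a)
    obs_b <- ifelse(cens_b, t_b * runif(n), t_b)
    logrank_test(obs_a, !cens_a, obs_b, !cens_b)$p_value < 0.001
  }, logical(1))
  expect_gte(sum(reject), 29)

  same <- logrank_test(1:20, rep(TRUE, 20), 1:20, rep(TRUE, 20))
  expect_lt(same$chisq, 1e-8)
  expect_gt(same$p_value, 0.99)

  set.seed(9)
  tiny <- logrank_test(rexp(20, 1), rep(TRUE, 20), rexp(20, 1) + 0.01,
                       rep(TRUE, 20))
  expect_gt(tiny$p_value, 0.05)
  expect_error(logrank_test(numeric(0), logical(0), 1:3, rep(TRUE, 3)),
               "nonempty")
})

test_that("interarrival aggregation bins, dedups and imputes", {
  # metronome arrivals: every bin mean is exactly the gap
  log <- stream_log(seq(5, 2880, by = 5))
  rs <- aggregate_interarrivals(log)
  expect_s3_class(rs, "rate_series")
  expect_true(all(abs(rs$mean_interarrival - 5) < 1e-9))
  expect_true(all(diff(rs$bin_start) == 120))

  # six requests from one identifier within a bin count once
  log2 <- stream_log(c(10, 20, 30, 40, 50, 60, 90, 130, 250),
                     ids = c(rep("dup", 6), "other", "x1", "x2"))
  rs2 <- aggregate_interarrivals(log2)
  expect_identical(rs2$n_arrivals[1], 2)
  # dedup never increases the count; equality when identifiers are distinct
  expect_lte(sum(rs2$n_arrivals), nrow(log2))
  rs3 <- aggregate_interarrivals(stream_log(c(10, 90, 130, 250)))
  expect_identical(sum(rs3$n_arrivals), 4)

  # a silent bin is imputed from its neighbours and flagged
  log4 <- stream_log(c(seq(10, 110, by = 20), seq(250, 350, by = 20)))
  rs4 <- aggregate_interarrivals(log4)
  expect_true(rs4$imputed[2])
  expect_false(rs4$imputed[1])
  expect_true(all(rs4$mean_interarrival > 0))
  expect_error(aggregate_interarrivals(stream_log(5)), "at least 2")
})

test_that("binned interarrival means track a sinusoidal intensity", {
  rf <- as_rate_function(function(t) 0.5 + 0.3 * sin(2 * pi * t / 1440),
                         t_max = 20 * 1440)
  st <- sample_nhpp(rf, 20 * 1440, seed = 31)
  rs <- aggregate_interarrivals(stream_log(st$time))
  mid <- rs$bin_start + 60
  expected <- 1 / rate_at(rf, mid)
  rel <- abs(rs$mean_interarrival - expected) / expected
  expect_lt(stats::median(rel), 0.15)
  expect_lt(mean(rel), 0.25)
})

test_that("Box-Cox transforms, bias adjustment and profile lambda behave", {
  x <- c(0.5, 1, 2, 7)
  expect_equal(boxcox(x, 1), x - 1)
  expect_equal(boxcox(x, 0), log(x))
  expect_error(boxcox(c(1, -2), 0.3), "positive")

  # lambda = 0 with variance v: exact lognormal mean m * exp(v/2)
  m <- 3.7; v <- 0.4
  expect_equal(inverse_boxcox_bias_adjusted(log(m), v, 0), m * exp(v / 2))
  # linear case recovers x exactly
  expect_equal(inverse_boxcox_bias_adjusted(boxcox(x, 1), 0, 1), x)
  # zero variance: plain inverse round-trips at any lambda
  for (l in c(-1, -0.3, 0, 0.4, 1, 2)) {
    expect_equal(inverse_boxcox_bias_adjusted(boxcox(x, l), 0, l), x,
                 tolerance = 1e-12)
  }
  # Jensen direction: adjustment raises the naive inverse when lambda < 1
  naive <- inverse_boxcox_bias_adjusted(boxcox(x, 0.3), 0, 0.3)
  adj <- inverse_boxcox_bias_adjusted(boxcox(x, 0.3), 0.2, 0.3)
  expect_true(all(adj >= naive))

  set.seed(2)
  z <- exp(rnorm(500, 1, 0.4))  # truth: lambda = 0
  expect_lt(abs(boxcox_lambda(z)), 0.35)
})

test_that("valid-case tally is boundary-inclusive and matches a brute filter", {
  arr <- c(0, 100, 200)
  log <- chat_log(user_id = c("a", "b", "c"), channel = "web",
                  arrival_ts = minutes_to_minsec(arr), tos_accepted = TRUE,
                  pickup_ts = minutes_to_minsec(arr),
                  end_ts = minutes_to_minsec(arr + c(7.4, 7.5, 7.6)))
  expect_identical(tally_valid_cases(log), 2L)
  expect_identical(tally_valid_cases(renege_log(c(3, 5))), 0L)

  full <- generate_synthetic_log(default_ground_truth(), 5 * 1440,
                                 n_counselors = 6, seed = 13)
  brute <- sum(!is.na(full$pickup_ts) & !is.na(full$end_ts) &
                 as.numeric(full$end_ts - full$pickup_ts, units = "mins") >= 7.5)
  expect_identical(tally_valid_cases(full), brute)
})

test_that("a fitted parameter set survives the YAML round trip", {
  log <- generate_synthetic_log(default_ground_truth(), 30 * 1440,
                                n_counselors = 6, seed = 21)
  ps <- fit_parameter_set(log)
  expect_s3_class(ps, "parameter_set")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_parameter_set(ps, path)
  back <- read_parameter_set(path)
  expect_equal(back$tos_p, ps$tos$p, tolerance = 1e-9)
  expect_equal(back$user_type_p, ps$user_type_p, tolerance = 1e-9)
  expect_equal(back$durations$nonrepeat$low$alpha, ps$durations$nonrepeat$low$alpha,
               tolerance = 1e-6)
  expect_equal(back$patience$`repeat`$mean_minutes, ps$patience$`repeat`$mean_minutes,
               tolerance = 1e-9)
})
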