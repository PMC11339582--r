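test_that("round-robin recycling caps the horizon exactly", {
  t <- empirical_roundrobin_arrivals(10, 43200)
  expect_identical(length(t), 4320L)
  expect_equal(t[length(t)], 43200)
  # a list summing exactly to the horizon never wraps
  t2 <- empirical_roundrobin_arrivals(c(4, 6), 10)
  expect_equal(t2, c(4, 10))
  # counts are invariant under permutation when whole cycles tile the
  # horizon (integer gaps keep the cycle sums exact)
  ia <- rep(c(2, 3, 5), 20)  # cycle sum 200
  n0 <- length(empirical_roundrobin_arrivals(ia, 1000))
  expect_identical(n0, 5L * 60L)
  set.seed(1)
  t_shuf <- empirical_roundrobin_arrivals(ia, 1000, shuffle = TRUE)
  expect_identical(length(t_shuf), n0)
  expect_false(identical(t_shuf, empirical_roundrobin_arrivals(ia, 1000)))
  expect_error(empirical_roundrobin_arrivals(c(3, 0), 100), "positive")
})

test_that("a zero-arrival scenario yields zero tallies and full vacancy", {
  cfg <- scenario_config(
    shifts = list(shift(0, 24, list(counselor_spec("full_time")))),
    arrivals = arrivals_nhpp(constant_rate(0)),
    params = oracle_params(10, 5),
    horizon_minutes = 2 * 1440, replications = 1, seed = 1
  )
  run <- run_replication(cfg, seed = 1)
  expect_true(all(run$tallies == 0))
  vc <- run$hourly$vacancy_counts
  # every sampled minute shows the full concurrent capacity (3) unused
  expect_identical(sum(vc[, colnames(vc) != "3"]), 0L)
  expect_identical(sum(vc[, "3"]), 2880L)
})

test_that("the conversion conservation identity holds in every replication", {
  for (seed in 1:4) {
    for (evict in c(TRUE, FALSE)) {
      run <- run_replication(short_base_config(days = 2,
                                               zombie_eviction = evict),
                             seed = seed)
      t <- run$tallies
      expect_identical(
        t[["tos_accepted"]],
        t[["served_immediately"]] + t[["served_after_queue"]] +
          t[["reneged"]] + t[["in_system_at_horizon"]],
        label = sprintf("seed %d evict %s", seed, evict)
      )
    }
  }
})

test_that("pickups respect FIFO order within the single case queue", {
  run <- run_replication(short_base_config(days = 3), seed = 6, keep_log = TRUE)
  cd <- run$case_detail  # rows are in arrival order
  picked <- cd$pickup[!is.na(cd$pickup)]
  expect_gt(length(picked), 200)
  expect_false(is.unsorted(picked))
})

test_that("zombie eviction dominates zombie retention under paired seeds", {
  cfg_keep <- short_base_config(days = 4, zombie_eviction = FALSE)
  cfg_evict <- short_base_config(days = 4, zombie_eviction = TRUE)
  for (seed in 1:10) {
    a <- run_replication(cfg_keep, seed = seed)$tallies
    b <- run_replication(cfg_evict, seed = seed)$tallies
    conv <- function(t) (t[["served_immediately"]] + t[["served_after_queue"]]) /
      t[["arrivals"]]
    expect_gte(conv(b), conv(a), label = paste("paired seed", seed))
  }
})

test_that("adding a counselor never hurts conversion beyond noise", {
  base <- base_case_schedule()
  bigger <- base
  bigger[[5]] <- shift(19, 24, c(bigger[[5]]$staff,
                                 list(counselor_spec("volunteer"))))
  gt <- default_ground_truth()
  mk <- function(sh) scenario_config(
    shifts = sh, arrivals = arrivals_nhpp(default_rate_profile(t_max = 4 * 1440)),
    params = gt, horizon_minutes = 4 * 1440, replications = 1, seed = 1
  )
  cfg_a <- mk(base); cfg_b <- mk(bigger)
  diffs <- vapply(1:30, function(s) {
    ta <- run_replication(cfg_a, seed = s)$tallies
    tb <- run_replication(cfg_b, seed = s)$tallies
    conv <- function(t) (t[["served_immediately"]] + t[["served_after_queue"]]) /
      t[["arrivals"]]
    conv(tb) - conv(ta)
  }, numeric(1))
  expect_gt(mean(diffs), -0.002)
  expect_gt(mean(diffs > -1e-12), 0.6)
})

test_that("replications are deterministic given the seed", {
  cfg <- short_base_config(days = 2)
  a <- run_replication(cfg, seed = 42)
  b <- run_replication(cfg, seed = 42)
  expect_identical(a$tallies, b$tallies)
  expect_identical(a$hourly$queue_counts, b$hourly$queue_counts)
})

test_that("zombies consume only survey time", {
  # one single-chat counselor, long services, short patience, heavy traffic:
  # with retention, reneged heads must be opened and surveyed before real
  # cases are reached
  params <- oracle_params(60, 2)
  mk <- function(evict) scenario_config(
    shifts = list(shift(0, 24, list(counselor_spec("duty_officer")))),
    arrivals = arrivals_nhpp(constant_rate(0.5)),
    params = params, horizon_minutes = 1440, survey_minutes = 4,
    zero_wait_window_s = 60, zombie_eviction = evict,
    replications = 1, seed = 1
  )
  keep <- run_replication(mk(FALSE), seed = 2, keep_log = TRUE)
  evicted <- run_replication(mk(TRUE), seed = 2, keep_log = TRUE)
  cd <- keep$case_detail
  zp <- cd[cd$zombie, ]
  expect_gt(nrow(zp), 10)
  # zombie pickups happen after the user left
  expect_true(all(zp$pickup > zp$renege_at))
  # retention wastes capacity: strictly fewer real services than eviction
  expect_lt(sum(cd$served), sum(evicted$case_detail$served))
  # zombie-held slots free after survey_minutes: the log shows zero-length
  # chats for them
  lg <- keep$log
  zl <- !is.na(lg$renege_ts) & !is.na(lg$pickup_ts)
  expect_identical(sum(zl), nrow(zp))
  expect_true(all(lg$end_ts[zl] == lg$pickup_ts[zl]))
})

test_that("bootstrap envelopes contain the mean and tighten with replications", {
  cfg <- short_base_config(days = 2, replications = 24)
  res <- run_bootstrap(cfg, seed = 3)
  expect_s3_class(res, "sim_result")
  expect_identical(nrow(res$tallies), 24L)
  s <- res$summary
  expect_true(all(s$lower <= s$mean + 1e-9 & s$mean <= s$upper + 1e-9))

  res_big <- run_bootstrap(cfg, replications = 96, seed = 3)
  mean_se <- function(r) stats::sd(r$tallies$conversion) /
    sqrt(nrow(r$tallies))
  expect_lt(mean_se(res_big), mean_se(res))
})

test_that("Little's law holds in the stationary oracle configuration", {
  # M/M/1 with rho = 2/3: E[Lq] = rho^2/(1-rho) = 4/3
  cfg <- oracle_config(rate = 1 / 6, capacity = 1, mean_service = 4,
                       patience_mean = Inf, horizon = 40000)
  run <- run_replication(cfg, seed = 8)
  qc <- colSums(run$hourly$queue_counts)
  lens <- as.integer(names(qc))
  mean_q <- sum(lens * qc) / sum(qc)
  expect_lt(abs(mean_q - 4 / 3) / (4 / 3), 0.12)
})

test_that("shift and break windows gate new assignments", {
  # a single counselor staffed 9-10 only; arrivals all day, infinite patience
  cfg <- scenario_config(
    shifts = list(shift(9, 10, list(counselor_spec("duty_officer")))),
    arrivals = arrivals_nhpp(constant_rate(0.05)),
    params = oracle_params(0.5, Inf),
    horizon_minutes = 1440, survey_minutes = 0, replications = 1, seed = 1
  )
  run <- run_replication(cfg, seed = 4, keep_log = TRUE)
  cd <- run$case_detail
  hrs <- (cd$pickup[!is.na(cd$pickup)] %% 1440) / 60
  expect_true(all(hrs >= 9 & hrs < 10))
  expect_gt(sum(is.na(cd$pickup)), 0)  # off-hours arrivals left waiting
})

test_that("scenario configuration survives the YAML round trip", {
  cfg <- short_base_config(days = 2, zombie_eviction = TRUE)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario_config(cfg, path)
  back <- read_scenario_config(path, arrivals = cfg$arrivals,
                               params = default_ground_truth())
  expect_identical(length(back$shifts), length(cfg$shifts))
  expect_identical(back$zombie_eviction, TRUE)
  expect_identical(back$horizon_minutes, cfg$horizon_minutes)
  # the day shift's staggered meal breaks survive
  expect_equal(back$shifts[[2]]$breaks[[2]][[1]], c(11, 11.5))
  # and the reloaded config replays identically
  a <- run_replication(cfg, seed = 5)
  b <- run_replication(back, seed = 5)
  expect_identical(a$tallies, b$tallies)
})
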