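test_that("conversion decompositions reproduce published funnel arithmetic", {
  # base case: 74.81% TOS x (40.70% immediate + 8.70% queued) = 36.96%
  base <- conversion_decomposition(0.7481, 0.4070, 0.0870)
  expect_equal(round_half_up(100 * base$overall_conversion, 2), 36.96)
  # retrospective month: 75.06% x 50.72% pickup share = 38.07%
  retro <- conversion_decomposition(0.7506, 0.5072, 0)
  expect_equal(round_half_up(100 * retro$overall_conversion, 2), 38.07)
  # degenerate: everyone accepted and served immediately
  expect_equal(conversion_decomposition(1, 1, 0)$overall_conversion, 1)
  expect_error(conversion_decomposition(1.4, 0.2, 0.1), "\\[0, 1\\]")
})

test_that("tally-based and raw-log decompositions agree exactly", {
  run <- run_replication(short_base_config(days = 3), seed = 9,
                         keep_log = TRUE)
  from_tallies <- decompose_conversion(run)
  from_log <- decompose_conversion(run$log)
  for (f in c("p_tos", "frac_immediate", "frac_queued_served", "frac_reneged",
              "frac_in_system", "overall_conversion")) {
    expect_identical(from_tallies[[f]], from_log[[f]], label = f)
  }
  # fractions of accepted users partition
  expect_equal(from_tallies$frac_immediate + from_tallies$frac_queued_served +
                 from_tallies$frac_reneged + from_tallies$frac_in_system, 1)
  expect_error(decompose_conversion(c(arrivals = 0, tos_accepted = 0,
                                      served_immediately = 0,
                                      served_after_queue = 0, reneged = 0,
                                      in_system_at_horizon = 0)),
               "no arrivals")
})

test_that("hourly profiles are CDF-monotone and pledge logic is sound", {
  res <- run_bootstrap(short_base_config(days = 3, replications = 6), seed = 2)
  prof <- hourly_queue_profiles(res, k = c(0, 1, 2, 5, 10),
                                w = c(1, 2, 5, 10, 30))
  for (h in 0:23) {
    q <- prof$queue$prob[prof$queue$hour == h]
    expect_false(is.unsorted(q), label = paste("queue CDF hour", h))
    w <- prof$wait$prob[prof$wait$hour == h]
    w <- w[!is.na(w)]
    if (length(w)) expect_false(is.unsorted(w), label = paste("wait CDF hour", h))
  }
  expect_true(all(prof$queue$prob >= 0 & prof$queue$prob <= 1))
  pl <- pledge_check(res)
  expect_identical(nrow(pl), 24L)
  expect_type(pl$wait_ok, "logical")

  # zero-arrival scenario: both pledges pass everywhere
  cfg0 <- scenario_config(
    shifts = list(shift(0, 24, list(counselor_spec("full_time")))),
    arrivals = arrivals_nhpp(constant_rate(0)),
    params = oracle_params(10, 5), horizon_minutes = 1440,
    replications = 1, seed = 1
  )
  res0 <- run_bootstrap(cfg0, replications = 2, seed = 1)
  pl0 <- pledge_check(res0)
  expect_true(all(pl0$wait_ok))
  expect_true(all(pl0$queue_ok))
  expect_true(all(pl0$p_queue == 1))
})

test_that("a saturated single server fails the wait pledge", {
  cfg <- scenario_config(
    shifts = list(shift(0, 24, list(counselor_spec("duty_officer")))),
    arrivals = arrivals_nhpp(constant_rate(0.5)),
    params = oracle_params(30, 60),  # patient users, slow service
    horizon_minutes = 2 * 1440, replications = 1, seed = 1
  )
  res <- run_bootstrap(cfg, replications = 3, seed = 5)
  pl <- pledge_check(res)
  expect_gt(sum(!pl$wait_ok | !pl$queue_ok), 12)
  # and its vacancy is modal zero around the clock
  vd <- vacancy_distribution(res)
  expect_true(all(vd$by_hour$modal_vacancy == 0))
})

test_that("dropout densities normalise and expose evening pressure", {
  fake <- list(hourly = list(dropout_counts = rep(10L, 24)))
  dd <- dropout_density(fake)
  expect_equal(sum(dd$density$p), 1, tolerance = 1e-12)
  expect_equal(dd$density$p, rep(1 / 24, 24))
  expect_equal(round(dd$mean_p, 4), 0.0417, tolerance = 1e-4)
  expect_equal(dd$windows$cumulative[dd$windows$window == "evening"], 5 / 24)

  res <- run_bootstrap(short_base_config(days = 3, replications = 6), seed = 7)
  dd2 <- dropout_density(res)
  expect_equal(sum(dd2$density$p), 1, tolerance = 1e-12)
  # the diurnal peak drives more dropout into the evening window than a
  # uniform clock would
  ev <- dd2$windows[dd2$windows$window == "evening", ]
  expect_gt(ev$cumulative, 5 / 24)
  expect_error(dropout_density(list(hourly = list(dropout_counts = rep(0L, 24)))),
               "undefined")
})

test_that("vacancy distributions are proper and bounded by the schedule", {
  res <- run_bootstrap(short_base_config(days = 2, replications = 4), seed = 11)
  vd <- vacancy_distribution(res)
  for (h in 0:23) {
    p <- vd$distribution$prob[vd$distribution$hour == h]
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_true(all(p >= 0))
  }
  cap <- staffing_summary(base_case_schedule())$total_capacity
  seen <- vd$distribution$vacancy[vd$distribution$prob > 0]
  expect_true(all(seen >= 0 & seen <= cap))
})

test_that("staffing summaries price the published optimal roster", {
  d <- counselor_spec("duty_officer")
  f <- counselor_spec("full_time")
  v <- counselor_spec("volunteer")
  # 3 duty officers + 11 full-timers + 10 volunteers across four shifts
  shifts <- list(
    shift(0, 9, c(list(d), rep(list(f), 2), rep(list(v), 2))),
    shift(9, 14, c(list(d), rep(list(f), 3), rep(list(v), 2))),
    shift(14, 19, c(list(d), rep(list(f), 3), rep(list(v), 3))),
    shift(19, 24, c(rep(list(f), 3), rep(list(v), 3)))
  )
  s <- staffing_summary(shifts)
  expect_identical(s$n_counselors, 24L)
  expect_equal(s$total_cost, 46)
  expect_equal(s$total_capacity, 56)
})

test_that("cost and effectiveness curves intersect where expected", {
  # symmetric rising/falling lines cross at the midpoint capacity
  pts <- list(
    cost_effectiveness_point("a", failure_rate = 0.8, total_cost = 10,
                             total_capacity = 10),
    cost_effectiveness_point("b", failure_rate = 0.5, total_cost = 25,
                             total_capacity = 20),
    cost_effectiveness_point("c", failure_rate = 0.2, total_cost = 40,
                             total_capacity = 30)
  )
  cc <- cost_effectiveness_curves(pts)
  expect_equal(cc$intersection_capacity, 20, tolerance = 1e-9)
  expect_identical(cc$nearest, "b")

  # a scenario appended beyond the crossing segment that extends neither
  # value range leaves the intersection untouched (interpolation locality
  # under the shared min-max normalisation)
  pts2 <- c(pts, list(cost_effectiveness_point("d", failure_rate = 0.2,
                                               total_cost = 40,
                                               total_capacity = 40)))
  cc2 <- cost_effectiveness_curves(pts2)
  expect_equal(cc2$intersection_capacity, cc$intersection_capacity,
               tolerance = 1e-9)

  # parallel curves: no crossing, reported as absent rather than an error
  flat <- list(
    cost_effectiveness_point("x", failure_rate = 0.9, total_cost = 10,
                             total_capacity = 5),
    cost_effectiveness_point("y", failure_rate = 0.95, total_cost = 20,
                             total_capacity = 15)
  )
  expect_true(is.na(cost_effectiveness_curves(flat)$intersection_capacity))
  expect_error(cost_effectiveness_curves(pts[1]), "at least 2")
})

test_that("repeat share follows the forecast-gap arithmetic", {
  rs <- repeat_share(9175, 5544)
  expect_equal(round_half_up(100 * rs$share, 2), 39.57)
  expect_identical(rs$status, "ok")
  expect_equal(repeat_share(100, 100)$share, 0)
  expect_equal(repeat_share(100, 0)$share, 1)
  expect_warning(out <- repeat_share(100, 120), "exceeds")
  expect_identical(out$status, "forecast_exceeds_actual")
  expect_error(repeat_share(0, 0), "positive")
})

test_that("contingency proportions match published screener percentages", {
  tab <- cbind(counselor = c(49083, 5381, 573),
               chatbot = c(1863, 1649, 1530))
  rownames(tab) <- c("low", "medium", "high_crisis")
  cp <- contingency_proportions(tab)
  expect_equal(cp$percent["high_crisis", "chatbot"], 30.35)
  expect_equal(cp$percent["high_crisis", "counselor"], 1.04)
  expect_equal(unname(colSums(cp$exact)), c(100, 100), tolerance = 1e-9)

  one <- contingency_proportions(matrix(7, 1, 1))
  expect_equal(unname(one$percent[1, 1]), 100)
  z <- contingency_proportions(cbind(a = c(0, 0), b = c(1, 1)))
  expect_identical(z$undefined_columns, "a")
  expect_error(contingency_proportions(matrix(-1, 1, 1)), "nonnegative")
})

test_that("saturation flags trip when marginal gains fall away", {
  pts <- list(
    cost_effectiveness_point("s1", failure_rate = 0.60, total_cost = 20,
                             total_capacity = 20),
    cost_effectiveness_point("s2", failure_rate = 0.45, total_cost = 30,
                             total_capacity = 30),
    cost_effectiveness_point("s3", failure_rate = 0.448, total_cost = 40,
                             total_capacity = 40)
  )
  fl <- saturation_flags(pts, counselors = c(10, 15, 20))
  expect_identical(fl$saturated, c(FALSE, FALSE, TRUE))
})
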