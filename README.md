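# crisisim

Discrete-event simulation of 24/7 text-based crisis-counseling operations.

Nonprofit crisis-chat platforms run small, shift-staffed counseling floors
against bursty, strongly diurnal demand from users whose patience is measured
in minutes. Classical steady-state staffing formulas (Erlang-C/A) do not
apply: arrivals are nonstationary, counselors work overlapping shifts with
unequal simultaneous-chat capacities, and a quirk of many chat systems means
abandoned ("zombie") cases stay in the queue until a counselor opens and
closes them by hand. `crisisim` gives service managers and operations
researchers a full pipeline to quantify those dynamics: estimate every input
distribution from an event log, forecast demand, replay the counseling floor
event by event, and compare staffing scenarios on cost and effectiveness.

## The models at its core

* **Arrivals.** Chat requests form a nonhomogeneous Poisson process with
  intensity λ(t), sampled exactly by Lewis–Shedler thinning against the
  dominating rate λ\* = max λ(t). The terms-of-service (TOS) consent gate is
  an independent Bernoulli(p) split, so the accepted substream is again
  Poisson with intensity p·λ(t). Repeat-user re-contact bursts are modeled as
  a subcritical Hawkes process — immigrants from the base intensity λ₀(t),
  each event spawning Poisson(η) offspring at exponential lags — whose
  offspring can be purged to recover the independent-increment stream that
  capacity planning needs.
* **Demand forecasting.** Interarrival times, deduplicated to the first
  instance per identifier per 2-hour bin, are Box–Cox transformed and
  decomposed by an unobserved-components state-space model: random-walk
  level + trigonometric seasonal (period s = 12 bins, harmonic cutoff κ
  selected by AICc) + optional campaign-dummy regressors + AR(1) irregular,
  estimated by maximum likelihood via the Kalman filter. Forecasts return to
  the rate scale through a bias-adjusted inverse Box–Cox transform and are
  downsampled to a continuous rate function with monotone piecewise-cubic
  Hermite (PCHIP) interpolation.
* **Service and patience.** Chat durations follow scaled beta distributions
  fitted by method of moments per (user type × risk level) stratum after
  iterated 1.5×IQR outlier trimming. Caller patience and virtual waiting
  time are exponential, estimated by right-censored maximum likelihood
  (reneges are events and pickups censorings for patience; the reverse for
  virtual wait), with pickups inside a 60-second zero-wait window excluded
  as never having queued.
* **The floor.** A discrete-event engine replays a FIFO case queue against
  overlapping shifts, per-counselor concurrent-chat capacities, meal breaks,
  post-chat survey overhead, exponential reneging, and both zombie policies
  (retained cases that cost a counselor the survey time, or automatic
  eviction). Bootstrap replication yields mean and 2.5/97.5-percentile
  envelopes for every statistic.

## Worked example

```r
library(crisisim)

# a synthetic 30-day event log with known ground truth
gt  <- default_ground_truth()
log <- generate_synthetic_log(gt, horizon_minutes = 43200,
                              n_counselors = 8, seed = 1)
nrow(log)                                   # 9214 records

estimate_tos_probability(log)$p             # 0.7428 (truth 0.7478)
fit_patience(log, "nonrepeat", "patience")
#> <patience_model> Exponential(mean 3.4785 min, se 0.0933; events 1390, censored 417)
fit_duration_model(log, risk_level = "low")
#> <duration_model> 136.40 * Beta(1.276, 2.263) min (mean 49.20, sd 30.74, n=4378)

# bootstrap the reconstructed base-case roster over 30 days
cfg <- scenario_config(
  shifts   = base_case_schedule(),
  arrivals = arrivals_nhpp(default_rate_profile(t_max = 43200)),
  params   = gt, replications = 100, seed = 1
)
res <- run_bootstrap(cfg)
decompose_conversion(res)
#> conversion: 49.07% = 74.71% TOS x (58.14% immediate + 7.54% queued)
#>   reneged 34.31%, in system at horizon 0.01% (of accepted)

dropout_density(res)$windows
#>      window start end cumulative hourly_mean  hourly_sd
#> 1 afternoon    14  17  0.2162293  0.07207644 0.02944426
#> 2   evening    19  24  0.3577343  0.07154685 0.02291888
```

The decomposition reads: 74.71% of visitors accept the TOS, 58.14% of
accepters are picked up within the 60-second zero-wait window, 7.54% are
served after queueing, and the rest renege — an overall visitor-to-case
conversion of 49.07%. The dropout table shows the evening block (7 PM to
midnight) absorbing 35.8% of all abandonments, which is where additional
staffing buys the most conversion. `pledge_check(res)` flags, hour by hour,
whether the floor meets an "85% chance of service within 10 minutes / at
most one person in line" service pledge, and
`cost_effectiveness_curves()` locates the optimal roster at the intersection
of the normalized cost and failure-rate curves across candidate scenarios.

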