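---
title: "Modeling a 24/7 crisis-counseling floor: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling a 24/7 crisis-counseling floor: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`crisisim` simulates the operation of a text-based crisis-counseling service:
a small, shift-staffed floor of counselors answering a nonstationary stream
of chat requests from users who abandon the queue within minutes. This
vignette documents the statistical models, their assumptions, the tunable
parameters, and every numerically consequential design decision, so that a
reader can judge what a passing test suite does — and does not — establish
about a real service.

## 1. The arrival process

Chat requests are modeled as a nonhomogeneous Poisson process (NHPP) with
intensity $\lambda(t)$ in events per minute. The Poisson assumption rests on
the independent-increment property of deduplicated request streams: no two
requests from the same identifier are counted close together, so after
collapsing re-contacts the counting process is memoryless. Sampling uses
Lewis–Shedler thinning: candidates arrive at the constant dominating rate
$\lambda^* = \max_t \lambda(t)$ and a candidate at $t$ survives with
probability $\lambda(t)/\lambda^*$, which is exact for any bounded
intensity.

The terms-of-service (TOS) consent gate is an independent Bernoulli($p$)
mark on each arrival. By the thinning property the accepted substream is
again NHPP with intensity $p\,\lambda(t)$; `split_tos()` relies on this and
the tests verify it bin by bin.

Repeat users who fire several requests in quick succession violate
independent increments. They are represented by a subcritical Hawkes
process: *immigrants* arrive from the base intensity $\lambda_0(t)$ and
every event spawns a Poisson($\eta$) number of *offspring* at forward lags.
The memory kernel is exponential,
$\phi(u) = \eta\,\delta e^{-\delta u}$, the standard tractable choice; the
kernel's shape is not otherwise identified here because only the purged
(immigrant-only) stream feeds capacity planning, and purging is invariant to
the lag distribution. The branching ratio $\eta \in [0,1)$ and decay
$\delta > 0$ (per minute) ship without defaults and must be set by the user;
they are illustrative parameters, not fitted quantities — Hawkes estimation
from data is deliberately out of scope.

## 2. Demand aggregation and forecasting

`aggregate_interarrivals()` turns a log into a binned series: arrivals are
deduplicated to the first instance per identifier per 2-hour bin (a cheap
proxy for offspring purging), successive gaps are averaged within the bin of
the later arrival, and empty bins are linearly imputed and flagged. Two-hour
bins give $s = 12$ bins per day — fine enough to resolve the diurnal cycle,
coarse enough that bin means are stable.

The transformed series $\mathrm{BoxCox}(\bar\tau_a(t))$ is decomposed by an
unobserved-components state-space model: a random-walk local level, a
trigonometric seasonal of period 12 truncated at $\kappa$ harmonics,
optional campaign-dummy regressors, and an AR(1) irregular. Estimation is
Gaussian maximum likelihood through the Kalman filter; components come from
the fixed-interval smoother. Choices that matter numerically:

* **Deterministic seasonal by default.** The harmonic disturbance variances
  are fixed at zero (a parsimony choice); `stochastic_seasonal = TRUE` frees
  a common variance.
* **Harmonic cutoff by AICc.** When $\kappa$ is unspecified all cutoffs
  $1..s/2$ are fitted. Because each extra harmonic adds diffuse states, the
  selection likelihood is recomputed with a burn-in common to all candidates
  (the largest diffuse-state count); otherwise models would be compared on
  different subsets of the data. Diffuse states are counted as parameters in
  the AICc penalty.
* **Initialisation and optimisation.** Diffuse states start at variance
  $10^7 \times \mathrm{scale}$; the AR state starts at its stationary
  variance. Free variances are parameterised as
  $\mathrm{scale}\times e^\theta$ where the scale is the variance of the
  *differenced* series — unlike the raw variance it is not inflated by the
  wandering level, which keeps optimizer starts sane. Likelihood
  maximisation runs Nelder–Mead from two start points followed by an
  L-BFGS-B polish; the polish is discarded if it fails or worsens the
  objective. Standard errors come from the numerical Hessian with a delta
  step to the natural scale.
* **Degenerate inputs.** A tiny jitter ($10^{-8}\times$ scale) stabilises
  the one-step prediction variance so that noiseless and constant series
  filter cleanly; prediction variances are floored at the jitter. Missing
  bins are skipped by the filter rather than imputed.

Forecasts propagate the state recursion with 95% Gaussian intervals. Return
to the rate scale uses the bias-adjusted inverse Box–Cox transform — exact
lognormal mean $e^{m+v/2}$ at $\lambda = 0$, the second-order correction
$(\lambda m + 1)^{1/\lambda}\bigl[1 + \tfrac{v(1-\lambda)}{2(\lambda m+1)^2}\bigr]$
otherwise — so the back-transform estimates a mean, not a median. The
forecast rate is the reciprocal of the back-transformed mean interarrival.
The continuous $\lambda(t)$ handed to the sampler interpolates bin midpoints
with a monotone (Fritsch–Carlson) piecewise-cubic Hermite polynomial,
clipped below at $10^{-9}$/min. Because R's monotone filter can overshoot
knot values by a small amount, the audited `max_rate` carries 1% headroom —
a conservative dominating rate is always exact for thinning, merely slightly
wasteful.

## 3. Service durations and patience

Chat durations per (user type × risk level) stratum are modeled as
$\mathrm{scale}\times\mathrm{Beta}(\alpha,\beta)$, fitted by method of
moments after outlier removal, so the implied mean reproduces the sample
mean exactly. Two open choices were settled as follows:

* **Outlier rule.** Durations outside the Tukey fences
  $[Q_1 - 1.5\,\mathrm{IQR},\; Q_3 + 1.5\,\mathrm{IQR}]$ are removed, and
  the fences are re-applied until nothing changes. A single pass is not
  idempotent (trimming moves the quartiles); the iterated filter is, and on
  beta-like samples it trims only marginally more (≈0.7% vs ≈0.6% of a
  5,000-point sample).
* **Support.** The beta's upper bound is not identified by published
  summary tables, so the default is the maximum retained duration —
  preserving the observed range and keeping the moment fit well-posed. When
  the true support is known (as in recovery tests) it can be passed
  explicitly; when a model is built from published moments alone,
  `duration_model_from_moments()` defaults to mean + 4 SD, which covers the
  IQR-trimmed range of these strongly right-skewed durations. Method of
  moments is preferred to beta maximum likelihood because published tables
  report only means and SDs — moments are the reproducible surface.

Patience (time to renege) and virtual waiting time (time an infinitely
patient user would wait) are both exponential, per the queueing convention
for abandonment. Each queued case contributes one censored observation:
for patience, reneges are events and pickups censorings; for virtual wait,
the reverse. The censored MLE is $\hat\mu = \sum t_i / n_{\text{events}}$
with standard error $\hat\mu/\sqrt{n_{\text{events}}}$. Pickups within the
60-second zero-wait window are excluded from both fits — such cases never
queued, and removing them (a selection on the censoring variable only) does
not bias the exponential MLE. Whether the two user types need separate
patience models is decided by a standard two-group log-rank test
(`survival::survdiff` behind `logrank_test()`). Zombie cases (renege
followed by a later administrative pickup) count as reneges for patience and
as pickups for virtual wait.

## 4. The discrete-event engine

One replication replays, in continuous minutes:

* **Arrivals** from one of three sources: a fresh NHPP draw, a Hawkes draw,
  or round-robin recycling of an empirical interarrival list (reshuffled per
  replication; recycling tops the stream up so a 30-day sample exactly
  covers the 43,200-minute horizon).
* **A single FIFO case queue.** A free slot always takes the head case.
  Under zombie retention (the default, matching chat systems that cannot
  auto-evict), a reneged head still occupies a counselor for the post-chat
  survey time before the next case can be reached; under eviction it
  vanishes. Risk level is drawn at service start (risk is a counselor
  rating, so it cannot affect patience), then duration from the stratum's
  beta times `duration_scale`, then the survey overhead.
* **Shifts and breaks** as half-open daily windows $[s, e)$ per counselor;
  off-duty counselors accept no new cases but finish chats in progress.
  Contiguous windows are merged and, at boundary ties, off-events process
  before on-events.
* **Tie-breaking** at equal event times: service completions, then reneges
  (applied lazily at assignment: a case whose renege time has passed is
  gone), then arrivals — capacity frees before assignment decisions, and
  every run is reproducible bit for bit from its seed.
* **Zero-wait accounting** on the 1-second system clock, so tallies computed
  in the engine and tallies recomputed from the serialized CSV log agree
  exactly.

Hourly series (queue length and unused capacity sampled each minute,
dropouts, waits) are aggregated per hour of day; the bootstrap pools them
across replications and reports mean and 2.5/97.5-percentile envelopes.

Unprinted operational constants were set once and exposed in
`scenario_config()`: per-role concurrency 1 (duty officer) / 3 (full-time) /
2 (volunteer); cost weights 3 / 2 / 1.5; post-chat survey 5 minutes;
zero-wait window 60 seconds; 1,500 replications and a 43,200-minute horizon
as defaults. The shipped `base_case_schedule()` is a documented
*reconstruction* of a 15-counselor, four-shift roster with at-least-8
shift-wide concurrency, staggered 11:00–12:00 meal breaks, 14:00 and 17:00
afternoon starts, and a three-full-timer evening shift; the true timetable
behind the published figures is not public, so scenario-level conversion
numbers from this schedule are plausibility checks, not reproductions.

## 5. The synthetic-data generator

`generate_synthetic_log()` exists so every estimator is testable without any
real service database. Its defaults are the study conditions: TOS
acceptance 0.7478; 71.08% nonrepeat share; risk mixes of roughly 89/10/1
percent across low/medium/high-crisis; stratum duration moments matching the
published table (pooled low-risk mean 50.21, SD 31.65 minutes); patience
means 3.4550 (nonrepeat) and 5.2895 (repeat) minutes; and a stylised diurnal
intensity 0.2124 + 0.107·cos(2π(h − 21.5)/24) per minute — a busy month of
roughly 9,200 visitors per 30 days, peaking late evening and bottoming out
around 5 AM, chosen once from the published traffic descriptions.

Its occupancy emulation is deliberately crude: a fixed number of always-on
single-chat servers via the Lindley recursion, no shifts, no breaks, no
zombies. That suffices to create realistic censoring patterns for the
patience estimators, but it means passing recovery tests demonstrate
estimator correctness under the stated models — not that real chat logs
follow beta durations or exponential patience, nor that real queue dynamics
match the simple emulation. Channel labels are decorative; identities are
unique per arrival, so dedup-sensitive code paths must be exercised with
constructed logs (and are).

## 6. Analytics conventions

Conversion decomposes as
$\text{overall} = p_{\text{TOS}} \times (\text{frac}_{\text{immediate}} +
\text{frac}_{\text{queued-served}})$, with the immediate / queued-served /
reneged / in-system fractions partitioning accepted users. The same
decomposition is computed through two independent code paths (engine tallies
and a raw-log pass) and must agree exactly. Cost-effectiveness curves
min-max normalise cost and failure rate to a shared $[0,1]$ axis over the
evaluated capacity range — the two series carry unlike units, and an
intersection is otherwise unit-dependent — then interpolate piecewise
linearly and locate the crossing by root finding. A crossing requires an
interior sign change; endpoint coincidences manufactured by the
normalisation itself do not count, and curves that never trade off return a
no-intersection result rather than an error. Percentages are rounded half-up
to two decimals only at the reporting boundary. Dropout windows are
half-open $[{\rm start}, {\rm end})$ hours. The repeat-share estimate is the
forecast-gap ratio $(\text{actual} - \text{forecast})/\text{actual}$, valid
insofar as the purged forecast captures first-contact demand only.

## 7. Test problem sizes

The suite favours analytic oracles over golden values: Erlang-C mean waits
(single- and three-slot stations at utilisation 2/3, 200 replications of
6,000–10,000 minutes with warm-up discarded), the truncated birth–death
abandonment probability for an M/M/1+M station at utilisation 1, an
inversion (time-rescaling) sampler cross-checking the thinning sampler,
branching-process means for the Hawkes cluster construction, and
moment-matched 10⁶-draw samples for the distribution models. Recovery runs
use 5,000-case strata for the beta fit, ≥5,000 censored observations for
patience, and 720-bin series for the state-space model. These sizes were
chosen so Monte-Carlo error is small against each test's tolerance while
the whole suite stays desk-scale.

## 8. Known limitations

* Hawkes parameters are not estimable from data inside the package.
* Priority/triage queueing, language routing, transfers, counselor fatigue
  and IP-abuse suspensions are out of scope; the queue is strictly FIFO.
* The exponential patience model is a single-parameter summary; mixture or
  covariate-adjusted survival is not supported.
* Published scenario-level conversion figures depend on an unpublished
  timetable and cannot be reproduced exactly from this package's
  reconstruction; the package instead verifies the printed funnel
  arithmetic, table moments, and all structural laws of the machinery.
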