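---
title: "Scoring social competition and its prefrontal encoding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring social competition and its prefrontal encoding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hierphys)
```

`hierphys` re-implements, as a tested pipeline over plain CSV tables, the
analysis chain used in studies of social competition in group-housed mice
with chronic extracellular recording in the prelimbic (PL) subregion of
medial prefrontal cortex: dominance-hierarchy scoring from tube-test round
robins, warm-spot occupancy and pairwise food-competition trials; spike-
waveform unit typing; task-related unit categorization; day-wise population
delta z-score series across a 21-day intervention; and lagged
cross-correlation between neural-encoding change and behavioral change.
Because such studies typically deposit no raw recordings, the package ships
a synthetic-data generator with known ground truth, so every downstream
stage has a closed-loop test. This vignette documents the models, the
tunable parameters, the numerical choices, and what the synthetic conditions
do and do not establish about real data.

## Behavioral scoring

**Tube test.** Each day every pair of cagemates meets once; the mouse that
forces its opponent to retreat wins. `tube_daily_ranks()` counts wins per
mouse over the day's round robin and ranks by descending wins (rank 1 =
dominant). A day is *linear* when win counts are all distinct, i.e. the
transitive ladder N-1, ..., 0. Tied counts are broken by the head-to-head
result when exactly two mice tie and met that day, otherwise by lower mouse
id. The tie rule only needs to be deterministic: non-linear days never enter
downstream analysis. `detect_stable_hierarchy()` reads "stable linear rank
for over 3 days" as: the earliest day from which the ranking is linear and
identical for `window = 3` consecutive days (configurable).

**Tube-time inflection.** The settling of a hierarchy shortens bouts. The
inflection of the mean-duration-by-day series is operationalized as the
two-segment piecewise-constant least-squares change point (scanning all
split days and minimizing total within-segment squared error), valid only
when the after-segment mean is strictly lower; otherwise no inflection is
reported. The source studies show this inflection but never define an
estimator, so the least-squares change point is this package's declared
operationalization.

**Food competition.** Two mice are released from a shared starting area (SA)
and race to a reward zone (RZ) holding one pellet; consumption defines the
win. `winning_proportions()` scores, per pair, the fraction of trials each
mouse was first to exit the SA, first to reach the RZ, or consumed the
pellet; identical stage timestamps award 0.5 to each mouse so per-pair
proportions always sum to 1. `assign_competitive_order()` orders mice
(C1..CN) by descending overall pellet proportion, breaking ties by ascending
mean gate-open-to-RZ latency. Latency is anchored at gate open (release),
not SA exit, since "latency to reach the RZ" starts at release. The training
criterion is a daily mean latency under 5 s on two consecutive days.

**Warm spot.** One heated spot in a cold arena; only one mouse fits.
`warmspot_occupancy()` totals occupancy per 20-min session, validates totals
against the session length, and orders mice by occupancy.
`order_rank_correlation()` reports the Spearman correlation between the
competitive order and the tube ranking.

## Unit typing from waveform shape

Three features of the averaged waveform at the maximum-amplitude recording
site (`average_waveform()`, `extract_features()`):

* trough-to-peak (TP) latency: time from the global trough to the following
  positive peak (ms);
* half-width: width of the trough at half its depth, linearly interpolated
  between samples (ms);
* AUC: trapezoidal integral of the rectified waveform (uV.ms). Whether AUC
  should be computed on the signed or rectified waveform is not specified in
  the source description; the rectified version is used because it is
  monotone in spike size for biphasic shapes.

`classify_cell_types()` standardizes the three features and runs k-means
with k = 2 (50 random restarts, fixed seed, `stats::kmeans`); the cluster
with the smaller mean TP latency is labeled narrow-spiking (putative
inhibitory), the other broad-spiking (putative excitatory). On every random
instance with n <= 12 the returned partition equals the exhaustive
minimum-SSE 2-partition (tested against a brute-force oracle).

**Burst index.** The autocorrelogram is built over lags (0, 300] ms with
1-ms bins, zero-lag excluded (only the two bands are prescribed by the field
definition; the bin width and range are package choices). The index is the
mean bin count at lags in [3, 5] ms divided by the mean count at lags in
[200, 300] ms; a homogeneous Poisson train gives 1 in expectation, bursty
(doublet-firing) units give large values. An empty denominator band yields
`NA` flagged `undefined` rather than an error. The type split is
corroborated by `validate_bimodality()`: a parametric-bootstrap
likelihood-ratio test of a 2-component versus 1-component univariate
Gaussian mixture (mclust) on the pooled burst indices, passing when p <
0.05 and the broad-spiking cluster is the burstier one. A mixture LRT was
chosen as the bimodality test because it gives a calibrated p-value with a
fully specified null and is available in the standard toolchain.

## Task-related categorization

Per-trial firing rates are spike counts in the half-open window
[RZ entry - 2 s, RZ entry + 2 s) divided by the window length
(`trial_firing_rates()`). The window anchor and extent are configurable;
the source protocol defers its exact window to prior work without restating
it, so the symmetric 4-s window at RZ entry is a declared default.

`classify_task_related()` runs two contrasts per unit: win vs loss trials
(competition) and dominant- vs subordinate-opponent trials (rank), at
alpha = 0.05 per unit with no correction across units, mirroring the
per-unit treatment of the source analyses. The default test is a **van
Elteren stratified rank-sum test**: the competition contrast is stratified
by opponent rank and the rank contrast by trial outcome. Stratification
matters because outcome and opponent rank are behaviorally confounded — a
mouse wins more often against subordinate opponents — so a marginal
two-sample test falsely flags purely competition-modulated units as
rank-related through that association (in simulation, roughly 40% of true
competition-only units acquire a spurious rank flag marginally; the
stratified test holds the rate at alpha). The marginal Mann-Whitney U and a
Welch t alternative remain available (`stratified = FALSE`,
`test = "welch"`). Complete ties in every stratum give p = 1 (no evidence),
and a condition with fewer than `min_trials = 5` trials marks the unit
unclassifiable; such units are excluded from numerators and denominators of
population summaries.

Categories follow the two significance flags: both flags on = both-related,
one on = competition- or rank-related, neither = non-related.
`summarize_population()` cross-tabulates cell type by category and reports
percentages at three scopes (all, excitatory, inhibitory) rounded
half-away-from-zero to one decimal — the rounding that reproduces all ten
published percentages of the reference cross-tabulation (86/22/14/166 of
288 excitatory; 12/10/6/63 of 91 inhibitory).

```{r summary-example}
types <- rep(c("excitatory", "inhibitory"), c(288, 91))
cats <- c(rep(c("competition", "rank", "both", "non"), c(86, 22, 14, 166)),
          rep(c("competition", "rank", "both", "non"), c(12, 10, 6, 63)))
ids <- sprintf("u%03d", seq_along(types))
summarize_population(data.frame(unit_id = ids, cell_type = types),
                     data.frame(unit_id = ids, category = cats))
```

## Longitudinal delta z-scores and cross-correlation

`delta_zscore_series()` z-scores the daily population mean rate against the
baseline day's per-trial distribution, z_d = (mean_d - mean_0)/SD_0, and
expresses the series as change from day 0 (so it starts at 0). The
population-pooled form is the default; whether the source computed per-unit
z-scores first is not stated.

`cross_correlate()` computes the Pearson correlation between `x_t` and
`y_(t+l)` for every lag l in [-max_lag, max_lag] on the overlapping
segment. Positive lag means y lags x; with x the neural series and y the
behavioral one, a positive peak lag means encoding leads behavior. Peak-lag
ties prefer the smaller |lag|, then the negative one. The default max_lag of
15 days on a 21-day series keeps at least 6 overlapping points; both
functions refuse series shorter than max_lag + 3 (a single consistent
length rule, since the alternative of requiring 2 x max_lag points would
reject the design's own defaults). Zero-variance overlaps yield `NA` at
that lag rather than an error.

`significance_band()` builds a per-lag null from circular shifts of y by
uniform random offsets — preserving each series' autocorrelation while
destroying alignment, which is the property a lag test must not borrow —
with two-sided add-one-corrected empirical p-values. The source cites prior
work for its significance band without details; the circular-shift null is
this package's declared stand-in. Type-I error is verified by simulation to
sit at the nominal level per lag.

## The synthetic generator: what it emulates

`gen_config()` fixes the study conditions; all randomness flows from one
seed through stable per-(stage, group, unit) hashed sub-streams, so runs are
bit-reproducible and adding units does not perturb existing ones.

* **Population.** 379 units, 288/91 broad/narrow, task categories in the
  reference proportions. Quota mode (default) applies largest-remainder
  quotas so worked examples are exact; sampling mode draws multinomially.
  Waveform features come from per-type Gaussians (broad: TP 0.65 +/- 0.08 ms,
  half-width 0.26 +/- 0.035 ms, AUC 60 +/- 9; narrow: 0.25 +/- 0.04,
  0.12 +/- 0.018, 28 +/- 5) — values in the range reported for cortical
  broad- vs narrow-spiking units, separated enough that k-means recovers the
  split exactly, as the reference classification did. Waveforms are
  synthesized as biphasic templates (Gaussian trough sized to the half-width
  and AUC, delayed Gaussian peak at 35% amplitude) rather than from tetrode
  geometry; feature extraction on the synthesized shape reproduces the
  targets to within a few hundredths of a millisecond.
* **Sessions.** Round-robin pairs, 10 trials per pair per day alternating
  the shared starting area, pellet winner from a logistic (Bradley-Terry)
  model p = plogis((c_i - c_j)/tau) on latent competitiveness — the simplest
  exchangeable contest model, since none is specified by the protocol. The
  default ladder c = (0.6, 0.2, -0.2, -0.6) with tau = 2 yields a clear
  expected order but moderately biased single trials. That moderation is a
  modeling requirement, not a convenience: were outcome a near-deterministic
  function of opponent rank, the win/loss and opponent-rank contrasts would
  be confounded at the trial level and no per-unit test could attribute
  modulation. Four recorded session days (120 trials for the implanted,
  mid-ranked mouse) are pooled per unit.
* **Spike trains.** Homogeneous Poisson at 5 Hz per unit, multiplied by
  `modulation_gain = 2` inside the analysis window on win trials
  (competition-modulated), dominant-opponent trials (rank-modulated), or one
  factor gain each (both-modulated — multiplicative, so both contrasts stay
  identifiable). Broad-spiking units emit 3-5 ms doublet companions with
  probability 0.3, making them the bursty class.
* **Tube/warm spot.** Daily round robins for 21 days; upset probability
  decays linearly from `tube_noise = 0.4` to 0 at the stable day (day 5);
  bout durations are gamma with mean 25 s before and 8 s after the stable
  day. Warm-spot occupancy is a softmax of latent dominance with lognormal
  noise (SD 0.15); at zero noise the occupancy order equals dominance.
* **Intervention series.** Day 0 = intervention start, 21 days.
  Competition-related gain declines from 2 to 1 along a logistic ramp with
  midpoint 5 days after onset and time scale 1.25 days; the rank-related
  gain follows the identical ramp delayed by `rank_lag_days = 10` — the lag
  the reference study reports between rank- and competition-encoding change.
  The winning proportion is coupled to the competition ramp with zero lag,
  falling from 0.75 to 0.2 (the intervention demotes the subject below its
  cagemates); daily values are binomial over 30 trials. Per-day, per-trial
  population rates are Poisson counts over 30 units in the 4-s window.

With these conditions the rank-vs-competition cross-correlogram peaks at
+10 days in every one of 100 seeded replicates, and the winning-proportion
vs competition-encoding correlogram peaks at 0 modally (61% of seeds, 97%
within +/-1 day): the +/-1-day scatter is exactly the binomial noise a
30-trial/day behavioral series carries on a 21-day grid, so a per-seed
exact-zero requirement would be unattainable at realistic trial counts.

**What passing tests do not show.** The generator draws stationary Poisson
spiking, exchangeable trials, a single latent competitiveness scale, and
noise-free event detection. Real recordings have non-Poisson firing,
slow drifts, unit loss across days, imperfect spike sorting, and behavioral
nonstationarities none of which are modeled; closed-loop recovery here
validates the *estimators*, not the biological claims.

## Problem sizes and determinism

Defaults are desk-scale by design: 379 units x 120 trials for the
classification chain, 21-day series with 1000 circular shifts for the
significance band, 100 seeds for lag-recovery summaries. Every stochastic
stage takes an explicit seed; `run_pipeline()` writes a manifest recording
seed and parameters, and rerunning a configuration reproduces every output
byte-for-byte (timestamps aside). The interchange format is RFC-4180 CSV
(UTF-8, header row) plus JSON for summaries; the run configuration is YAML
with unknown keys rejected at every level. The numbered scripts under
`analysis/` are the command-line entry points: each is a thin driver over
the package functions, readable top to bottom as the narrative of one
analysis stage.

## Known limitations

* The task-relatedness criterion of the original recordings is deferred to
  prior literature and not restated there; the stratified rank-sum default
  is this package's construction and other criteria (marginal tests,
  windows, baselines) may categorize borderline units differently.
* The tube-rank series is a latent expectation, not a re-scored tournament;
  hysteresis between encoding change and rank change is imposed, not
  emergent.
* `tube_time_inflection()` fits exactly two segments; multi-phase duration
  profiles will be summarized by their single largest drop.
* Percentages are rounded half-away-from-zero to one decimal to match the
  published table convention; consumers needing exact fractions should use
  the counts.
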