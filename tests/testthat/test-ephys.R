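test_that("average_waveform picks the largest-amplitude site", {
  template <- synthesize_waveform(0.5, 0.25, 60, 20000)$amplitude_uv
  sites <- list(s1 = rbind(template, template),
                s2 = rbind(2 * template, 2 * template))
  got <- average_waveform(sites)
  expect_equal(got$site, "s2")
  expect_equal(got$waveform, 2 * template) # idempotent mean of identical spikes

  # mean of noisy copies converges to the template (RMS error ~ 1/sqrt(N))
  set.seed(1)
  rms_at <- function(N) {
    spikes <- t(replicate(N, template + stats::rnorm(length(template), 0, 5)))
    sqrt(mean((average_waveform(list(a = spikes))$waveform - template)^2))
  }
  r4 <- mean(replicate(20, rms_at(4)))
  r64 <- mean(replicate(20, rms_at(64)))
  expect_equal(r4 / r64, 4, tolerance = 0.25)

  expect_error(average_waveform(list(a = matrix(0, 2, 10))), "all-zero")
  expect_error(average_waveform(list(a = matrix(1, 2, 10),
                                     b = matrix(1, 2, 8))), "sample count")
})

test_that("waveform features match constructed geometry", {
  rate <- 100000 # 0.01 ms resolution
  t_ms <- seq(0, 3, by = 1000 / rate)

  # trough at 1.0 ms, peak at 1.5 ms
  w <- -100 * exp(-(t_ms - 1)^2 / (2 * 0.05^2)) +
    40 * exp(-(t_ms - 1.5)^2 / (2 * 0.1^2))
  f <- extract_features(w, rate)
  expect_equal(f$tp_latency_ms, 0.5, tolerance = 0.02)

  # rectangular trough of depth -100 from 0.9 to 1.1 ms: half-width 0.2 ms
  wr <- ifelse(t_ms >= 0.9 & t_ms <= 1.1, -100, 0)
  wr[t_ms > 1.3 & t_ms < 1.4] <- 20 # small late peak to stay biphasic
  fr <- extract_features(wr, rate)
  # instantaneous edges are interpolated across one sample on each flank
  expect_lt(abs(fr$half_width_ms - 0.2), 1.5 * 1000 / rate)

  # triangle: |area| equals closed-form 0.5 * base * height
  wt <- numeric(length(t_ms))
  base_idx <- t_ms >= 0.8 & t_ms <= 1.2
  wt[base_idx] <- -100 * (1 - abs(t_ms[base_idx] - 1) / 0.2)
  wt[t_ms > 1.5 & t_ms < 1.6] <- 10
  ft <- extract_features(wt, rate)
  tri_area <- 0.5 * 0.4 * 100
  expect_equal(ft$auc, tri_area + 0.1 * 10, tolerance = 0.5)

  expect_error(extract_features(-abs(sin(t_ms)), rate), "monophasic")
})

test_that("synthesized waveforms round-trip their target features", {
  set.seed(3)
  for (r in 1:10) {
    tp <- stats::runif(1, 0.2, 0.8)
    hw <- stats::runif(1, 0.1, 0.3)
    auc <- stats::runif(1, 20, 80)
    w <- synthesize_waveform(tp, hw, auc, 40000)
    f <- extract_features(w$amplitude_uv, 40000)
    # trough/peak overlap biases the read-back slightly; bounds are absolute
    expect_lt(abs(f$tp_latency_ms - tp), 0.09)
    expect_lt(abs(f$half_width_ms - hw), 0.05)
    expect_lt(abs(f$auc - auc) / auc, 0.05)
  }
})

test_that("cell-type clustering recovers separated populations and labels", {
  cfg <- gen_config(seed = 12, n_units = 120)
  pop <- generate_unit_population(cfg)
  feats <- pop$units[, c("unit_id", "tp_latency_ms", "half_width_ms", "auc")]
  ct <- classify_cell_types(feats, seed = 4)
  expect_equal(ct$cell_type, pop$truth$cell_type)

  same <- data.frame(unit_id = c("a", "b"), tp_latency_ms = 1,
                     half_width_ms = 1, auc = 1)
  expect_error(classify_cell_types(same), "degenerate")
})

test_that("small-n clustering equals the exhaustive minimum-SSE partition", {
  set.seed(11)
  for (r in 1:50) {
    n <- sample(4:12, 1)
    X <- cbind(stats::rnorm(n), stats::rnorm(n), stats::rnorm(n))
    feats <- data.frame(unit_id = sprintf("u%02d", 1:n),
                        tp_latency_ms = X[, 1], half_width_ms = X[, 2],
                        auc = X[, 3])
    km <- classify_cell_types(feats, seed = r)
    oracle <- brute_force_two_partition(X)
    # same partition up to label swap
    agree <- mean((km$cluster_id - 1) == oracle$assignment)
    expect_true(agree %in% c(0, 1))
  }
})

test_that("burst index is ~1 for Poisson trains and exact for doublet trains", {
  set.seed(5)
  bis <- replicate(25, burst_index(cumsum(stats::rexp(3000, 5))))
  se <- stats::sd(bis) / sqrt(length(bis))
  expect_lt(abs(mean(bis) - 1), 3 * se)

  # doublet train: pairs (k, k + 4 ms) every 250 ms for 300 s
  n_pairs <- 1200
  starts <- (seq_len(n_pairs) - 1) * 0.25
  train <- sort(c(starts, starts + 0.004))
  # hand-counted autocorrelogram: bin (3,4] gets n_pairs; adjacent-pair lags
  # 246, 250 (twice), 254 ms give 4*(n_pairs-1) counts in the 200-300 band
  expected <- (n_pairs / 2) / (4 * (n_pairs - 1) / 100)
  expect_equal(burst_index(train), expected, tolerance = 1e-12)

  expect_error(burst_index(1.0), "2 spikes")
  two <- burst_index(c(0, 0.004))
  expect_true(is.na(two))
  expect_true(isTRUE(attr(two, "undefined")))
  # translation invariance
  expect_equal(burst_index(train + 123.4), burst_index(train))
})

test_that("bimodality validation separates mixtures from single Gaussians", {
  set.seed(6)
  bi_mix <- c(stats::rnorm(100, 1, 0.2), stats::rnorm(100, 4, 0.2))
  ct_mix <- rep(c("inhibitory", "excitatory"), each = 100)
  v <- validate_bimodality(bi_mix, ct_mix, nboot = 60, seed = 2)
  expect_true(v$pass)
  expect_lt(v$p_value, 0.05)

  bi_uni <- stats::rnorm(200, 2, 0.5)
  vu <- validate_bimodality(bi_uni, rep(c("excitatory", "inhibitory"), 100),
                            nboot = 60, seed = 2)
  expect_false(vu$pass)

  expect_error(validate_bimodality(stats::rnorm(5), rep("excitatory", 5)),
               "10 units")
  expect_error(validate_bimodality(rep(1, 20), rep("excitatory", 20)),
               "constant")
})

test_that("trial firing rates use the half-open window convention", {
  trials <- data.frame(trial_id = c("t1", "t2"), t_reach_rz_s = c(10, 50))
  spikes <- data.frame(unit_id = "u1",
                       spike_time_s = c(seq(8.1, 11.9, length.out = 10),
                                        48, 52)) # t2 window [48,52) empty at 52
  r <- trial_firing_rates(spikes, trials, window = c(-2, 2))
  expect_equal(r$rate_hz[r$trial_id == "t1"], 10 / 4)
  # spike exactly at window start counts, at window end does not
  expect_equal(r$rate_hz[r$trial_id == "t2"], 1 / 4)
  expect_error(trial_firing_rates(spikes, data.frame(trial_id = "x"),
                                  window = c(-2, 2)), "anchor")
})

test_that("task classifier finds constructed effects and respects min_trials", {
  # identical distributions in both contrasts: non-related
  fx <- make_rate_fixture(80, function(won, dom) rep(5, 80), seed = 2)
  got <- classify_task_related(fx$rates, fx$trials)
  expect_equal(got$category, "non")

  # 3x win-trial rate: competition-related in >= 95% of replicates
  hits <- 0L
  for (r in 1:40) {
    fx <- make_rate_fixture(40, function(won, dom) {
      stats::rpois(length(won), ifelse(won, 15, 5) * 4) / 4
    }, seed = 100 + r)
    got <- classify_task_related(fx$rates, fx$trials)
    if (got$category %in% c("competition", "both")) hits <- hits + 1L
  }
  expect_gte(hits / 40, 0.95)

  # unclassifiable when one condition has too few trials
  fx <- make_rate_fixture(12, function(won, dom) stats::rpois(12, 20) / 4,
                          seed = 3, p_win = 0.05)
  got <- classify_task_related(fx$rates, fx$trials, min_trials = 5L)
  expect_true(is.na(got$category))
})

test_that("task classifier type-I error stays at the nominal level", {
  set.seed(9)
  n_units <- 400
  flags_c <- flags_r <- logical(n_units)
  fx0 <- make_rate_fixture(120, function(won, dom) stats::rpois(120, 20) / 4,
                           seed = 1, p_win = 0.55, p_dom = 1 / 3)
  for (u in seq_len(n_units)) {
    rates <- fx0$rates
    rates$rate_hz <- stats::rpois(120, 20) / 4
    got <- classify_task_related(rates, fx0$trials)
    flags_c[u] <- got$p_competition < 0.05
    flags_r[u] <- got$p_rank < 0.05
  }
  se <- sqrt(0.05 * 0.95 / n_units)
  expect_lt(abs(mean(flags_c) - 0.05), 3 * se)
  expect_lt(abs(mean(flags_r) - 0.05), 3 * se)
})

test_that("detection power rises with modulation gain and trial count", {
  power_at <- function(gain, n_trials) {
    hits <- 0L
    for (r in 1:25) {
      fx <- make_rate_fixture(n_trials, function(won, dom) {
        stats::rpois(length(won), ifelse(won, gain * 5, 5) * 4) / 4
      }, seed = 1000 * gain + 10 * n_trials + r)
      got <- classify_task_related(fx$rates, fx$trials)
      if (got$category %in% c("competition", "both")) hits <- hits + 1L
    }
    hits / 25
  }
  p <- outer(c(1.3, 1.6, 2.2), c(24, 60), Vectorize(power_at))
  expect_true(all(diff(p[, 1]) >= 0 | p[-1, 1] > 0.9))
  expect_true(all(p[, 2] >= p[, 1] - 0.1))
  expect_gt(p[3, 2], p[1, 1])
})

test_that("population summary reproduces the recorded cross-tabulation", {
  counts <- c(excitatory = c(competition = 86, rank = 22, both = 14, non = 166),
              inhibitory = c(competition = 12, rank = 10, both = 6, non = 63))
  types <- rep(c("excitatory", "inhibitory"), c(288, 91))
  cats <- c(rep(c("competition", "rank", "both", "non"), c(86, 22, 14, 166)),
            rep(c("competition", "rank", "both", "non"), c(12, 10, 6, 63)))
  ids <- sprintf("u%03d", seq_along(types))
  summ <- summarize_population(
    data.frame(unit_id = ids, cell_type = types),
    data.frame(unit_id = ids, category = cats)
  )
  expect_equal(summ$totals[["all"]], 379)
  p_all <- summ$percentages$all
  expect_equal(unname(p_all[c("competition", "rank", "both")]),
               c(25.9, 8.4, 5.3))
  p_exc <- summ$percentages$excitatory
  expect_equal(unname(p_exc[c("competition", "rank", "both", "task_related")]),
               c(29.9, 7.6, 4.9, 42.4))
  p_inh <- summ$percentages$inhibitory
  expect_equal(unname(p_inh[c("competition", "rank", "both")]),
               c(13.2, 11.0, 6.6))
  # scope percentages sum to 100 within rounding slack
  for (scope in names(summ$percentages)) {
    s <- sum(summ$percentages[[scope]][c("competition", "rank", "both", "non")])
    expect_lt(abs(s - 100), 0.3)
  }
})

test_that("population summary flags mismatches and NA categories", {
  ct <- data.frame(unit_id = c("a", "b"), cell_type = c("excitatory", "inhibitory"))
  expect_error(summarize_population(ct, data.frame(unit_id = "a",
                                                   category = "non")),
               "only one table")
  cats <- data.frame(unit_id = c("a", "b"), category = c("non", NA))
  summ <- summarize_population(ct, cats)
  expect_equal(summ$totals[["all"]], 1) # unclassifiable excluded
  empty <- summarize_population(ct[0, ], cats[0, ])
  expect_equal(unname(empty$totals[["all"]]), 0)
  expect_true(all(is.na(empty$percentages$all)))
})

test_that("delta z-score series follow their definition", {
  rates <- expand.grid(day = 0:3, trial = 1:20)
  rates$category <- "competition"
  set.seed(8)
  base <- stats::rnorm(20, 10, 1)
  rates$rate_hz <- NA_real_
  rates$rate_hz[rates$day == 0] <- base
  m0 <- mean(base); s0 <- stats::sd(base)
  for (d in 1:3) rates$rate_hz[rates$day == d] <- base # identical days
  dz <- delta_zscore_series(rates, 0)
  expect_equal(dz$delta_z, rep(0, 4))

  rates$rate_hz[rates$day == 2] <- base + 2 * s0
  dz2 <- delta_zscore_series(rates, 0)
  expect_equal(dz2$delta_z[dz2$day == 2], 2, tolerance = 1e-10)

  const <- rates; const$rate_hz <- 5
  expect_error(delta_zscore_series(const, 0), "zero baseline SD")

  # generator with declining gain: series decreases (Spearman rho < 0)
  neg <- 0L
  for (r in 1:20) {
    long <- generate_longitudinal(gen_config(seed = 400 + r))
    s <- delta_zscore_series(long$rates, 0)
    s <- s[s$category == "competition", ]
    if (stats::cor(s$day, s$delta_z, method = "spearman") < 0) neg <- neg + 1L
  }
  expect_gte(neg / 20, 0.9)
})

test_that("mEPSC filter applies the stated acceptance rule", {
  ev <- data.frame(
    amplitude_pa = c(6, 4, 6, 6, 5, 8),
    rise_rate_pa_per_ms = c(0.5, 0.5, 0.2, 0.5, 0.5, 0.3),
    decay_tau_ms = c(5, 5, 5, 13, 5, 1)
  )
  kept <- filter_mepsc_events(ev)
  expect_equal(rownames(kept), c("1", "6")) # inside bounds; tau = 1 inclusive
  expect_error(filter_mepsc_events(ev[, 1:2]), "missing field")
  ev_na <- ev; ev_na$amplitude_pa[1] <- NA
  expect_error(filter_mepsc_events(ev_na), "missing measurement")
})
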