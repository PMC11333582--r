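#' Average waveform at the maximum-amplitude recording site
#'
#' Averages per-spike waveforms within each recording site and returns the
#' averaged waveform of the site with the largest peak-to-trough amplitude,
#' which is the waveform used for feature extraction.
#'
#' @param site_waveforms named list of numeric matrices (spikes x samples),
#'   one per recording site.
#' @return list(site, waveform) with the mean waveform as a numeric vector.
#' @export
average_waveform <- function(site_waveforms) {
  stopifnot(is.list(site_waveforms), length(site_waveforms) >= 1L)
  ns <- vapply(site_waveforms, ncol, integer(1))
  if (length(unique(ns)) != 1L) stop("sites must share sample count", call. = FALSE)
  means <- lapply(site_waveforms, colMeans)
  amp <- vapply(means, function(w) max(w) - min(w), numeric(1))
  if (all(amp == 0)) stop("all-zero waveforms", call. = FALSE)
  best <- which.max(amp)
  list(site = names(site_waveforms)[best] %||% best, waveform = means[[best]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract waveform shape features
#'
#' Computes the three features used to segregate narrow- from broad-spiking
#' units: trough-to-peak latency (time from the global trough to the
#' following positive peak), trough half-width (width at half the trough
#' depth, linearly interpolated between samples), and AUC (trapezoidal
#' integral of the rectified waveform).
#'
#' @param waveform numeric amplitude vector (uV), trough-negative.
#' @param sampling_rate_hz sampling rate of the waveform.
#' @return data.frame(tp_latency_ms, half_width_ms, auc).
#' @export
extract_features <- function(waveform, sampling_rate_hz) {
  n <- length(waveform)
  dt_ms <- 1000 / sampling_rate_hz
  t_ms <- (seq_len(n) - 1) * dt_ms
  i_tr <- which.min(waveform)
  if (waveform[i_tr] >= 0 || i_tr == n) {
    stop("monophasic waveform: no negative trough followed by a peak",
         call. = FALSE)
  }
  after <- waveform[(i_tr + 1):n]
  i_pk <- i_tr + which.max(after)
  if (waveform[i_pk] <= 0) {
    stop("monophasic waveform: no positive peak after the trough",
         call. = FALSE)
  }
  tp <- t_ms[i_pk] - t_ms[i_tr]
  half <- waveform[i_tr] / 2
  # crossing of the half-depth level on each flank, linear interpolation
  cross_left <- NA_real_
  for (i in seq(i_tr, 2)) {
    if (waveform[i - 1] > half && waveform[i] <= half) {
      f <- (half - waveform[i - 1]) / (waveform[i] - waveform[i - 1])
      cross_left <- t_ms[i - 1] + f * dt_ms
      break
    }
  }
  cross_right <- NA_real_
  for (i in seq(i_tr, n - 1)) {
    if (waveform[i] <= half && waveform[i + 1] > half) {
      f <- (half - waveform[i]) / (waveform[i + 1] - waveform[i])
      cross_right <- t_ms[i] + f * dt_ms
      break
    }
  }
  if (is.na(cross_left) || is.na(cross_right)) {
    stop("trough does not cross its half-depth on both flanks", call. = FALSE)
  }
  data.frame(tp_latency_ms = tp, half_width_ms = cross_right - cross_left,
             auc = trapezoid(t_ms, abs(waveform)))
}

#' Feature table for many units from a long waveform table
#'
#' @param waveforms long table (unit_id, time_ms or sample_idx, amplitude_uv).
#' @param sampling_rate_hz sampling rate.
#' @return data.frame(unit_id, tp_latency_ms, half_width_ms, auc).
#' @export
extract_features_table <- function(waveforms, sampling_rate_hz) {
  out <- lapply(split(waveforms, waveforms$unit_id), function(wu) {
    wu <- wu[order(wu$sample_idx), ]
    cbind(data.frame(unit_id = wu$unit_id[1], stringsAsFactors = FALSE),
          extract_features(wu$amplitude_uv, sampling_rate_hz))
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Classify units into excitatory and inhibitory types
#'
#' Standardizes the three waveform features (zero mean, unit variance per
#' dimension) and runs k-means with k = 2 and many random restarts under a
#' fixed seed. The cluster with the smaller mean trough-to-peak latency is
#' labeled inhibitory (narrow-spiking); the other excitatory (broad-spiking).
#'
#' @param features data.frame(unit_id, tp_latency_ms, half_width_ms, auc).
#' @param seed RNG seed for the restarts.
#' @param nstart number of random restarts.
#' @return data.frame(unit_id, cell_type, cluster_id).
#' @export
classify_cell_types <- function(features, seed = 1L, nstart = 50L) {
  stopifnot(nrow(features) >= 2L)
  X <- as.matrix(features[, c("tp_latency_ms", "half_width_ms", "auc")])
  if (any(!is.finite(X))) stop("non-finite features", call. = FALSE)
  if (all(apply(X, 2, function(col) length(unique(col)) == 1L))) {
    stop("degenerate clustering: all units identical", call. = FALSE)
  }
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0] <- 1
  Xs <- scale(X, center = TRUE, scale = sds)
  km <- with_substream(seed, "kmeans", expr = {
    stats::kmeans(Xs, centers = 2L, nstart = nstart, iter.max = 100L)
  })
  mean_tp <- tapply(features$tp_latency_ms, km$cluster, mean)
  narrow <- as.integer(names(mean_tp)[which.min(mean_tp)])
  data.frame(
    unit_id = features$unit_id,
    cell_type = ifelse(km$cluster == narrow, "inhibitory", "excitatory"),
    cluster_id = km$cluster, stringsAsFactors = FALSE
  )
}

#' Autocorrelogram burst index
#'
#' Builds the spike-train autocorrelogram over (0, `max_lag_ms`] with
#' `bin_ms` bins (zero-lag excluded) and returns the mean bin count at lags
#' in the 3-5 ms band divided by the mean bin count at lags in the 200-300 ms
#' band. Bursty units fire doublets at short inter-spike intervals, inflating
#' the numerator band.
#'
#' @param spike_times spike times in seconds, any order.
#' @param bin_ms bin width (must divide the band edges).
#' @param max_lag_ms autocorrelogram extent.
#' @return scalar burst index; `NA` (with attribute `undefined = TRUE`) when
#'   the 200-300 ms band is empty.
#' @export
burst_index <- function(spike_times, bin_ms = 1, max_lag_ms = 300) {
  if (length(spike_times) < 2L) stop("need at least 2 spikes", call. = FALSE)
  edges <- c(3, 5, 200, 300)
  if (any(abs(edges / bin_ms - round(edges / bin_ms)) > 1e-9)) {
    stop("bin_ms must divide the 3-5 and 200-300 ms band edges", call. = FALSE)
  }
  t <- sort(spike_times) * 1000 # ms
  n <- length(t)
  counts <- integer(max_lag_ms / bin_ms)
  k <- 1L
  repeat {
    if (k >= n) break
    d <- t[(1 + k):n] - t[1:(n - k)]
    d <- d[d <= max_lag_ms & d > 0]
    if (!length(d)) break
    b <- ceiling(d / bin_ms)
    tb <- tabulate(b, nbins = length(counts))
    counts <- counts + tb
    k <- k + 1L
  }
  in_band <- function(lo, hi) {
    b <- seq_len(length(counts))
    counts[(b - 1) * bin_ms >= lo & b * bin_ms <= hi]
  }
  num <- mean(in_band(3, 5))
  den <- mean(in_band(200, 300))
  if (den == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  num / den
}

#' Validate the type split by burst-index bimodality
#'
#' The narrow/broad split is corroborated when the pooled burst-index
#' distribution is bimodal and the cluster means differ in the expected
#' direction (broad-spiking excitatory units burstier). Bimodality is tested
#' with a parametric-bootstrap likelihood-ratio test of a 2-component versus
#' 1-component univariate Gaussian mixture (mclust).
#'
#' @param burst_indices numeric burst index per unit.
#' @param cell_types character vector ("excitatory"/"inhibitory") aligned
#'   with `burst_indices`.
#' @param nboot bootstrap replicates; @param alpha test level;
#' @param seed RNG seed.
#' @return list(statistic, p_value, mean_excitatory, mean_inhibitory, pass).
#' @export
validate_bimodality <- function(burst_indices, cell_types, nboot = 100L,
                                alpha = 0.05, seed = 1L) {
  ok <- is.finite(burst_indices)
  bi <- burst_indices[ok]; ct <- cell_types[ok]
  if (length(bi) < 10L) stop("need at least 10 units", call. = FALSE)
  if (stats::sd(bi) == 0) stop("constant burst indices", call. = FALSE)
  lrt <- with_substream(seed, "bimodality", expr = {
    quiet <- utils::capture.output(
      res <- mclust::mclustBootstrapLRT(bi, modelName = "V", maxG = 1L,
                                        nboot = nboot, verbose = FALSE)
    )
    res
  })
  stat <- lrt$obs[1]
  p <- lrt$p.value[1]
  m_exc <- mean(bi[ct == "excitatory"])
  m_inh <- mean(bi[ct == "inhibitory"])
  list(statistic = stat, p_value = p,
       mean_excitatory = m_exc, mean_inhibitory = m_inh,
       pass = is.finite(p) && p < alpha && m_exc > m_inh)
}

#' Per-trial firing rates in an event-anchored window
#'
#' Counts spikes in the half-open window `[event + a, event + b)` around the
#' anchor event of each trial and divides by the window length.
#'
#' @param spikes data.frame(unit_id, spike_time_s).
#' @param trials trial table; one row per (trial, subject perspective).
#' @param window numeric c(a, b) in seconds relative to the anchor.
#' @param anchor trial column holding the anchor timestamp.
#' @return data.frame(unit_id, trial_id, rate_hz).
#' @export
trial_firing_rates <- function(spikes, trials, window = c(-2, 2),
                               anchor = "t_reach_rz_s") {
  if (!anchor %in% names(trials) || any(is.na(trials[[anchor]]))) {
    stop(sprintf("trials lack anchor event '%s'", anchor), call. = FALSE)
  }
  dur <- window[2] - window[1]
  spl <- split(spikes$spike_time_s, spikes$unit_id)
  out <- list()
  for (uid in names(spl)) {
    st <- sort(spl[[uid]])
    lo <- trials[[anchor]] + window[1]
    hi <- trials[[anchor]] + window[2]
    k <- findInterval(hi - 1e-12, st) - findInterval(lo - 1e-12, st)
    out[[length(out) + 1L]] <- data.frame(
      unit_id = uid, trial_id = trials$trial_id, rate_hz = k / dur,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Stratified (van Elteren) rank-sum test
#'
#' Two-sided Wilcoxon rank-sum test of `x[g]` vs `x[!g]` combined across
#' strata with the van Elteren weights 1/(N_s + 1), normal approximation
#' with mid-ranks and tie-corrected variance. Strata missing either group
#' contribute nothing; with a single stratum this reduces to the ordinary
#' normal-approximation Mann-Whitney U test.
#'
#' @param x numeric response; @param g logical group indicator;
#' @param strata stratum labels (same length).
#' @return two-sided p-value (NA when no stratum holds both groups).
#' @export
van_elteren_test <- function(x, g, strata = rep(1L, length(x))) {
  stopifnot(length(x) == length(g), length(g) == length(strata))
  T_ <- E_ <- V_ <- 0
  any_str <- FALSE
  for (s in unique(strata)) {
    xs <- x[strata == s]; gs <- g[strata == s]
    m <- sum(gs); nn <- sum(!gs); N <- m + nn
    if (m == 0 || nn == 0) next
    any_str <- TRUE
    r <- rank(xs)
    W <- sum(r[gs])
    ties <- table(xs)
    tie_term <- sum(ties^3 - ties)
    varW <- m * nn * (N + 1) / 12
    if (N > 1) varW <- varW - m * nn * tie_term / (12 * N * (N - 1))
    w <- 1 / (N + 1)
    T_ <- T_ + w * W
    E_ <- E_ + w * m * (N + 1) / 2
    V_ <- V_ + w^2 * varW
  }
  if (!any_str) return(NA_real_)
  if (V_ <= 0) return(1) # complete ties in every stratum: no evidence
  z <- (T_ - E_) / sqrt(V_)
  2 * stats::pnorm(-abs(z))
}

#' Categorize units as competition-, rank-, both- or non-related
#'
#' Per unit, compares per-trial firing rates between win and loss trials
#' (competition contrast) and between dominant- and subordinate-opponent
#' trials (rank contrast). Because trial outcome and opponent rank are
#' behaviorally correlated (a mouse wins more often against subordinate
#' opponents), each contrast is by default stratified on the other factor
#' with a van Elteren combined rank-sum test, so a purely
#' competition-modulated unit is not falsely flagged as rank-related through
#' the outcome-by-opponent association. Set `stratified = FALSE` for the
#' marginal two-sample test. The category follows the two p < alpha flags;
#' the absolute mean rate difference of each contrast is reported as its
#' effect. Units with fewer than `min_trials` trials in any condition are
#' marked unclassifiable (category NA) and are excluded from population
#' denominators.
#'
#' @param rates output of [trial_firing_rates()].
#' @param trials trial table carrying `trial_id`, `subject_id`,
#'   `pellet_winner_id`, `opponent_relative_rank`.
#' @param alpha per-unit test level (no correction across units).
#' @param min_trials minimum trials per condition.
#' @param test "wilcoxon" (rank-based; stratified by default) or "welch".
#' @param stratified stratify each contrast on the other factor.
#' @return data.frame(unit_id, category, p_competition, p_rank,
#'   effect_competition, effect_rank).
#' @export
classify_task_related <- function(rates, trials, alpha = 0.05, min_trials = 5L,
                                  test = c("wilcoxon", "welch"),
                                  stratified = TRUE) {
  test <- match.arg(test)
  if (anyDuplicated(trials$trial_id)) {
    stop("trials must hold one perspective row per trial (filter to the recorded subject first)",
         call. = FALSE)
  }
  meta <- trials[, c("trial_id", "subject_id", "pellet_winner_id",
                     "opponent_relative_rank")]
  df <- merge(rates, meta, by = "trial_id")
  df$won <- df$pellet_winner_id == df$subject_id
  df$dom <- df$opponent_relative_rank == "dominant"
  two_sample_p <- function(x, flag, strata) {
    if (test == "wilcoxon") {
      if (stratified) {
        van_elteren_test(x, flag, strata)
      } else {
        suppressWarnings(stats::wilcox.test(x[flag], x[!flag],
                                            exact = FALSE)$p.value)
      }
    } else {
      stats::t.test(x[flag], x[!flag])$p.value
    }
  }
  out <- lapply(split(df, df$unit_id), function(du) {
    contrast <- function(flag, strata) {
      a <- du$rate_hz[flag]; b <- du$rate_hz[!flag]
      if (length(a) < min_trials || length(b) < min_trials) {
        return(c(NA_real_, NA_real_))
      }
      c(two_sample_p(du$rate_hz, flag, strata), abs(mean(a) - mean(b)))
    }
    cc <- contrast(du$won, du$dom)
    rr <- contrast(du$dom, du$won)
    cat_lab <- if (anyNA(c(cc[1], rr[1]))) NA_character_ else {
      sc <- cc[1] < alpha; sr <- rr[1] < alpha
      if (sc && sr) "both" else if (sc) "competition" else if (sr) "rank" else "non"
    }
    data.frame(unit_id = du$unit_id[1], category = cat_lab,
               p_competition = cc[1], p_rank = rr[1],
               effect_competition = cc[2], effect_rank = rr[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

# half-away-from-zero rounding to `digits` decimals
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Cross-tabulate cell type by task category
#'
#' Counts units in each (cell type, task category) cell and reports category
#' percentages at three scopes (all classified units, excitatory,
#' inhibitory), each rounded half-away-from-zero to one decimal, plus the
#' task-related total (competition + rank + both) per scope. Unclassifiable
#' units (category NA) are excluded from numerators and denominators.
#'
#' @param cell_types output of [classify_cell_types()].
#' @param categories output of [classify_task_related()] (or a truth table
#'   with columns unit_id, category/task_category).
#' @return object of class `population_summary`: list(counts, totals,
#'   percentages).
#' @export
summarize_population <- function(cell_types, categories) {
  if ("task_category" %in% names(categories) && !"category" %in% names(categories)) {
    categories$category <- categories$task_category
  }
  only <- union(setdiff(cell_types$unit_id, categories$unit_id),
                setdiff(categories$unit_id, cell_types$unit_id))
  if (length(only)) {
    stop(sprintf("unit %s present in only one table", only[1]), call. = FALSE)
  }
  df <- merge(cell_types[, c("unit_id", "cell_type")],
              categories[, c("unit_id", "category")], by = "unit_id")
  df <- df[!is.na(df$category), ]
  cats <- c("competition", "rank", "both", "non")
  types <- c("excitatory", "inhibitory")
  counts <- matrix(0L, 2, 4, dimnames = list(types, cats))
  for (ty in types) for (cc in cats) {
    counts[ty, cc] <- sum(df$cell_type == ty & df$category == cc)
  }
  totals <- c(all = nrow(df), excitatory = sum(counts["excitatory", ]),
              inhibitory = sum(counts["inhibitory", ]))
  pct_for <- function(cnt, total) {
    if (total == 0) return(stats::setNames(rep(NA_real_, 5),
                                           c(cats, "task_related")))
    p <- round_half_away(100 * cnt / total, 1)
    task <- round_half_away(100 * sum(cnt[c("competition", "rank", "both")]) / total, 1)
    c(p, task_related = task)
  }
  percentages <- list(
    all = pct_for(colSums(counts), totals[["all"]]),
    excitatory = pct_for(counts["excitatory", ], totals[["excitatory"]]),
    inhibitory = pct_for(counts["inhibitory", ], totals[["inhibitory"]])
  )
  structure(list(counts = counts, totals = totals, percentages = percentages),
            class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat("Population summary (", x$totals[["all"]], " classified units)\n", sep = "")
  print(x$counts)
  for (scope in names(x$percentages)) {
    p <- x$percentages[[scope]]
    cat(sprintf("%-10s n=%3d  comp %.1f%%  rank %.1f%%  both %.1f%%  non %.1f%%  task-related %.1f%%\n",
                scope, x$totals[[scope]], p[["competition"]], p[["rank"]],
                p[["both"]], p[["non"]], p[["task_related"]]))
  }
  invisible(x)
}

#' Day-wise delta z-score series per category
#'
#' For each task category, the daily population mean rate is z-scored against
#' the baseline day's per-trial distribution, z_d = (mean_d - mean_0)/SD_0,
#' and expressed as change from day 0 so every series starts at 0.
#'
#' @param rates data.frame(day, category, trial, rate_hz) of per-trial
#'   population rates (e.g. from [generate_longitudinal()]).
#' @param baseline_day day index of the pre-intervention baseline.
#' @return data.frame(category, day, delta_z).
#' @export
delta_zscore_series <- function(rates, baseline_day = 0L) {
  stopifnot(all(c("day", "category", "rate_hz") %in% names(rates)))
  if (!baseline_day %in% rates$day) stop("baseline day absent", call. = FALSE)
  out <- lapply(split(rates, rates$category), function(rc) {
    base <- rc$rate_hz[rc$day == baseline_day]
    m0 <- mean(base); s0 <- stats::sd(base)
    if (!is.finite(s0) || s0 == 0) stop("zero baseline SD", call. = FALSE)
    daily <- stats::aggregate(rate_hz ~ day, data = rc, FUN = mean)
    z <- (daily$rate_hz - m0) / s0
    dz <- z - z[daily$day == baseline_day]
    data.frame(category = rc$category[1], day = daily$day, delta_z = dz,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Accept or reject candidate mEPSC events
#'
#' Applies the stated detection criteria: amplitude greater than 5 pA,
#' minimum rise rate 0.3 pA/ms, and decay time constant between 1 and 12 ms.
#'
#' @param events data.frame(amplitude_pa, rise_rate_pa_per_ms, decay_tau_ms).
#' @return the accepted subset of `events`.
#' @export
filter_mepsc_events <- function(events) {
  need <- c("amplitude_pa", "rise_rate_pa_per_ms", "decay_tau_ms")
  miss <- setdiff(need, names(events))
  if (length(miss)) stop(sprintf("missing field %s", miss[1]), call. = FALSE)
  if (anyNA(events[, need])) stop("missing measurement values", call. = FALSE)
  keep <- events$amplitude_pa > 5 &
    events$rise_rate_pa_per_ms >= 0.3 &
    events$decay_tau_ms >= 1 & events$decay_tau_ms <= 12
  events[keep, , drop = FALSE]
}
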