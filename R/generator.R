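#' Generate a synthetic unit population with ground truth
#'
#' Draws a population of sorted units with a cell type (broad-spiking
#' excitatory vs narrow-spiking inhibitory), a task category
#' (competition/rank/both/non), waveform features from per-type Gaussians in
#' the 3D (trough-to-peak latency, half-width, AUC) feature space, and a
#' burstiness setting (excitatory units carry the configured doublet
#' probability). In quota mode (default) type and category counts are exact
#' largest-remainder quotas, so a configuration mirroring a recorded
#' population reproduces its cross-tabulation exactly.
#'
#' @param config a [gen_config()].
#' @return list with `units` (unit_id, group_id, true feature values,
#'   doublet_prob) and `truth` (unit_id, cell_type, task_category).
#' @export
generate_unit_population <- function(config) {
  validate_gen_config(config)
  n <- config$n_units
  with_substream(config$seed, "population", expr = {
    if (config$quota_mode) {
      n_exc <- quota_counts(n, c(config$prop_excitatory, 1 - config$prop_excitatory))[1]
      types <- rep(c("excitatory", "inhibitory"), c(n_exc, n - n_exc))
    } else {
      types <- ifelse(stats::runif(n) < config$prop_excitatory,
                      "excitatory", "inhibitory")
    }
    cats <- character(n)
    for (ty in c("excitatory", "inhibitory")) {
      idx <- which(types == ty)
      if (!length(idx)) next
      p <- config$category_props[ty, ]
      if (config$quota_mode) {
        k <- quota_counts(length(idx), p)
        cats[idx] <- rep(colnames(config$category_props), k)
      } else {
        cats[idx] <- sample(colnames(config$category_props), length(idx),
                            replace = TRUE, prob = p)
      }
    }
    wf <- config$waveform_params
    rownames(wf) <- wf$cell_type
    draw <- function(mu, sd, lo) pmax(stats::rnorm(n, mu, sd), lo)
    tp <- draw(wf[types, "tp_mean_ms"], wf[types, "tp_sd_ms"], 0.05)
    hw <- draw(wf[types, "hw_mean_ms"], wf[types, "hw_sd_ms"], 0.03)
    auc <- draw(wf[types, "auc_mean"], wf[types, "auc_sd"], 5)
    units <- data.frame(
      unit_id = sprintf("u%03d", seq_len(n)),
      group_id = sprintf("g%d", ((seq_len(n) - 1L) %% config$n_groups) + 1L),
      tp_latency_ms = tp, half_width_ms = hw, auc = auc,
      doublet_prob = ifelse(types == "excitatory", config$doublet_prob, 0),
      stringsAsFactors = FALSE
    )
    truth <- data.frame(
      unit_id = units$unit_id, cell_type = types, task_category = cats,
      stringsAsFactors = FALSE
    )
    list(units = units, truth = truth)
  })
}

#' Synthesize a biphasic average waveform from target features
#'
#' Builds a negative-trough-then-positive-peak template parameterized directly
#' by the three target shape features: the trough is a Gaussian whose FWHM is
#' the requested half-width, the after-peak is a broader Gaussian of 35% the
#' trough amplitude placed `tp_latency_ms` later, and the trough amplitude is
#' scaled so the rectified area matches the requested AUC.
#'
#' @param tp_latency_ms,half_width_ms,auc target trough-to-peak latency (ms),
#'   trough half-width (ms) and rectified area (uV*ms).
#' @param sampling_rate_hz sample rate; @param dur_ms template duration.
#' @return data.frame(time_ms, amplitude_uv).
#' @export
synthesize_waveform <- function(tp_latency_ms, half_width_ms, auc,
                                sampling_rate_hz = 40000, dur_ms = 3) {
  t <- seq(0, dur_ms, by = 1000 / sampling_rate_hz)
  sigma_t <- half_width_ms / (2 * sqrt(2 * log(2)))
  t_trough <- 1.0
  trough <- exp(-(t - t_trough)^2 / (2 * sigma_t^2))
  peak <- 0.35 * exp(-(t - t_trough - tp_latency_ms)^2 / (2 * (1.8 * sigma_t)^2))
  w <- -trough + peak
  amp <- auc / trapezoid(t, abs(w))
  data.frame(time_ms = t, amplitude_uv = amp * w)
}

trapezoid <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

#' Waveform samples for every unit in a population
#'
#' @param pop output of [generate_unit_population()].
#' @param config the same [gen_config()].
#' @return long data.frame(unit_id, sample_idx, time_ms, amplitude_uv).
#' @export
generate_waveform_table <- function(pop, config) {
  out <- lapply(seq_len(nrow(pop$units)), function(i) {
    u <- pop$units[i, ]
    w <- synthesize_waveform(u$tp_latency_ms, u$half_width_ms, u$auc,
                             config$sampling_rate_hz)
    data.frame(unit_id = u$unit_id, sample_idx = seq_len(nrow(w)) - 1L,
               time_ms = w$time_ms, amplitude_uv = w$amplitude_uv,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Generate one round-robin food-competition session
#'
#' Every unordered pair of group mates runs `trials_per_pair` trials,
#' alternating the shared starting area so each side is used equally. The
#' pellet winner is drawn from a logistic (Bradley-Terry style) win
#' probability on the latent competitiveness difference; stage timestamps
#' (gate open < starting-area exit < reward-zone entry) are drawn with
#' latencies that shorten with competitiveness. Each trial is emitted twice,
#' once from each mouse's perspective (`subject_id` / `opponent_id`), which is
#' how chronic-recording sessions are analyzed.
#'
#' @param config a [gen_config()]; @param group_id group label;
#' @param day session day (recorded in the table).
#' @return trial table; see `schema_trials()` for columns.
#' @export
generate_competition_session <- function(config, group_id = "g1", day = 1L) {
  validate_gen_config(config)
  comp <- config$competitiveness
  if (is.null(comp) || any(!is.finite(comp))) {
    stop("missing competitiveness scores", call. = FALSE)
  }
  m <- config$mice_per_group
  mice <- sprintf("%s_m%d", group_id, seq_len(m))
  # latent dominance order: rank 1 = most competitive
  lat_rank <- rank(-comp, ties.method = "first")
  pairs <- utils::combn(m, 2)
  with_substream(config$seed, "session", group_id, day, expr = {
    rows <- list()
    t0 <- 0
    trial_counter <- 0L
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1, p]; j <- pairs[2, p]
      for (k in seq_len(config$trials_per_pair)) {
        trial_counter <- trial_counter + 1L
        start_area <- if (k %% 2 == 1) "A" else "B"
        p_win_i <- stats::plogis((comp[i] - comp[j]) / config$win_tau)
        winner <- if (stats::runif(1) < p_win_i) i else j
        lat_exit <- 0.3 + stats::rexp(2, rate = exp(0.4 * comp[c(i, j)]))
        lat_rz <- lat_exit + 0.5 + stats::rexp(2, rate = 1.5 * exp(0.4 * comp[c(i, j)]))
        # the pellet winner tends to reach the reward zone first, but never
        # before leaving its own starting area
        wi <- if (winner == i) 1 else 2
        if (lat_rz[wi] > min(lat_rz)) {
          lat_rz[wi] <- max(lat_exit[wi] + 0.2, min(lat_rz) * 0.95)
        }
        for (s in 1:2) {
          subj <- c(i, j)[s]; opp <- c(i, j)[3 - s]
          rows[[length(rows) + 1L]] <- data.frame(
            group_id = group_id, day = as.integer(day), session_id = 1L,
            pair_id = sprintf("%s-%s", mice[i], mice[j]),
            trial_id = sprintf("%s_d%d_t%03d", group_id, day, trial_counter),
            subject_id = mice[subj], opponent_id = mice[opp],
            start_area = start_area,
            t_gate_open_s = t0,
            t_exit_sa_s = t0 + lat_exit[s],
            t_reach_rz_s = t0 + lat_rz[s],
            pellet_winner_id = mice[winner],
            opponent_relative_rank = if (lat_rank[opp] < lat_rank[subj])
              "dominant" else "subordinate",
            stringsAsFactors = FALSE
          )
        }
        t0 <- t0 + 30
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate all recorded session days for a group
#'
#' Convenience wrapper running [generate_competition_session()] for days
#' `1..n_session_days` and stacking the tables; successive days continue the
#' session clock so trial timestamps stay strictly increasing.
#'
#' @param config a [gen_config()]; @param group_id group label.
#' @return stacked trial table.
#' @export
generate_competition_sessions <- function(config, group_id = "g1") {
  out <- lapply(seq_len(config$n_session_days), function(d) {
    tr <- generate_competition_session(config, group_id, day = d)
    off <- (d - 1) * (max(tr$t_gate_open_s) + 60)
    for (col in c("t_gate_open_s", "t_exit_sa_s", "t_reach_rz_s")) {
      tr[[col]] <- tr[[col]] + off
    }
    tr$trial_id <- sprintf("%s", tr$trial_id)
    tr
  })
  do.call(rbind, out)
}

#' Generate spike trains for a unit population over a trial table
#'
#' Each unit fires as an inhomogeneous Poisson process at `base_rate_hz` over
#' its subject's trials (from 2 s before gate open to 4 s after reward-zone
#' entry), with the rate multiplied by `modulation_gain` inside the analysis
#' window around reward-zone entry on win trials (competition-modulated
#' units), dominant-opponent trials (rank-modulated units), or both
#' (both-modulated). Bursty units emit a doublet companion 3-5 ms after a
#' spike with their configured probability.
#'
#' @param config a [gen_config()].
#' @param trials trial table from [generate_competition_session()].
#' @param pop population list from [generate_unit_population()].
#' @return data.frame(unit_id, spike_time_s), sorted within unit.
#' @export
generate_spike_trains <- function(config, trials, pop) {
  if (is.null(trials) || nrow(trials) == 0L) {
    stop("empty trial table", call. = FALSE)
  }
  stopifnot(all(c("pellet_winner_id", "opponent_relative_rank") %in% names(trials)))
  w <- config$analysis_window
  out <- vector("list", nrow(pop$units))
  for (i in seq_len(nrow(pop$units))) {
    u <- pop$units[i, ]
    category <- pop$truth$task_category[i]
    subj <- sprintf("%s_m%d", u$group_id, config$recorded_mouse)
    tr <- trials[trials$group_id == u$group_id & trials$subject_id == subj, ]
    if (nrow(tr) == 0L) next
    out[[i]] <- with_substream(config$seed, "spikes", u$unit_id, expr = {
      spk <- numeric(0)
      for (r in seq_len(nrow(tr))) {
        t_rz <- tr$t_reach_rz_s[r]
        seg_lo <- tr$t_gate_open_s[r] - 2
        seg_hi <- t_rz + 4
        won <- tr$pellet_winner_id[r] == tr$subject_id[r]
        dom <- tr$opponent_relative_rank[r] == "dominant"
        # both-modulated units carry one multiplicative gain per factor
        gain <- 1
        if (category %in% c("competition", "both") && won) {
          gain <- gain * config$modulation_gain
        }
        if (category %in% c("rank", "both") && dom) {
          gain <- gain * config$modulation_gain
        }
        mod_lo <- max(seg_lo, t_rz + w[1]); mod_hi <- min(seg_hi, t_rz + w[2])
        segs <- rbind(c(seg_lo, mod_lo, 1), c(mod_lo, mod_hi, gain),
                      c(mod_hi, seg_hi, 1))
        for (s in seq_len(nrow(segs))) {
          dur <- segs[s, 2] - segs[s, 1]
          if (dur <= 0) next
          k <- stats::rpois(1, config$base_rate_hz * segs[s, 3] * dur)
          if (k > 0) spk <- c(spk, stats::runif(k, segs[s, 1], segs[s, 2]))
        }
      }
      spk <- sort(spk)
      if (u$doublet_prob > 0 && length(spk)) {
        sel <- stats::runif(length(spk)) < u$doublet_prob
        if (any(sel)) {
          comp <- spk[sel] + stats::runif(sum(sel), 0.003, 0.005)
          spk <- sort(c(spk, comp))
        }
      }
      if (length(spk)) data.frame(unit_id = u$unit_id, spike_time_s = spk,
                                  stringsAsFactors = FALSE) else NULL
    })
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(unit_id = character(0),
                                      spike_time_s = numeric(0))
  rownames(res) <- NULL
  res
}

#' Generate daily tube-test bouts and warm-spot occupancy
#'
#' Runs a full round robin every day for `n_days`. Bout winners are drawn
#' from latent dominance with early-day upset noise that decays linearly to
#' zero by `tube_time_stable_day`; bout durations are gamma-distributed with
#' a higher mean before the stable day and a lower mean after, emulating the
#' shortening of contested bouts once the hierarchy settles. Warm-spot
#' occupancy per mouse is proportional (in expectation) to a softmax of
#' latent dominance, so occupancy order matches dominance order when the
#' noise SD is zero.
#'
#' @param config a [gen_config()]; @param group_id group label.
#' @return list(tube = bout table, warmspot = occupancy table).
#' @export
generate_tube_and_warmspot <- function(config, group_id = "g1") {
  validate_gen_config(config)
  if (config$n_days < 1L) stop("n_days must be >= 1", call. = FALSE)
  m <- config$mice_per_group
  mice <- sprintf("%s_m%d", group_id, seq_len(m))
  comp <- config$competitiveness
  pairs <- utils::combn(m, 2)
  with_substream(config$seed, "tube", group_id, expr = {
    tube <- list(); ws <- list()
    for (d in seq_len(config$n_days)) {
      stable <- d >= config$tube_time_stable_day
      frac <- if (config$tube_time_stable_day <= 1L) 0 else
        max(0, 1 - (d - 1) / (config$tube_time_stable_day - 1))
      p_upset <- config$tube_noise * frac
      for (p in seq_len(ncol(pairs))) {
        i <- pairs[1, p]; j <- pairs[2, p]
        stronger <- if (comp[i] >= comp[j]) i else j
        weaker <- i + j - stronger
        winner <- if (stats::runif(1) < p_upset) weaker else stronger
        mu <- if (stable) config$tube_dur_post_s else config$tube_dur_pre_s
        tube[[length(tube) + 1L]] <- data.frame(
          group_id = group_id, day = d, mouse_a = mice[i], mouse_b = mice[j],
          winner = mice[winner],
          duration_s = stats::rgamma(1, shape = 9, scale = mu / 9),
          stringsAsFactors = FALSE
        )
      }
      wgt <- exp(comp) * exp(stats::rnorm(m, 0, config$ws_noise_sd))
      ws[[length(ws) + 1L]] <- data.frame(
        group_id = group_id, day = d, mouse_id = mice,
        occupancy_s = 1000 * wgt / sum(wgt), stringsAsFactors = FALSE
      )
    }
    list(tube = do.call(rbind, tube), warmspot = do.call(rbind, ws))
  })
}

#' Generate the longitudinal intervention bundle
#'
#' Simulates a 21-day (by default) intervention window, day 0 = intervention
#' start. Competition-related modulation declines along a sigmoid with
#' midpoint `ramp_mid_days` after onset; rank-related modulation follows the
#' same trajectory delayed by `rank_lag_days`. The winning proportion is
#' coupled to the competition trajectory with zero lag; the tube-rank series
#' moves after the competition change (hysteresis). Per-day, per-trial
#' population firing rates are Poisson counts over `long_units` units in the
#' analysis window, from which [delta_zscore_series()] computes day-wise
#' z-scores.
#'
#' @param config a [gen_config()].
#' @return list with `rates` (day, category, trial, rate_hz), `winning`,
#'   `tube_time`, `tube_rank` (data.frames day/value with a `label`
#'   attribute), and `truth` (day, gain_competition, gain_rank, p_win).
#' @export
generate_longitudinal <- function(config) {
  validate_gen_config(config)
  days <- seq(0L, config$n_days - 1L)
  G <- config$modulation_gain
  ramp <- function(lag) {
    stats::plogis((days - (config$intervention_day + config$ramp_mid_days + lag)) /
                    config$ramp_tau_days)
  }
  s_comp <- ramp(0)
  s_rank <- ramp(config$rank_lag_days)
  gain_comp <- 1 + (G - 1) * (1 - s_comp)
  gain_rank <- 1 + (G - 1) * (1 - s_rank)
  p_win <- config$win_p1 + (config$win_p0 - config$win_p1) * (1 - s_comp)
  T_win <- diff(config$analysis_window)
  with_substream(config$seed, "longitudinal", expr = {
    rates <- list()
    for (ci in 1:2) {
      cat_name <- c("competition", "rank")[ci]
      gain <- if (ci == 1) gain_comp else gain_rank
      for (di in seq_along(days)) {
        mu <- config$long_units * config$base_rate_hz * gain[di] * T_win
        counts <- stats::rpois(config$long_trials, mu)
        rates[[length(rates) + 1L]] <- data.frame(
          day = days[di], category = cat_name,
          trial = seq_len(config$long_trials),
          rate_hz = counts / (config$long_units * T_win),
          stringsAsFactors = FALSE
        )
      }
    }
    winning <- data.frame(
      day = days,
      value = stats::rbinom(length(days), config$long_trials, p_win) /
        config$long_trials
    )
    tube_time <- data.frame(
      day = days,
      value = config$tube_dur_post_s +
        (config$tube_dur_pre_s - config$tube_dur_post_s) * s_comp +
        stats::rnorm(length(days), 0, 0.5)
    )
    tube_rank <- data.frame(
      day = days,
      value = config$recorded_mouse +
        (config$mice_per_group - config$recorded_mouse) * s_rank
    )
    attr(winning, "label") <- "winning_proportion"
    attr(tube_time, "label") <- "tube_time_s"
    attr(tube_rank, "label") <- "tube_rank"
    list(rates = do.call(rbind, rates), winning = winning,
         tube_time = tube_time, tube_rank = tube_rank,
         truth = data.frame(day = days, gain_competition = gain_comp,
                            gain_rank = gain_rank, p_win = p_win))
  })
}
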