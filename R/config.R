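#' Build a generator configuration
#'
#' Collects and validates every parameter of the synthetic-data generator.
#' Defaults emulate the recorded study population: groups of 4 mice tested
#' pairwise in a round-robin food competition (10 trials per pair, 5 starts
#' from each starting area), a unit population that is ~76% broad-spiking
#' (putative excitatory), task-category composition matching the recorded
#' cross-tabulation, and a 21-day intervention window in which rank-related
#' modulation changes 10 days after competition-related modulation.
#'
#' @param seed integer seed; the single entry point for all randomness. Per
#'   (group, unit, stage) sub-streams are derived by stable hashing so adding
#'   units or groups does not perturb existing ones.
#' @param n_groups number of 4-mouse groups.
#' @param mice_per_group mice per group (>= 2).
#' @param trials_per_pair food-competition trials per pair per session day;
#'   starting areas alternate so each pair starts `trials_per_pair/2` times
#'   from each side.
#' @param n_session_days number of daily food-competition sessions recorded
#'   for the implanted mouse; per-unit contrasts pool trials across days.
#' @param n_units total sorted units across groups.
#' @param prop_excitatory fraction of broad-spiking (excitatory) units.
#' @param category_props 2 x 4 matrix of task-category fractions
#'   (rows `excitatory`, `inhibitory`; columns `competition`, `rank`, `both`,
#'   `non`), each row summing to 1.
#' @param quota_mode if TRUE (default) type and category counts are exact
#'   quotas (largest-remainder rounding); if FALSE they are sampled.
#' @param base_rate_hz baseline firing rate of every unit (Hz).
#' @param modulation_gain multiplicative rate gain (>= 1) applied inside the
#'   analysis window on win trials (competition-modulated units) or
#'   dominant-opponent trials (rank-modulated units).
#' @param waveform_params data frame of per-type feature means/SDs
#'   (columns `cell_type`, `tp_mean_ms`, `tp_sd_ms`, `hw_mean_ms`, `hw_sd_ms`,
#'   `auc_mean`, `auc_sd`); SDs must be strictly positive.
#' @param doublet_prob probability that a spike of a bursty (excitatory) unit
#'   is followed by a doublet companion 3-5 ms later.
#' @param analysis_window half-open window `[a, b)` in seconds around reward
#'   zone entry in which modulation applies.
#' @param sampling_rate_hz waveform sampling rate.
#' @param n_days length of the longitudinal intervention window (days).
#' @param intervention_day day index (0-based) at which the intervention
#'   starts; series are indexed with day 0 = intervention start.
#' @param rank_lag_days delay (days) between the onset of competition-related
#'   and rank-related modulation change.
#' @param ramp_mid_days,ramp_tau_days midpoint (after onset) and time scale of
#'   the sigmoidal modulation decline in the longitudinal series.
#' @param long_units,long_trials units per category and trials per day used to
#'   simulate the longitudinal per-trial population rates.
#' @param win_p0 pre-intervention winning proportion of the recorded mouse.
#' @param win_p1 post-intervention asymptotic winning proportion (the
#'   intervention demotes the recorded mouse below its group mates).
#' @param competitiveness per-mouse latent competitiveness scores (length
#'   `mice_per_group`); defaults to an evenly spaced descending ladder whose
#'   gaps, together with `win_tau`, give adjacent mice moderately biased
#'   pellet odds -- competition among familiar cagemates is tight, and trial
#'   outcome must not be a near-deterministic function of opponent rank or
#'   the win/loss and opponent-rank contrasts would be confounded.
#' @param win_tau temperature of the logistic (Bradley-Terry style) win model
#'   `p = plogis((c_i - c_j)/win_tau)`.
#' @param recorded_mouse index of the implanted mouse in each group
#'   (mid-ranked by default).
#' @param tube_time_stable_day day by which tube-bout outcome noise has
#'   decayed to zero and bout durations reach their stable (lower) mean.
#' @param tube_noise initial probability that the weaker mouse wins a tube
#'   bout on day 1; decays linearly to 0 at `tube_time_stable_day`.
#' @param tube_dur_pre_s,tube_dur_post_s mean bout duration before/after the
#'   stable day (seconds).
#' @param ws_noise_sd SD of the lognormal noise on warm-spot occupancy
#'   weights; 0 gives occupancy order identical to latent dominance.
#'
#' @return a validated list of class `gen_config`.
#' @export
gen_config <- function(seed = 1L,
                       n_groups = 1L,
                       mice_per_group = 4L,
                       trials_per_pair = 10L,
                       n_session_days = 4L,
                       n_units = 40L,
                       prop_excitatory = 288 / 379,
                       category_props = default_category_props(),
                       quota_mode = TRUE,
                       base_rate_hz = 5,
                       modulation_gain = 2,
                       waveform_params = default_waveform_params(),
                       doublet_prob = 0.3,
                       analysis_window = c(-2, 2),
                       sampling_rate_hz = 40000,
                       n_days = 21L,
                       intervention_day = 0L,
                       rank_lag_days = 10L,
                       ramp_mid_days = 5,
                       ramp_tau_days = 1.25,
                       long_units = 30L,
                       long_trials = 30L,
                       win_p0 = 0.75,
                       win_p1 = 0.2,
                       competitiveness = NULL,
                       win_tau = 2,
                       recorded_mouse = 2L,
                       tube_time_stable_day = 5L,
                       tube_noise = 0.4,
                       tube_dur_pre_s = 25,
                       tube_dur_post_s = 8,
                       ws_noise_sd = 0.15) {
  if (is.null(competitiveness)) {
    competitiveness <- seq(0.6, -0.6, length.out = mice_per_group)
  }
  cfg <- list(
    seed = as.integer(seed), n_groups = as.integer(n_groups),
    mice_per_group = as.integer(mice_per_group),
    trials_per_pair = as.integer(trials_per_pair),
    n_session_days = as.integer(n_session_days),
    n_units = as.integer(n_units), prop_excitatory = prop_excitatory,
    category_props = category_props, quota_mode = isTRUE(quota_mode),
    base_rate_hz = base_rate_hz, modulation_gain = modulation_gain,
    waveform_params = waveform_params, doublet_prob = doublet_prob,
    analysis_window = analysis_window, sampling_rate_hz = sampling_rate_hz,
    n_days = as.integer(n_days), intervention_day = as.integer(intervention_day),
    rank_lag_days = as.integer(rank_lag_days),
    ramp_mid_days = ramp_mid_days, ramp_tau_days = ramp_tau_days,
    long_units = as.integer(long_units), long_trials = as.integer(long_trials),
    win_p0 = win_p0, win_p1 = win_p1, competitiveness = competitiveness, win_tau = win_tau,
    recorded_mouse = as.integer(recorded_mouse),
    tube_time_stable_day = as.integer(tube_time_stable_day),
    tube_noise = tube_noise,
    tube_dur_pre_s = tube_dur_pre_s, tube_dur_post_s = tube_dur_post_s,
    ws_noise_sd = ws_noise_sd
  )
  class(cfg) <- "gen_config"
  validate_gen_config(cfg)
  cfg
}

#' @rdname gen_config
#' @export
default_category_props <- function() {
  m <- rbind(
    excitatory = c(86, 22, 14, 166) / 288,
    inhibitory = c(12, 10, 6, 63) / 91
  )
  colnames(m) <- c("competition", "rank", "both", "non")
  m
}

#' @rdname gen_config
#' @export
default_waveform_params <- function() {
  data.frame(
    cell_type = c("excitatory", "inhibitory"),
    tp_mean_ms = c(0.65, 0.25), tp_sd_ms = c(0.08, 0.04),
    hw_mean_ms = c(0.26, 0.12), hw_sd_ms = c(0.035, 0.018),
    auc_mean = c(60, 28), auc_sd = c(9, 5),
    stringsAsFactors = FALSE
  )
}

validate_gen_config <- function(cfg) {
  stopifnot(is.list(cfg))
  fracs <- c(cfg$prop_excitatory, cfg$doublet_prob, cfg$tube_noise, cfg$win_p0, cfg$win_p1)
  if (any(fracs < 0 | fracs > 1)) {
    stop("all fractions must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$n_units < 1L) stop("n_units must be positive", call. = FALSE)
  if (cfg$n_session_days < 1L) stop("n_session_days must be >= 1", call. = FALSE)
  if (cfg$mice_per_group < 2L) stop("mice_per_group must be >= 2", call. = FALSE)
  cp <- cfg$category_props
  if (!is.matrix(cp) || nrow(cp) != 2L || ncol(cp) != 4L) {
    stop("category_props must be a 2 x 4 matrix", call. = FALSE)
  }
  if (any(cp < 0 | cp > 1)) stop("category_props must lie in [0, 1]", call. = FALSE)
  if (any(abs(rowSums(cp) - 1) > 1e-9)) {
    stop("each category_props row must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  wf <- cfg$waveform_params
  sds <- unlist(wf[, c("tp_sd_ms", "hw_sd_ms", "auc_sd")])
  if (any(!is.finite(sds)) || any(sds <= 0)) {
    stop("degenerate waveform_params: all feature SDs must be > 0", call. = FALSE)
  }
  if (cfg$base_rate_hz <= 0) stop("base_rate_hz must be > 0", call. = FALSE)
  if (cfg$modulation_gain < 1) stop("modulation_gain must be >= 1", call. = FALSE)
  if (length(cfg$competitiveness) != cfg$mice_per_group) {
    stop("competitiveness must have one score per mouse", call. = FALSE)
  }
  if (cfg$n_days < 1L) stop("n_days must be >= 1", call. = FALSE)
  if (cfg$intervention_day < 0L || cfg$intervention_day >= cfg$n_days) {
    stop("intervention_day must lie in [0, n_days)", call. = FALSE)
  }
  if (cfg$rank_lag_days >= cfg$n_days) {
    stop("rank_lag_days must be smaller than n_days", call. = FALSE)
  }
  w <- cfg$analysis_window
  if (length(w) != 2L || w[2] <= w[1]) {
    stop("analysis_window must be an increasing pair c(a, b)", call. = FALSE)
  }
  invisible(cfg)
}

# Deterministic sub-stream seed from the run seed plus arbitrary keys.
# Polynomial string hash mod a 31-bit prime keeps seeds valid R integers and
# independent of how many other sub-streams exist.
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 131 + v) %% 2147483629
  as.integer(h)
}

# Evaluate expr under a derived, restored-on-exit RNG state.
with_substream <- function(seed, ..., expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, ...))
  expr
}

# Largest-remainder apportionment: integer counts summing to n with
# proportions p. Ties in remainder go to the earlier column (deterministic).
quota_counts <- function(n, p) {
  raw <- n * p
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    extra <- order(raw - k, decreasing = TRUE)[seq_len(rem)]
    k[extra] <- k[extra] + 1
  }
  as.integer(k)
}
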