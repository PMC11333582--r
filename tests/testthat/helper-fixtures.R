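# Shared fixture builders and independent oracles.

# Round-robin bout table for 4 mice from a winner matrix: beats[i, j] = TRUE
# means mouse i beats mouse j.
make_bouts <- function(beats, day = 1L, group_id = "g1",
                       mice = paste0("m", seq_len(nrow(beats)))) {
  pr <- utils::combn(nrow(beats), 2)
  do.call(rbind, lapply(seq_len(ncol(pr)), function(k) {
    i <- pr[1, k]; j <- pr[2, k]
    data.frame(group_id = group_id, day = day, mouse_a = mice[i],
               mouse_b = mice[j],
               winner = if (beats[i, j]) mice[i] else mice[j],
               duration_s = 10, stringsAsFactors = FALSE)
  }))
}

# Minimal two-mouse trial table from a vector of pellet winners and optional
# per-trial (latency_a, latency_b) reach-RZ latencies.
make_pair_trials <- function(winners, mice = c("A", "B"),
                             lat_a = rep(2, length(winners)),
                             lat_b = rep(3, length(winners)),
                             group_id = "g1", day = 1L) {
  n <- length(winners)
  do.call(rbind, lapply(seq_len(n), function(k) {
    t0 <- (k - 1) * 30
    do.call(rbind, lapply(1:2, function(s) {
      data.frame(group_id = group_id, day = day, session_id = 1L,
                 pair_id = paste(mice, collapse = "-"),
                 trial_id = sprintf("t%03d", k),
                 subject_id = mice[s], opponent_id = mice[3 - s],
                 start_area = "A", t_gate_open_s = t0,
                 t_exit_sa_s = t0 + 1,
                 t_reach_rz_s = t0 + c(lat_a[k], lat_b[k])[s],
                 pellet_winner_id = winners[k],
                 opponent_relative_rank = "subordinate",
                 stringsAsFactors = FALSE)
    }))
  }))
}

# Per-unit rate table plus matching one-perspective trial metadata with
# independent win/dominance flags; used to probe the task classifier without
# the session generator.
make_rate_fixture <- function(n_trials, rate_fun, seed = 1L,
                              p_win = 0.5, p_dom = 0.5) {
  set.seed(seed)
  won <- stats::runif(n_trials) < p_win
  dom <- stats::runif(n_trials) < p_dom
  trials <- data.frame(
    trial_id = sprintf("t%04d", seq_len(n_trials)),
    subject_id = "S", opponent_id = "O",
    pellet_winner_id = ifelse(won, "S", "O"),
    opponent_relative_rank = ifelse(dom, "dominant", "subordinate"),
    stringsAsFactors = FALSE
  )
  rates <- data.frame(unit_id = "u1", trial_id = trials$trial_id,
                      rate_hz = rate_fun(won, dom), stringsAsFactors = FALSE)
  list(rates = rates, trials = trials, won = won, dom = dom)
}

# Exhaustive minimum within-cluster-SSE 2-partition over standardized
# features (independent oracle for k-means with k = 2).
brute_force_two_partition <- function(X) {
  Xs <- scale(X)
  Xs[, apply(X, 2, stats::sd) == 0] <- 0
  n <- nrow(Xs)
  best_sse <- Inf; best <- NULL
  for (mask in 1:(2^(n - 1) - 1)) { # unit 1 fixed in cluster 0, halves the space
    grp <- c(0L, as.integer(intToBits(mask))[seq_len(n - 1)])
    sse <- 0
    for (g in 0:1) {
      sub <- Xs[grp == g, , drop = FALSE]
      if (nrow(sub) == 0) { sse <- Inf; break }
      ctr <- colMeans(sub)
      sse <- sse + sum(sweep(sub, 2, ctr)^2)
    }
    if (sse < best_sse) { best_sse <- sse; best <- grp }
  }
  list(assignment = best, sse = best_sse)
}

# Closed-form Spearman rho for rank vectors without ties.
spearman_closed_form <- function(r1, r2) {
  n <- length(r1)
  1 - 6 * sum((r1 - r2)^2) / (n * (n^2 - 1))
}

# Independent per-lag Pearson correlation used to cross-check cross_correlate.
naive_lag_cor <- function(x, y, l) {
  n <- length(x)
  idx <- seq_len(n)
  keep <- idx + l >= 1 & idx + l <= n
  stats::cor(x[idx[keep]], y[idx[keep] + l])
}
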