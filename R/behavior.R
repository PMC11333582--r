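#' Daily tube-test ranks from round-robin bouts
#'
#' Counts each mouse's wins over the day's round robin and ranks by
#' descending win count (rank 1 = dominant). A day is `linear` when the win
#' counts are all distinct, i.e. they form the transitive ladder
#' N-1, N-2, ..., 0. Tied win counts are broken by the head-to-head result
#' when exactly two mice are tied and they met that day, otherwise by lower
#' mouse id; the tie rule only has to be deterministic because non-linear
#' days are excluded from downstream analysis.
#'
#' @param bouts tube bout table (group_id, day, mouse_a, mouse_b, winner,
#'   duration_s); each day must contain a complete round robin.
#' @return data.frame(group_id, day, mouse_id, wins, rank, linear).
#' @export
tube_daily_ranks <- function(bouts) {
  stopifnot(all(c("group_id", "day", "mouse_a", "mouse_b", "winner") %in% names(bouts)))
  bad <- bouts$winner != bouts$mouse_a & bouts$winner != bouts$mouse_b
  if (any(bad)) stop("winner must be one of the two bout mice", call. = FALSE)
  out <- list()
  for (g in unique(bouts$group_id)) {
    bg <- bouts[bouts$group_id == g, ]
    mice <- sort(unique(c(bg$mouse_a, bg$mouse_b)))
    need <- utils::combn(mice, 2)
    for (d in sort(unique(bg$day))) {
      bd <- bg[bg$day == d, ]
      seen <- paste(pmin(bd$mouse_a, bd$mouse_b), pmax(bd$mouse_a, bd$mouse_b))
      want <- paste(need[1, ], need[2, ])
      missing <- setdiff(want, seen)
      if (length(missing)) {
        stop(sprintf("incomplete round robin for group %s day %s: missing pair %s",
                     g, d, missing[1]), call. = FALSE)
      }
      wins <- vapply(mice, function(mm) sum(bd$winner == mm), integer(1))
      ord <- order_with_h2h(mice, wins, bd)
      rk <- integer(length(mice)); rk[ord] <- seq_along(mice)
      out[[length(out) + 1L]] <- data.frame(
        group_id = g, day = d, mouse_id = mice, wins = wins, rank = rk,
        linear = length(unique(wins)) == length(mice),
        stringsAsFactors = FALSE, row.names = NULL
      )
    }
  }
  do.call(rbind, out)
}

# order mice by descending wins; two-way ties by head-to-head, else mouse id
order_with_h2h <- function(mice, wins, bd) {
  ord <- order(-wins, mice)
  for (w in unique(wins)) {
    tied <- which(wins == w)
    if (length(tied) == 2L) {
      a <- mice[tied[1]]; b <- mice[tied[2]]
      met <- bd[(bd$mouse_a == a & bd$mouse_b == b) |
                  (bd$mouse_a == b & bd$mouse_b == a), ]
      if (nrow(met) == 1L && met$winner == b) {
        ia <- which(mice[ord] == a); ib <- which(mice[ord] == b)
        ord[c(min(ia, ib), max(ia, ib))] <- c(tied[2], tied[1])
      }
    }
  }
  ord
}

#' Earliest day of a stable linear hierarchy
#'
#' Returns the earliest day `d` such that the ranking is linear and identical
#' over `window` consecutive days starting at `d` ("stable linear rank for
#' over `window` days"), or `NA` if no such day exists.
#'
#' @param rank_days output of [tube_daily_ranks()] for one group.
#' @param window number of consecutive identical linear days required.
#' @return integer day or NA.
#' @export
detect_stable_hierarchy <- function(rank_days, window = 3L) {
  if (is.null(rank_days) || nrow(rank_days) == 0L) {
    stop("empty rank table", call. = FALSE)
  }
  stopifnot(length(unique(rank_days$group_id)) == 1L)
  days <- sort(unique(rank_days$day))
  sig <- function(d) {
    rd <- rank_days[rank_days$day == d, ]
    if (!all(rd$linear)) return(NA_character_)
    paste(rd$mouse_id[order(rd$rank)], collapse = ">")
  }
  sigs <- vapply(days, sig, character(1))
  for (i in seq_along(days)) {
    span <- days[i] + seq_len(window) - 1L
    if (!all(span %in% days)) next
    ss <- sigs[match(span, days)]
    if (!anyNA(ss) && length(unique(ss)) == 1L) return(days[i])
  }
  NA_integer_
}

#' Inflection day of mean tube-bout duration
#'
#' Operationalizes the "time-in-tube becomes stable" inflection as the
#' two-segment piecewise-constant least-squares change point: the day `k`
#' minimizing the total squared error of fitting one mean to days before `k`
#' and one to days from `k` on. The after-segment mean must be strictly lower
#' than the before-segment mean (a settling hierarchy shortens bouts),
#' otherwise no inflection is reported.
#'
#' @param series data.frame(day, value) with consecutive days, length >= 4.
#' @return the day label of the first after-segment day, or NA.
#' @export
tube_time_inflection <- function(series) {
  stopifnot(all(c("day", "value") %in% names(series)))
  series <- series[order(series$day), ]
  if (nrow(series) < 4L) stop("need at least 4 days", call. = FALSE)
  if (any(diff(series$day) != 1)) {
    stop("series has missing days", call. = FALSE)
  }
  v <- series$value
  n <- length(v)
  sse <- function(x) sum((x - mean(x))^2)
  total <- vapply(2:n, function(k) sse(v[1:(k - 1)]) + sse(v[k:n]), numeric(1))
  k <- (2:n)[which.min(total)]
  if (mean(v[k:n]) >= mean(v[1:(k - 1)])) return(NA_integer_)
  series$day[k]
}

#' Per-pair winning proportions at a race stage
#'
#' For each pair, the proportion of trials in which each mouse was first to
#' exit the starting area or reach the reward zone, or the proportion of
#' pellets it consumed. Trials with identical stage timestamps award 0.5 to
#' each mouse, so per-pair proportions always sum to 1.
#'
#' @param trials trial table with two perspective rows per trial.
#' @param stage one of "exit_sa", "reach_rz", "pellet".
#' @return data.frame(group_id, pair_id, mouse_id, wins, n_trials, proportion).
#' @export
winning_proportions <- function(trials, stage = c("pellet", "exit_sa", "reach_rz")) {
  stage <- match.arg(stage)
  tcol <- switch(stage, exit_sa = "t_exit_sa_s", reach_rz = "t_reach_rz_s",
                 pellet = NULL)
  if (!is.null(tcol) && any(is.na(trials[[tcol]]))) {
    stop(sprintf("missing %s timestamps", stage), call. = FALSE)
  }
  out <- list()
  key <- paste(trials$group_id, trials$pair_id)
  for (k in unique(key)) {
    tp <- trials[key == k, ]
    mice <- sort(unique(tp$subject_id))
    stopifnot(length(mice) == 2L)
    score <- stats::setNames(c(0, 0), mice)
    tids <- unique(tp$trial_id)
    for (tid in tids) {
      tt <- tp[tp$trial_id == tid, ]
      stopifnot(nrow(tt) == 2L)
      if (stage == "pellet") {
        wname <- tt$pellet_winner_id[1]
        score[wname] <- score[wname] + 1
      } else {
        tv <- stats::setNames(tt[[tcol]], tt$subject_id)[mice]
        if (tv[1] == tv[2]) score <- score + 0.5
        else score[which.min(tv)] <- score[which.min(tv)] + 1
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      group_id = tp$group_id[1], pair_id = tp$pair_id[1], mouse_id = mice,
      wins = as.numeric(score), n_trials = length(tids),
      proportion = as.numeric(score) / length(tids),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  do.call(rbind, out)
}

#' Assign the within-group competitive order (C1..CN)
#'
#' Mice are ordered by descending overall pellet-consumption proportion; mice
#' sharing the same proportion are ordered by ascending mean latency to reach
#' the reward zone (gate open to reward-zone entry). `tie_broken` flags mice
#' whose position was decided by the latency rule.
#'
#' @param trials trial table (two perspective rows per trial).
#' @return data.frame(group_id, mouse_id, order_index, order_label,
#'   pellet_proportion, mean_latency_s, tie_broken).
#' @export
assign_competitive_order <- function(trials) {
  out <- list()
  for (g in unique(trials$group_id)) {
    tg <- trials[trials$group_id == g, ]
    mice <- sort(unique(c(tg$subject_id, tg$opponent_id)))
    prop <- numeric(length(mice)); lat <- numeric(length(mice))
    for (i in seq_along(mice)) {
      tm <- tg[tg$subject_id == mice[i], ]
      if (nrow(tm) == 0L) {
        stop(sprintf("mouse %s has zero trials", mice[i]), call. = FALSE)
      }
      prop[i] <- mean(tm$pellet_winner_id == mice[i])
      lat[i] <- mean(tm$t_reach_rz_s - tm$t_gate_open_s)
    }
    ord <- order(-prop, lat, mice)
    tie <- vapply(seq_along(mice),
                  function(i) sum(abs(prop - prop[i]) < 1e-12) > 1L, logical(1))
    out[[length(out) + 1L]] <- data.frame(
      group_id = g, mouse_id = mice[ord], order_index = seq_along(mice),
      order_label = sprintf("C%d", seq_along(mice)),
      pellet_proportion = prop[ord], mean_latency_s = lat[ord],
      tie_broken = tie[ord], stringsAsFactors = FALSE, row.names = NULL
    )
  }
  do.call(rbind, out)
}

#' Per-mouse reward-zone latency and training criterion
#'
#' Mean latency from gate open to reward-zone entry per mouse (and per day),
#' plus the training criterion: a daily mean latency below `criterion_s` on
#' two consecutive days.
#'
#' @param trials trial table; if a `context` column is present, rows are
#'   filtered to the requested mode ("alone" training runs vs "competing"
#'   test trials), otherwise all rows are used.
#' @param mode "alone" or "competing".
#' @param criterion_s latency criterion in seconds (default 5).
#' @return list(daily = per mouse/day means, summary = per-mouse mean,
#'   criterion_met flag and first qualifying day).
#' @export
latency_summary <- function(trials, mode = c("competing", "alone"),
                            criterion_s = 5) {
  mode <- match.arg(mode)
  if ("context" %in% names(trials)) trials <- trials[trials$context == mode, ]
  if (nrow(trials) == 0L) stop(sprintf("no trials in mode '%s'", mode),
                               call. = FALSE)
  lat <- trials$t_reach_rz_s - trials$t_gate_open_s
  daily <- stats::aggregate(list(mean_latency_s = lat),
                            by = list(mouse_id = trials$subject_id,
                                      day = trials$day), FUN = mean)
  daily <- daily[order(daily$mouse_id, daily$day), ]
  summ <- lapply(split(daily, daily$mouse_id), function(dm) {
    ok <- dm$mean_latency_s < criterion_s
    two <- which(ok[-length(ok)] & ok[-1] & diff(dm$day) == 1)
    data.frame(mouse_id = dm$mouse_id[1],
               mean_latency_s = mean(dm$mean_latency_s),
               criterion_met = length(two) > 0L,
               criterion_day = if (length(two)) dm$day[two[1] + 1L] else NA_integer_,
               stringsAsFactors = FALSE)
  })
  list(daily = daily, summary = do.call(rbind, c(summ, make.row.names = FALSE)))
}

#' Warm-spot occupancy totals and order
#'
#' Sums each mouse's occupancy over the session and orders mice by descending
#' total (the warm-spot competitive order). Totals are validated against the
#' session length.
#'
#' @param records data.frame(group_id, day/session, mouse_id, occupancy_s).
#' @param session_s session length in seconds (20 min by default).
#' @return data.frame(group_id, mouse_id, total_occupancy_s, ws_order).
#' @export
warmspot_occupancy <- function(records, session_s = 1200) {
  if (any(records$occupancy_s < 0)) stop("negative occupancy", call. = FALSE)
  out <- list()
  for (g in unique(records$group_id)) {
    rg <- records[records$group_id == g, ]
    per_session <- stats::aggregate(occupancy_s ~ day, data = rg, FUN = sum)
    if (any(per_session$occupancy_s > session_s + 1e-9)) {
      stop("occupancy exceeds session length", call. = FALSE)
    }
    tot <- stats::aggregate(occupancy_s ~ mouse_id, data = rg, FUN = mean)
    ord <- order(-tot$occupancy_s, tot$mouse_id)
    out[[length(out) + 1L]] <- data.frame(
      group_id = g, mouse_id = tot$mouse_id[ord],
      total_occupancy_s = tot$occupancy_s[ord],
      ws_order = seq_len(nrow(tot)), stringsAsFactors = FALSE, row.names = NULL
    )
  }
  do.call(rbind, out)
}

#' Spearman correlation between competitive order and tube rank
#'
#' @param order output of [assign_competitive_order()] for one group.
#' @param ranks one day of [tube_daily_ranks()] output for the same mice.
#' @return Spearman rho in [-1, 1].
#' @export
order_rank_correlation <- function(order, ranks) {
  mice <- intersect(order$mouse_id, ranks$mouse_id)
  if (length(mice) < 3L) stop("need at least 3 mice", call. = FALSE)
  if (!setequal(order$mouse_id, ranks$mouse_id)) {
    stop("order and ranks must cover the same mice", call. = FALSE)
  }
  oi <- order$order_index[match(mice, order$mouse_id)]
  ri <- ranks$rank[match(mice, ranks$mouse_id)]
  stats::cor(oi, ri, method = "spearman")
}
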