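#' Column schemas for the interchange tables
#'
#' Named character vectors mapping column names to types ("integer",
#' "double", "character"). All tables are RFC-4180 CSV with a header row.
#'
#' @name schemas
#' @export
schema_trials <- function() c(
  group_id = "character", day = "integer", session_id = "integer",
  pair_id = "character", trial_id = "character", subject_id = "character",
  opponent_id = "character", start_area = "character",
  t_gate_open_s = "double", t_exit_sa_s = "double", t_reach_rz_s = "double",
  pellet_winner_id = "character", opponent_relative_rank = "character"
)

#' @rdname schemas
#' @export
schema_spikes <- function() c(unit_id = "character", spike_time_s = "double")

#' @rdname schemas
#' @export
schema_tube <- function() c(
  group_id = "character", day = "integer", mouse_a = "character",
  mouse_b = "character", winner = "character", duration_s = "double"
)

#' @rdname schemas
#' @export
schema_warmspot <- function() c(
  group_id = "character", day = "integer", mouse_id = "character",
  occupancy_s = "double"
)

#' @rdname schemas
#' @export
schema_truth <- function() c(
  unit_id = "character", cell_type = "character", task_category = "character"
)

#' @rdname schemas
#' @export
schema_waveforms <- function() c(
  unit_id = "character", sample_idx = "integer", time_ms = "double",
  amplitude_uv = "double"
)

#' Read and validate a CSV table against a schema
#'
#' Requires every schema column to be present, coerces each to its declared
#' type, and reports row-level parse failures with their line numbers.
#'
#' @param path CSV file path.
#' @param schema named character vector of column types (see [schemas]).
#' @param key optional column(s) whose combination must be unique.
#' @return validated data.frame.
#' @export
read_table <- function(path, schema, key = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  miss <- setdiff(names(schema), names(df))
  if (length(miss)) {
    stop(sprintf("schema error in %s: missing column(s) %s", basename(path),
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  errs <- character(0)
  for (col in names(schema)) {
    raw <- df[[col]]
    val <- switch(schema[[col]],
      integer = suppressWarnings(as.integer(raw)),
      double = suppressWarnings(as.numeric(raw)),
      character = raw,
      stop(sprintf("unknown schema type '%s'", schema[[col]]), call. = FALSE))
    bad <- which(is.na(val) & !is.na(raw) & nzchar(raw))
    if (length(bad)) {
      errs <- c(errs, sprintf("column %s: unparsable value at line %d", col,
                              bad[1] + 1L))
    }
    df[[col]] <- val
  }
  if (length(errs)) {
    stop(paste(c(sprintf("validation errors in %s:", basename(path)), errs),
               collapse = "\n  "), call. = FALSE)
  }
  if (!is.null(key)) {
    kk <- do.call(paste, df[key])
    if (anyDuplicated(kk)) {
      stop(sprintf("duplicate key in %s: %s", basename(path),
                   kk[anyDuplicated(kk)]), call. = FALSE)
    }
  }
  df
}

#' @rdname read_table
#' @param df table to write; @param path destination.
#' @export
write_table <- function(df, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load and validate a run configuration
#'
#' The YAML configuration has three blocks: `generator` (arguments to
#' [gen_config()]), `analysis` (alpha, window, bin_ms, max_lag, n_perm) and
#' `report` (out_dir). Unknown keys are rejected at every level.
#'
#' @param path YAML file, or a list with the same structure.
#' @param seed optional seed overriding the configured one.
#' @return validated list(generator = gen_config, analysis, report).
#' @export
run_config <- function(path, seed = NULL) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  known_top <- c("seed", "generator", "analysis", "report")
  check_keys(cfg, known_top, "top level")
  gen_args <- cfg$generator %||% list()
  check_keys(gen_args, names(formals(gen_config)), "generator")
  if (!is.null(seed)) gen_args$seed <- seed
  else if (!is.null(cfg$seed)) gen_args$seed <- gen_args$seed %||% cfg$seed
  analysis <- utils::modifyList(
    list(alpha = 0.05, window = c(-2, 2), bin_ms = 1, max_lag = 15L,
         n_perm = 1000L, min_trials = 5L),
    cfg$analysis %||% list()
  )
  check_keys(analysis, c("alpha", "window", "bin_ms", "max_lag", "n_perm",
                         "min_trials"), "analysis")
  report <- utils::modifyList(list(out_dir = "results"), cfg$report %||% list())
  check_keys(report, "out_dir", "report")
  list(generator = do.call(gen_config, gen_args), analysis = analysis,
       report = report)
}

check_keys <- function(x, known, where) {
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    stop(sprintf("unknown %s key(s): %s", where,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Run the full synthetic pipeline
#'
#' Chains simulate -> behavior -> ephys -> crosscorr and writes the report
#' bundle (CSV tables plus a JSON summary and run manifest) under the
#' configured output directory. Every stage logs its parameters and seed to
#' stderr; any stage failure aborts with a stage-scoped message.
#'
#' @param config output of [run_config()] (or a YAML path passed through it).
#' @param out_dir overrides the configured output directory.
#' @return invisibly, a list with every stage result.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) || is.null(config$generator)) {
    config <- run_config(config)
  }
  gc_ <- config$generator
  an <- config$analysis
  out <- out_dir %||% config$report$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    message(sprintf("[%s] start (seed %d)", name, gc_$seed))
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  sim <- stage("simulate", {
    pop <- generate_unit_population(gc_)
    trials <- do.call(rbind, lapply(seq_len(gc_$n_groups), function(g) {
      generate_competition_sessions(gc_, sprintf("g%d", g))
    }))
    tw <- generate_tube_and_warmspot(gc_, "g1")
    spikes <- generate_spike_trains(gc_, trials, pop)
    long <- generate_longitudinal(gc_)
    waveforms <- generate_waveform_table(pop, gc_)
    list(pop = pop, trials = trials, tube = tw$tube, warmspot = tw$warmspot,
         spikes = spikes, long = long, waveforms = waveforms)
  })
  write_table(sim$trials, file.path(out, "trials.csv"))
  write_table(sim$tube, file.path(out, "tube.csv"))
  write_table(sim$warmspot, file.path(out, "warmspot.csv"))
  write_table(sim$spikes, file.path(out, "spikes.csv"))
  write_table(sim$pop$truth, file.path(out, "truth.csv"))

  beh <- stage("behavior", {
    ranks <- tube_daily_ranks(sim$tube)
    stable_day <- detect_stable_hierarchy(ranks)
    order <- assign_competitive_order(sim$trials)
    wp <- winning_proportions(sim$trials, "pellet")
    ws <- warmspot_occupancy(sim$warmspot)
    last_day <- ranks[ranks$day == max(ranks$day), ]
    rho <- order_rank_correlation(order, last_day)
    list(ranks = ranks, stable_day = stable_day, order = order,
         winning = wp, warmspot = ws, order_rank_rho = rho)
  })
  write_table(beh$ranks, file.path(out, "hierarchy.csv"))
  write_table(beh$order, file.path(out, "competitive_order.csv"))
  write_table(beh$winning, file.path(out, "winning_proportions.csv"))

  eph <- stage("ephys", {
    feats <- extract_features_table(sim$waveforms, gc_$sampling_rate_hz)
    types <- classify_cell_types(feats, seed = gc_$seed)
    subj_trials <- sim$trials[
      sim$trials$subject_id == sprintf("%s_m%d", sim$trials$group_id,
                                       gc_$recorded_mouse), ]
    rates <- trial_firing_rates(sim$spikes, subj_trials, window = an$window)
    cats <- classify_task_related(rates, subj_trials, alpha = an$alpha,
                                  min_trials = an$min_trials)
    summ <- summarize_population(types, cats)
    dz <- delta_zscore_series(sim$long$rates, baseline_day = 0L)
    list(features = feats, types = types, categories = cats, summary = summ,
         delta_z = dz)
  })
  write_table(eph$features, file.path(out, "unit_features.csv"))
  write_table(eph$types, file.path(out, "cell_types.csv"))
  write_table(eph$categories, file.path(out, "task_categories.csv"))
  write_table(eph$delta_z, file.path(out, "delta_z.csv"))
  jsonlite::write_json(
    list(counts = eph$summary$counts, totals = as.list(eph$summary$totals),
         percentages = lapply(eph$summary$percentages, as.list)),
    file.path(out, "population_summary.json"), auto_unbox = TRUE, digits = NA
  )

  cc <- stage("crosscorr", {
    dz <- eph$delta_z
    series <- function(cat) {
      s <- dz[dz$category == cat, c("day", "delta_z")]
      names(s) <- c("day", "value")
      attr(s, "label") <- paste0(cat, "_delta_z")
      s
    }
    comp <- series("competition"); rnk <- series("rank")
    win <- sim$long$winning
    res <- list(
      "winning_vs_competition" = significance_band(
        comp, win, max_lag = an$max_lag, n_perm = an$n_perm,
        alpha = an$alpha, seed = gc_$seed),
      "rank_vs_competition" = significance_band(
        comp, rnk, max_lag = an$max_lag, n_perm = an$n_perm,
        alpha = an$alpha, seed = gc_$seed)
    )
    list(results = res, report = lag_report(res))
  })
  cc_tab <- do.call(rbind, lapply(names(cc$results), function(nm) {
    r <- cc$results[[nm]]
    data.frame(pair = nm, lag = r$lags, r = r$r, p = r$p,
               significant = r$significant, stringsAsFactors = FALSE)
  }))
  write_table(cc_tab, file.path(out, "crosscorr.csv"))

  report <- list(
    seed = gc_$seed,
    stable_hierarchy_day = beh$stable_day,
    order_rank_rho = beh$order_rank_rho,
    population = list(counts = eph$summary$counts,
                      percentages = lapply(eph$summary$percentages, as.list)),
    lag_report = cc$report
  )
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(seed = gc_$seed, n_units = gc_$n_units, n_groups = gc_$n_groups,
         alpha = an$alpha, max_lag = an$max_lag, n_perm = an$n_perm,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    file.path(out, "manifest.json"), auto_unbox = TRUE
  )
  invisible(list(sim = sim, behavior = beh, ephys = eph, crosscorr = cc,
                 report = report))
}
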