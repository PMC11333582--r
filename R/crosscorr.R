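#' Lagged cross-correlation between two daily series
#'
#' For every lag `l` in `[-max_lag, max_lag]`, the Pearson correlation
#' between `x_t` and `y_(t+l)` over the overlapping segment. Positive lags
#' mean `y` lags `x` (when `x` is the neural series and `y` the behavioral
#' one, a positive peak lag means the neural change leads). The peak lag is
#' the argmax of r; ties prefer the smaller |lag|, then the negative one.
#'
#' @param x,y data.frames (day, value) on a common, strictly increasing day
#'   grid.
#' @param max_lag maximum lag in days; the series must keep at least 3
#'   overlapping points at the extreme lags.
#' @return object of class `crosscorr`: list(lags, r, n_overlap, peak_lag,
#'   r_peak, labels).
#' @export
cross_correlate <- function(x, y, max_lag = 15L) {
  sx <- align_series(x); sy <- align_series(y)
  if (!identical(sx$day, sy$day)) {
    stop("series must share a common day grid", call. = FALSE)
  }
  n <- nrow(sx)
  if (n < max_lag + 3L) {
    stop("series too short for max_lag (need length >= max_lag + 3)",
         call. = FALSE)
  }
  lags <- seq(-max_lag, max_lag)
  r <- vapply(lags, function(l) lag_cor(sx$value, sy$value, l), numeric(1))
  peak <- pick_peak(lags, r)
  structure(list(
    lags = lags, r = r,
    n_overlap = n - abs(lags),
    peak_lag = peak, r_peak = r[match(peak, lags)],
    labels = c(x = attr(x, "label") %||% "x", y = attr(y, "label") %||% "y")
  ), class = "crosscorr")
}

align_series <- function(s) {
  stopifnot(all(c("day", "value") %in% names(s)))
  s <- s[order(s$day), c("day", "value")]
  if (any(diff(s$day) <= 0)) stop("days must be strictly increasing", call. = FALSE)
  if (anyNA(s$value)) stop("series has missing values", call. = FALSE)
  s
}

lag_cor <- function(xv, yv, l) {
  n <- length(xv)
  i <- seq(max(1, 1 - l), min(n, n - l))
  xs <- xv[i]; ys <- yv[i + l]
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(NA_real_)
  stats::cor(xs, ys)
}

pick_peak <- function(lags, r) {
  ok <- which(is.finite(r))
  if (!length(ok)) return(NA_integer_)
  best <- ok[r[ok] >= max(r[ok]) - 1e-12]
  best <- best[order(abs(lags[best]), lags[best])]
  lags[best[1]]
}

#' Permutation significance band for a cross-correlogram
#'
#' Builds a per-lag null by circularly shifting `y` by uniform random
#' offsets, which preserves each series' autocorrelation while destroying
#' their alignment. The two-sided empirical p-value uses the add-one
#' correction; a lag is significant when p < alpha.
#'
#' @inheritParams cross_correlate
#' @param n_perm number of circular shifts (>= 200).
#' @param alpha test level; @param seed RNG seed.
#' @return `crosscorr` object augmented with `p`, `significant`, `n_perm`,
#'   `alpha`.
#' @export
significance_band <- function(x, y, max_lag = 15L, n_perm = 1000L,
                              alpha = 0.05, seed = 1L) {
  if (n_perm < 200L) stop("n_perm must be >= 200", call. = FALSE)
  obs <- cross_correlate(x, y, max_lag)
  sy <- align_series(y)
  n <- nrow(sy)
  xv <- align_series(x)$value
  null_r <- with_substream(seed, "ccnull", expr = {
    offs <- sample.int(n - 1L, n_perm, replace = TRUE)
    vapply(offs, function(o) {
      ys <- sy$value[((seq_len(n) - 1L + o) %% n) + 1L]
      vapply(obs$lags, function(l) lag_cor(xv, ys, l), numeric(1))
    }, numeric(length(obs$lags)))
  })
  p <- vapply(seq_along(obs$lags), function(i) {
    if (!is.finite(obs$r[i])) return(NA_real_)
    nr <- null_r[i, ]
    nr <- nr[is.finite(nr)]
    (1 + sum(abs(nr) >= abs(obs$r[i]))) / (length(nr) + 1)
  }, numeric(1))
  obs$p <- p
  obs$significant <- !is.na(p) & p < alpha
  obs$n_perm <- n_perm
  obs$alpha <- alpha
  obs
}

#' Peak-lag comparison table across series pairs
#'
#' @param results named list of `crosscorr` objects.
#' @return data.frame(pair, peak_lag, r_peak, significant_at_peak).
#' @export
lag_report <- function(results) {
  if (!length(results)) {
    return(data.frame(pair = character(0), peak_lag = integer(0),
                      r_peak = numeric(0), significant_at_peak = logical(0)))
  }
  rows <- lapply(seq_along(results), function(i) {
    cc <- results[[i]]
    lab <- names(results)[i] %||% paste(cc$labels, collapse = " vs ")
    if (is.null(names(results)) || !nzchar(lab)) {
      lab <- paste(cc$labels, collapse = " vs ")
    }
    sig <- if (!is.null(cc$significant)) {
      cc$significant[match(cc$peak_lag, cc$lags)]
    } else NA
    data.frame(pair = lab, peak_lag = cc$peak_lag, r_peak = cc$r_peak,
               significant_at_peak = sig, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' @export
print.crosscorr <- function(x, ...) {
  cat(sprintf("cross-correlation %s vs %s: peak lag %d (r = %.3f)\n",
              x$labels[["x"]], x$labels[["y"]], x$peak_lag, x$r_peak))
  if (!is.null(x$significant)) {
    cat(sprintf("  significant lags (alpha %.3g): %s\n", x$alpha,
                paste(x$lags[x$significant], collapse = ", ")))
  }
  invisible(x)
}
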