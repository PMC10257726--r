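#' Per-cell pulse frequency over a frame window
#'
#' Counts detected peaks whose `peak_frame` lies in the window and
#' normalises by the window duration in hours (frames 1--40 span the
#' first 120 min, i.e. 2 h).
#'
#' @param peaks colony-wide peak table (needs `cell_id` and
#'   `peak_frame`; `colony_id` optional).
#' @param window inclusive frame range `c(first, last)`.
#' @param cell_ids cells to report; defaults to the cells present in
#'   `peaks`. Supplying the full cell list includes zero-pulse cells.
#' @return Data frame: `cell_id`, `window_start`, `window_end`,
#'   `n_pulses`, `hours`, `pulses_per_hour`.
#' @export
pulse_frequency <- function(peaks, window = c(1L, 40L), cell_ids = NULL) {
  if (length(window) != 2L || window[2] < window[1]) {
    stop_invalid("window must be a non-empty frame range c(first, last)")
  }
  hours <- (window[2] - window[1] + 1L) * FRAME_INTERVAL_MIN / 60
  key <- if ("colony_id" %in% names(peaks)) {
    paste(peaks$colony_id, peaks$cell_id, sep = "/")
  } else {
    peaks$cell_id
  }
  if (is.null(cell_ids)) cell_ids <- unique(key)
  in_win <- peaks$peak_frame >= window[1] & peaks$peak_frame <= window[2]
  counts <- vapply(cell_ids, function(cid) sum(in_win & key == cid),
                   integer(1))
  data.frame(cell_id = cell_ids,
             window_start = window[1], window_end = window[2],
             n_pulses = counts, hours = hours,
             pulses_per_hour = counts / hours,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-cell before/after frequency table around a perturbation
#'
#' Builds the paired pulses/hour table for cells classified active over
#' the full recording — only active cells are plotted and tested in
#' before/after comparisons. Windows are frames `1..boundary_frame` and
#' `boundary_frame+1..total_frames` (by default 1--40 and 41--80, the
#' two 120-min halves around a perturbation applied between frames 40
#' and 41).
#'
#' @param peaks colony-wide peak table.
#' @param statuses status table from [classify_cells()].
#' @param boundary_frame last pre-perturbation frame.
#' @param total_frames recording length in frames.
#' @return Data frame: `cell_id`, `before_per_hour`, `after_per_hour`.
#' @export
perturbation_table <- function(peaks, statuses, boundary_frame = 40L,
                               total_frames = 80L) {
  act <- statuses[statuses$status == "active", , drop = FALSE]
  ids <- paste(act$colony_id, act$cell_id, sep = "/")
  before <- pulse_frequency(peaks, c(1L, boundary_frame), ids)
  after <- pulse_frequency(peaks, c(boundary_frame + 1L, total_frames), ids)
  data.frame(cell_id = ids,
             before_per_hour = before$pulses_per_hour,
             after_per_hour = after$pulses_per_hour,
             row.names = NULL, stringsAsFactors = FALSE)
}

t_result <- function(test, n, t_stat, p, mean_a, mean_b,
                     p_below_1e6 = FALSE) {
  structure(list(test = test, n = n, t_statistic = t_stat, p_value = p,
                 mean_a = mean_a, mean_b = mean_b,
                 p_below_1e6 = p_below_1e6),
            class = "erk_test_result")
}

#' @export
print.erk_test_result <- function(x, ...) {
  p_str <- if (x$p_below_1e6) "< 1e-6" else format(x$p_value, digits = 4)
  cat(sprintf("%s: n = %d, t = %s, P %s %s (means %.4g vs %.4g)\n",
              x$test, x$n, format(x$t_statistic, digits = 4),
              if (x$p_below_1e6) "" else "=", p_str, x$mean_a, x$mean_b))
  invisible(x)
}

#' Paired t-test of before vs after pulse frequencies
#'
#' Two-sided paired t-test on per-cell differences (after - before).
#' Degenerate zero-variance differences are handled explicitly: all
#' differences zero gives t = 0, p = 1; a constant non-zero difference
#' is reported as p below 1e-6 (`p_below_1e6` flag) rather than NaN.
#'
#' @param before,after equal-length paired numeric vectors (e.g. the
#'   columns of [perturbation_table()]).
#' @return An `erk_test_result`: `test`, `n` (pairs), `t_statistic`,
#'   `p_value`, `mean_a` (before), `mean_b` (after), `p_below_1e6`.
#' @export
before_after_test <- function(before, after) {
  if (length(before) != length(after)) {
    stop_invalid("before and after must be paired (equal length)")
  }
  ok <- !is.na(before) & !is.na(after)
  before <- before[ok]
  after <- after[ok]
  n <- length(before)
  if (n < 2L) stop_invalid("need at least 2 pairs")
  d <- after - before
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(t_result("paired_t", n, 0, 1, mean(before), mean(after)))
    }
    return(t_result("paired_t", n, sign(mean(d)) * Inf, 0,
                    mean(before), mean(after), p_below_1e6 = TRUE))
  }
  tt <- stats::t.test(after, before, paired = TRUE)
  t_result("paired_t", n, unname(tt$statistic), tt$p.value,
           mean(before), mean(after))
}

#' Two-sample t-test of pulse frequencies between groups
#'
#' Two-sided two-sample t-test, Welch (unequal variance) by default, on
#' pulses/hour of two groups of cells (e.g. +LIF vs -LIF active cells
#' over the first 120 min).
#'
#' @param freqs_a,freqs_b numeric vectors of per-cell pulses/hour.
#' @param var_equal use the pooled-variance Student test instead of
#'   Welch.
#' @return An `erk_test_result` (see [before_after_test()]).
#' @export
compare_groups <- function(freqs_a, freqs_b, var_equal = FALSE) {
  freqs_a <- freqs_a[!is.na(freqs_a)]
  freqs_b <- freqs_b[!is.na(freqs_b)]
  if (length(freqs_a) < 2L || length(freqs_b) < 2L) {
    stop_invalid("each group needs at least 2 values")
  }
  if (stats::sd(freqs_a) == 0 && stats::sd(freqs_b) == 0) {
    if (mean(freqs_a) == mean(freqs_b)) {
      return(t_result("two_sample_t", length(freqs_a) + length(freqs_b),
                      0, 1, mean(freqs_a), mean(freqs_b)))
    }
    return(t_result("two_sample_t", length(freqs_a) + length(freqs_b),
                    sign(mean(freqs_a) - mean(freqs_b)) * Inf, 0,
                    mean(freqs_a), mean(freqs_b), p_below_1e6 = TRUE))
  }
  tt <- stats::t.test(freqs_a, freqs_b, var.equal = var_equal)
  t_result("two_sample_t", length(freqs_a) + length(freqs_b),
           unname(tt$statistic), tt$p.value, mean(freqs_a), mean(freqs_b))
}

#' Fit an exponential law to pooled inter-pulse intervals
#'
#' Inter-pulse intervals (IPIs) are gaps between consecutive pulse times
#' *within* a cell, pooled across cells and colonies; censored gaps
#' before the first and after the last pulse are not observable and are
#' dropped. The exponential rate is estimated by maximum likelihood
#' (rate = 60 / mean IPI in minutes, in events/hour) and a one-sample
#' Kolmogorov-Smirnov test against that exponential is reported, along
#' with histogram bin counts.
#'
#' @param peaks peak table with `cell_id` (and optionally `colony_id`)
#'   and `peak_time_min`; alternatively a list of per-cell numeric pulse
#'   time vectors (minutes).
#' @param min_intervals minimum pooled intervals required (default 10).
#' @param bin_width_min histogram bin width, minutes.
#' @return A list: `n_intervals`, `mean_ipi_min`, `rate_per_hour`,
#'   `ks_statistic`, `ks_p`, `histogram` (data frame `bin_left_min`,
#'   `count`), `intervals`.
#' @export
fit_ipi_exponential <- function(peaks, min_intervals = 10L,
                                bin_width_min = 10) {
  times_by_cell <- if (is.data.frame(peaks)) {
    key <- if ("colony_id" %in% names(peaks)) {
      paste(peaks$colony_id, peaks$cell_id, sep = "/")
    } else {
      peaks$cell_id
    }
    split(peaks$peak_time_min, key)
  } else {
    peaks
  }
  intervals <- unlist(lapply(times_by_cell, function(tt) diff(sort(tt))),
                      use.names = FALSE)
  if (length(intervals) < min_intervals) {
    stop_invalid(sprintf("need at least %d inter-pulse intervals, got %d",
                         min_intervals, length(intervals)))
  }
  mean_ipi <- mean(intervals)
  rate_hr <- 60 / mean_ipi
  ks <- suppressWarnings(
    stats::ks.test(intervals, stats::pexp, rate = 1 / mean_ipi))
  breaks <- seq(0, max(intervals) + bin_width_min, by = bin_width_min)
  counts <- tabulate(findInterval(intervals, breaks),
                     nbins = length(breaks) - 1L)
  list(n_intervals = length(intervals), mean_ipi_min = mean_ipi,
       rate_per_hour = rate_hr,
       ks_statistic = unname(ks$statistic), ks_p = ks$p.value,
       histogram = data.frame(bin_left_min = breaks[-length(breaks)],
                              count = counts),
       intervals = intervals)
}
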