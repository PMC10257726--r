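#' Synchrony analysis configuration
#'
#' @param max_lag_frames maximum lag examined, in frames. The default 8
#'   frames (24 min) is the largest frame multiple not exceeding the
#'   +/-25 min synchrony window.
#' @param r_threshold correlation above which a pair counts as strongly
#'   correlated (default 0.7).
#' @param window inclusive frame range analysed; the default `c(1, 40)`
#'   is the first 120 min.
#' @param min_overlap_frames minimum overlapping complete observations
#'   required at an evaluated lag.
#' @param detrend_window rolling-median window (frames) applied before
#'   correlating, so baseline differences and drift do not inflate r.
#' @return An object of class `sync_config`.
#' @export
sync_config <- function(max_lag_frames = 8L, r_threshold = 0.7,
                        window = c(1L, 40L), min_overlap_frames = 30L,
                        detrend_window = 21L) {
  max_lag_frames <- as.integer(max_lag_frames)
  if (is.na(max_lag_frames) || max_lag_frames < 0L) {
    stop_invalid("max_lag_frames must be >= 0")
  }
  if (r_threshold <= 0 || r_threshold > 1) {
    stop_invalid("r_threshold must lie in (0, 1]")
  }
  structure(list(max_lag_frames = max_lag_frames, r_threshold = r_threshold,
                 window = as.integer(window),
                 min_overlap_frames = as.integer(min_overlap_frames),
                 detrend_window = as.integer(detrend_window)),
            class = "sync_config")
}

# extract a trace's ratio on the window's frame grid (NA where missing),
# detrended and z-scored
windowed_series <- function(trace, config) {
  grid <- config$window[1]:config$window[2]
  x <- rep(NA_real_, length(grid))
  m <- match(grid, trace$frame)
  x[!is.na(m)] <- trace$ratio[m[!is.na(m)]]
  x <- detrend(x, "rolling_median", config$detrend_window)
  mu <- mean(x, na.rm = TRUE)
  sdev <- stats::sd(x, na.rm = TRUE)
  if (is.na(sdev) || sdev == 0) return(rep(NA_real_, length(grid)))
  (x - mu) / sdev
}

#' Lagged cross-correlation of two traces
#'
#' Both traces are restricted to the analysis window, detrended with a
#' rolling median and z-scored. For each integer lag k in
#' `[-max_lag, +max_lag]`, r(k) is the Pearson correlation of the
#' overlapping aligned samples of trace i against trace j shifted by k
#' frames; a positive reported lag means trace j lags (is delayed
#' relative to) trace i. The maximum of r(k) and its lag (in minutes)
#' are returned; ties go to the smallest absolute lag.
#'
#' @param trace_i,trace_j [new_trace()] objects from the same colony.
#' @param config a [sync_config()].
#' @return A list: `cell_i`, `cell_j`, `r_max`, `lag_at_max_min`,
#'   `is_strong`, `n_lags_evaluated`, `r_by_lag` (data frame
#'   `lag_frames`, `lag_min`, `r`, `n_overlap`), and `reason` (`NA` on
#'   success, otherwise why the result is absent).
#' @export
cross_correlation <- function(trace_i, trace_j, config = sync_config()) {
  xi <- windowed_series(trace_i, config)
  xj <- windowed_series(trace_j, config)
  n <- length(xi)
  lags <- -config$max_lag_frames:config$max_lag_frames
  r <- rep(NA_real_, length(lags))
  n_ov <- integer(length(lags))
  for (li in seq_along(lags)) {
    k <- lags[li]
    if (k >= 0) {
      a <- xi[seq_len(n - k)]
      b <- xj[seq_len(n - k) + k]
    } else {
      a <- xi[seq_len(n + k) - k]
      b <- xj[seq_len(n + k)]
    }
    ok <- !is.na(a) & !is.na(b)
    n_ov[li] <- sum(ok)
    if (n_ov[li] >= config$min_overlap_frames &&
        stats::sd(a[ok]) > 0 && stats::sd(b[ok]) > 0) {
      r[li] <- stats::cor(a[ok], b[ok])
    }
  }
  out <- list(cell_i = trace_i$cell_id, cell_j = trace_j$cell_id,
              r_max = NA_real_, lag_at_max_min = NA_real_,
              is_strong = NA, n_lags_evaluated = sum(!is.na(r)),
              r_by_lag = data.frame(lag_frames = lags,
                                    lag_min = FRAME_INTERVAL_MIN * lags,
                                    r = r, n_overlap = n_ov),
              reason = NA_character_)
  if (all(is.na(r))) {
    out$reason <- "insufficient_overlap"
    return(out)
  }
  rmax <- max(r, na.rm = TRUE)
  best <- lags[which(!is.na(r) & r == rmax)]
  best <- best[order(abs(best), best)][1]
  out$r_max <- rmax
  out$lag_at_max_min <- FRAME_INTERVAL_MIN * best
  out$is_strong <- rmax > config$r_threshold
  out
}

# minimal union-find for connected components of the strong-pair graph
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Pairwise synchrony analysis of a colony
#'
#' Evaluates the lagged cross-correlation of every unordered pair of
#' analysable (by default, active) cells, flags strong pairs
#' (`r_max > r_threshold`) and builds synchronised groups as the
#' connected components of the strong-pair graph.
#'
#' @param dataset a [colony_dataset()] (one colony).
#' @param statuses optional status table from [classify_cells()]; when
#'   supplied, only cells with status `"active"` are analysed.
#' @param config a [sync_config()].
#' @return A list: `pairs` (data frame `colony_id`, `cell_i`, `cell_j`,
#'   `r_max`, `lag_min`, `is_strong`), `strong_pairs` (its strong
#'   subset), `groups` (data frame `group_id`, `cell_id`; only groups
#'   with >= 2 members), `n_cells` analysed.
#' @export
pairwise_sync <- function(dataset, statuses = NULL, config = sync_config()) {
  traces <- dataset$traces
  if (!is.null(statuses)) {
    act <- statuses[statuses$status == "active", , drop = FALSE]
    keys <- paste(act$colony_id, act$cell_id, sep = "/")
    traces <- traces[names(traces) %in% keys]
  }
  empty <- data.frame(colony_id = character(0), cell_i = character(0),
                      cell_j = character(0), r_max = numeric(0),
                      lag_min = numeric(0), is_strong = logical(0))
  if (length(traces) < 2L) {
    return(list(pairs = empty, strong_pairs = empty,
                groups = data.frame(group_id = integer(0),
                                    cell_id = character(0)),
                n_cells = length(traces)))
  }
  m <- length(traces)
  rows <- list()
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      cc <- cross_correlation(traces[[i]], traces[[j]], config)
      rows[[length(rows) + 1L]] <- data.frame(
        colony_id = traces[[i]]$colony_id,
        cell_i = cc$cell_i, cell_j = cc$cell_j,
        r_max = cc$r_max, lag_min = cc$lag_at_max_min,
        is_strong = isTRUE(cc$is_strong), stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, rows)
  rownames(pairs) <- NULL
  strong <- pairs[pairs$is_strong, , drop = FALSE]

  ids <- vapply(traces, `[[`, character(1), "cell_id")
  parent <- seq_len(m)
  for (k in seq_len(nrow(strong))) {
    a <- uf_find(parent, match(strong$cell_i[k], ids))
    b <- uf_find(parent, match(strong$cell_j[k], ids))
    if (a != b) parent[b] <- a
  }
  root <- vapply(seq_len(m), function(i) uf_find(parent, i), integer(1))
  comp_sizes <- table(root)
  keep_roots <- as.integer(names(comp_sizes)[comp_sizes >= 2L])
  groups <- if (length(keep_roots)) {
    gid <- match(root, sort(keep_roots))
    keep <- !is.na(gid)
    data.frame(group_id = gid[keep], cell_id = ids[keep],
               stringsAsFactors = FALSE)[order(gid[keep]), , drop = FALSE]
  } else {
    data.frame(group_id = integer(0), cell_id = character(0))
  }
  rownames(groups) <- NULL
  list(pairs = pairs, strong_pairs = strong, groups = groups, n_cells = m)
}
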