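#' Flag dividing cells for exclusion
#'
#' Cells that divide during imaging must be excluded: both fluorescence
#' channels collapse at division and the ratio no longer reports kinase
#' activity. When raw channels are present, a cell is flagged iff CFP
#' *and* YFP each fall by at least `drop_fraction` (default 40%) between
#' consecutive frames — a drop in one channel alone is a ratio artifact,
#' not a division. Without channels, a ratio-only fallback applies: a
#' drop of >= 0.15 ratio units within one frame that stays depressed for
#' at least two frames.
#'
#' The channel rule is invariant to uniform rescaling of both channels
#' (drops are relative).
#'
#' @param trace an [new_trace()] object.
#' @param drop_fraction relative per-frame drop required in both
#'   channels.
#' @return A one-row data frame: `cell_id`, `excluded`, `reason`
#'   (`"division"` or `NA`), `first_bad_frame`.
#' @export
flag_division <- function(trace, drop_fraction = 0.4) {
  n <- length(trace$frame)
  hit <- integer(0)
  if (!is.null(trace$cfp) && !is.null(trace$yfp)) {
    if (n >= 2L) {
      rel_drop <- function(x) (x[-n] - x[-1]) / x[-n]
      dc <- rel_drop(trace$cfp)
      dy <- rel_drop(trace$yfp)
      both <- !is.na(dc) & !is.na(dy) & dc >= drop_fraction & dy >= drop_fraction
      hit <- which(both) + 1L
    }
  } else if (n >= 3L) {
    r <- trace$ratio
    for (i in 2:(n - 1L)) {
      if (!anyNA(r[(i - 1L):(i + 1L)]) &&
          r[i] <= r[i - 1L] - 0.15 && r[i + 1L] <= r[i - 1L] - 0.15) {
        hit <- i
        break
      }
    }
  }
  excluded <- length(hit) > 0L
  data.frame(cell_id = trace$cell_id,
             excluded = excluded,
             reason = if (excluded) "division" else NA_character_,
             first_bad_frame = if (excluded) trace$frame[hit[1]] else NA_integer_,
             stringsAsFactors = FALSE)
}

#' QC an entire dataset
#'
#' Applies [flag_division()] to every trace.
#'
#' @param dataset a [colony_dataset()].
#' @param drop_fraction passed to [flag_division()].
#' @return A data frame with one QC row per cell, plus `colony_id`.
#' @export
qc_dataset <- function(dataset, drop_fraction = 0.4) {
  rows <- lapply(dataset$traces, function(tr) {
    out <- flag_division(tr, drop_fraction)
    cbind(colony_id = tr$colony_id, out, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detrend a ratio series
#'
#' Removes slow baseline drift while preserving the local level of the
#' series, for use before cross-correlation. `rolling_median` subtracts
#' a centred running median (windows shrink at the edges) and adds back
#' the global median; `linear` subtracts the least-squares line and adds
#' back the mean; `none` is the identity. Peak detection itself runs on
#' the raw ratio — the absolute 1.2 threshold is only meaningful
#' undetrended.
#'
#' @param x numeric series (`NA`s allowed and preserved).
#' @param method `"none"`, `"linear"` or `"rolling_median"`.
#' @param window_frames odd window width for `rolling_median`.
#' @return Series of the same length.
#' @export
detrend <- function(x, method = c("none", "linear", "rolling_median"),
                    window_frames = 21L) {
  method <- tryCatch(match.arg(method),
                     error = function(e) stop_invalid(
                       sprintf("unknown detrend method '%s'", method[1])))
  n <- length(x)
  if (method == "none" || n == 0L) return(x)
  if (method == "linear") {
    idx <- seq_len(n)
    ok <- !is.na(x)
    if (sum(ok) < 2L) return(x)
    fit <- stats::lm.fit(cbind(1, idx[ok]), x[ok])
    trend <- cbind(1, idx) %*% fit$coefficients
    return(as.numeric(x - trend + mean(x, na.rm = TRUE)))
  }
  # rolling_median
  window_frames <- as.integer(window_frames)
  if (window_frames %% 2L == 0L) {
    stop_invalid("window_frames must be odd for rolling_median")
  }
  half <- window_frames %/% 2L
  med <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    stats::median(x[lo:hi], na.rm = TRUE)
  }, numeric(1))
  x - med + stats::median(x, na.rm = TRUE)
}
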