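#' Peak detector configuration
#'
#' @param mph minimum peak height: ratio threshold a sample must exceed
#'   to count as a pulse peak (default 1.2).
#' @param mpd minimum peak distance in frames (default 3 = 9 min):
#'   among candidate peaks separated by `mpd` frames or fewer, only the
#'   highest survives.
#' @param wide_min_frames minimum suprathreshold episode length, in
#'   frames, for the episode to count as "wide" (default 5 = 15 min).
#' @param strict_above if `TRUE` (default) a peak must be strictly above
#'   `mph`; `FALSE` admits exact ties, matching detectors with `>=`
#'   semantics. The two differ only on exact ties, measure-zero on real
#'   data.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(mph = 1.2, mpd = 3L, wide_min_frames = 5L,
                            strict_above = TRUE) {
  mpd <- as.integer(mpd)
  if (mph <= 0) stop_invalid("mph must be > 0")
  if (is.na(mpd) || mpd < 0L) stop_invalid("mpd must be a non-negative integer")
  structure(list(mph = mph, mpd = mpd,
                 wide_min_frames = as.integer(wide_min_frames),
                 strict_above = strict_above),
            class = "detector_config")
}

ratio_of <- function(x) if (inherits(x, "erk_trace")) x$ratio else as.numeric(x)
frames_of <- function(x, ratio) {
  if (inherits(x, "erk_trace")) x$frame else seq_along(ratio)
}

empty_peaks <- function() {
  data.frame(peak_frame = integer(0), peak_time_min = numeric(0),
              height = numeric(0))
}

#' Detect pulse peaks in a ratio trace
#'
#' A candidate peak is a sample strictly greater than its predecessor
#' and greater than or equal to its successor (a flat-topped plateau
#' yields its first sample) whose value exceeds the `mph` threshold.
#' Candidates are then pruned by the minimum-peak-distance rule: taking
#' candidates in descending height (ties broken toward the earlier
#' frame), a candidate is kept only if every already-kept peak is more
#' than `mpd` frames away. Missing (`NA`) samples break peak eligibility
#' at their neighbours.
#'
#' @param x an [new_trace()] object or a numeric ratio series.
#' @param config a [detector_config()].
#' @return A data frame of peaks: `peak_frame`, `peak_time_min`,
#'   `height`. Series shorter than 3 samples yield zero peaks.
#' @export
detect_peaks <- function(x, config = detector_config()) {
  r <- ratio_of(x)
  fr <- frames_of(x, r)
  n <- length(r)
  if (n < 3L) return(empty_peaks())

  above <- if (config$strict_above) r > config$mph else r >= config$mph
  i <- 2:(n - 1L)
  cand <- i[!is.na(r[i]) & !is.na(r[i - 1L]) & !is.na(r[i + 1L]) &
            r[i] > r[i - 1L] & r[i] >= r[i + 1L] & above[i]]
  if (!length(cand)) return(empty_peaks())

  # greedy minimum-peak-distance pruning, highest first
  ord <- cand[order(-r[cand], fr[cand])]
  kept <- integer(0)
  for (j in ord) {
    if (!length(kept) || all(abs(fr[kept] - fr[j]) > config$mpd)) {
      kept <- c(kept, j)
    }
  }
  kept <- sort(kept)
  data.frame(peak_frame = fr[kept],
             peak_time_min = FRAME_INTERVAL_MIN * fr[kept],
             height = r[kept])
}

# local baseline for width measurement: median of up to 3 sub-threshold
# samples flanking the suprathreshold episode containing the peak,
# capped at the global 10th percentile. The flank median alone sits on
# the pulse's own tails and overestimates the baseline of wide pulses
# (biasing FWHM low); the global lower decile alone is blind to local
# level shifts. The minimum of the two keeps the estimate robust both
# to neighbouring pulses and to the measured pulse's own skirt. If the
# trace never dips below threshold, only the global decile is usable.
local_baseline <- function(r, peak_idx, mph) {
  n <- length(r)
  lo <- peak_idx
  while (lo > 1L && !is.na(r[lo - 1L]) && r[lo - 1L] > mph) lo <- lo - 1L
  hi <- peak_idx
  while (hi < n && !is.na(r[hi + 1L]) && r[hi + 1L] > mph) hi <- hi + 1L
  flank <- c(
    if (lo > 1L) r[max(1L, lo - 3L):(lo - 1L)],
    if (hi < n) r[(hi + 1L):min(n, hi + 3L)]
  )
  flank <- flank[!is.na(flank) & flank <= mph]
  q10 <- stats::quantile(r, 0.10, na.rm = TRUE, names = FALSE)
  if (length(flank)) min(stats::median(flank), q10) else q10
}

# time of the half-level crossing walking from the peak in direction
# dir (-1 left, +1 right); NA if the series ends (or a gap intervenes)
# before crossing.
half_crossing <- function(t, r, peak_idx, half, dir) {
  n <- length(r)
  j <- peak_idx + dir
  prev <- peak_idx
  while (j >= 1L && j <= n) {
    if (is.na(r[j])) return(NA_real_)
    if (r[j] <= half) {
      if (r[j] == half || r[prev] == r[j]) return(t[j])
      # linear interpolation between prev (above) and j (below)
      return(t[prev] + (half - r[prev]) / (r[j] - r[prev]) * (t[j] - t[prev]))
    }
    prev <- j
    j <- j + dir
  }
  NA_real_
}

#' Measure a pulse's full width at half maximum
#'
#' The half level is `local_baseline + (height - local_baseline) / 2`;
#' the width is the time between the linearly interpolated crossings of
#' that level on either side of the peak. Pulses at the series edge with
#' no crossing on one side get `NA` width.
#'
#' @param x the trace (or ratio series) the pulse was detected in.
#' @param peak_frame frame index of the pulse peak.
#' @param config the [detector_config()] used for detection (supplies
#'   the threshold defining the flanking sub-threshold baseline).
#' @return Width in minutes, or `NA` if a crossing is missing.
#' @export
measure_width <- function(x, peak_frame, config = detector_config()) {
  r <- ratio_of(x)
  fr <- frames_of(x, r)
  idx <- match(peak_frame, fr)
  if (is.na(idx)) stop_invalid("peak_frame not present in the trace")
  t <- FRAME_INTERVAL_MIN * fr
  base <- local_baseline(r, idx, config$mph)
  half <- base + (r[idx] - base) / 2
  left <- half_crossing(t, r, idx, half, -1L)
  right <- half_crossing(t, r, idx, half, +1L)
  if (is.na(left) || is.na(right)) return(NA_real_)
  right - left
}

#' Find suprathreshold episodes and wide "aggregate" pulses
#'
#' Episodes are maximal runs of consecutive frames with ratio above the
#' threshold. An episode is *wide* if it spans at least
#' `wide_min_frames` frames (default 15 min) or contains two or more
#' detected peaks — the signature of a widened pulse recognised as an
#' aggregate of pulses by the detector.
#'
#' @param x trace or ratio series.
#' @param pulses peak table from [detect_peaks()] on the same series.
#' @param config a [detector_config()].
#' @return A list: `episodes` (data frame `episode_id`, `start_frame`,
#'   `end_frame`, `n_peaks`, `duration_min`, `is_wide`) and `pulses`
#'   (the input peak table with `episode_id` and `episode_is_wide`
#'   columns added).
#' @export
find_episodes <- function(x, pulses, config = detector_config()) {
  r <- ratio_of(x)
  fr <- frames_of(x, r)
  above <- if (config$strict_above) r > config$mph else r >= config$mph
  above[is.na(above)] <- FALSE
  # runs must be consecutive in frame index (gaps break runs)
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  episodes <- data.frame(episode_id = integer(0), start_frame = integer(0),
                         end_frame = integer(0), n_peaks = integer(0),
                         duration_min = numeric(0), is_wide = logical(0))
  pulses$episode_id <- rep(NA_integer_, nrow(pulses))
  pulses$episode_is_wide <- rep(NA, nrow(pulses))
  eid <- 0L
  for (k in keep) {
    idx <- starts[k]:ends[k]
    # split runs that span a frame gap
    brk <- c(0L, which(diff(fr[idx]) != 1L), length(idx))
    for (s in seq_len(length(brk) - 1L)) {
      sub <- idx[(brk[s] + 1L):brk[s + 1L]]
      eid <- eid + 1L
      f0 <- fr[sub[1]]
      f1 <- fr[sub[length(sub)]]
      in_ep <- !is.na(pulses$peak_frame) & pulses$peak_frame >= f0 &
        pulses$peak_frame <= f1
      n_peaks <- sum(in_ep)
      len <- f1 - f0 + 1L
      wide <- (len >= config$wide_min_frames) || (n_peaks >= 2L)
      episodes <- rbind(episodes, data.frame(
        episode_id = eid, start_frame = f0, end_frame = f1,
        n_peaks = n_peaks, duration_min = FRAME_INTERVAL_MIN * len,
        is_wide = wide))
      pulses$episode_id[in_ep] <- eid
      pulses$episode_is_wide[in_ep] <- wide
    }
  }
  rownames(episodes) <- NULL
  list(episodes = episodes, pulses = pulses)
}

#' Run pulse detection over a whole dataset
#'
#' Applies [detect_peaks()], [measure_width()] and [find_episodes()] to
#' every trace and assembles colony-wide peak and episode tables.
#'
#' @param dataset a [colony_dataset()].
#' @param config a [detector_config()].
#' @param measure_widths compute per-pulse FWHMs (default `TRUE`).
#' @return A list of data frames: `peaks` (`colony_id`, `cell_id`,
#'   `peak_frame`, `peak_time_min`, `height`, `width_min`, `episode_id`,
#'   `episode_is_wide`) and `episodes` (per-cell episode table).
#' @export
detect_pulses <- function(dataset, config = detector_config(),
                          measure_widths = TRUE) {
  peak_rows <- list()
  ep_rows <- list()
  for (tr in dataset$traces) {
    pk <- detect_peaks(tr, config)
    ep <- find_episodes(tr, pk, config)
    pk <- ep$pulses
    pk$width_min <- if (measure_widths && nrow(pk)) {
      vapply(pk$peak_frame, function(f) measure_width(tr, f, config),
             numeric(1))
    } else {
      numeric(nrow(pk))
    }
    if (nrow(pk)) {
      peak_rows[[length(peak_rows) + 1L]] <-
        cbind(colony_id = tr$colony_id, cell_id = tr$cell_id, pk,
              stringsAsFactors = FALSE)
    }
    if (nrow(ep$episodes)) {
      ep_rows[[length(ep_rows) + 1L]] <-
        cbind(colony_id = tr$colony_id, cell_id = tr$cell_id, ep$episodes,
              stringsAsFactors = FALSE)
    }
  }
  empty_pk <- data.frame(colony_id = character(0), cell_id = character(0),
                         peak_frame = integer(0), peak_time_min = numeric(0),
                         height = numeric(0), episode_id = integer(0),
                         episode_is_wide = logical(0), width_min = numeric(0))
  empty_ep <- data.frame(colony_id = character(0), cell_id = character(0),
                         episode_id = integer(0), start_frame = integer(0),
                         end_frame = integer(0), n_peaks = integer(0),
                         duration_min = numeric(0), is_wide = logical(0))
  peaks <- if (length(peak_rows)) do.call(rbind, peak_rows) else empty_pk
  episodes <- if (length(ep_rows)) do.call(rbind, ep_rows) else empty_ep
  rownames(peaks) <- rownames(episodes) <- NULL
  list(peaks = peaks, episodes = episodes)
}
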