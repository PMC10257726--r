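#' Construct a single-cell ratio trace
#'
#' A trace holds one cell's FRET/CFP ratio series sampled on a 3-minute
#' frame grid, together with optional raw donor (CFP) and acceptor (YFP)
#' channel intensities. Frames are 1-based indices `T` and time is
#' `3 * T` minutes exactly, so frame 33 corresponds to 99 min. Missing
#' frames are kept as `NA` gaps, never as zeros; the observed duration
#' used by classification is `3 *` (number of non-missing ratio samples).
#'
#' @param cell_id cell label.
#' @param colony_id colony label.
#' @param frame integer vector of 1-based frame indices, strictly
#'   increasing.
#' @param ratio numeric FRET/CFP ratio series (dimensionless); `NA` marks
#'   a missing sample.
#' @param cfp,yfp optional raw channel intensity series, same length as
#'   `frame`.
#' @return An object of class `erk_trace`: a list with fields `cell_id`,
#'   `colony_id`, `frame`, `time_min`, `ratio`, `cfp`, `yfp`,
#'   `observed_frames`.
#' @export
new_trace <- function(cell_id, colony_id, frame, ratio, cfp = NULL, yfp = NULL) {
  frame <- as.integer(frame)
  if (length(frame) == 0L) stop_invalid("trace must contain at least one frame")
  if (any(diff(frame) <= 0L)) {
    stop_invalid(sprintf("frames must be strictly increasing (cell %s)", cell_id))
  }
  if (length(ratio) != length(frame)) {
    stop_invalid("ratio and frame must have equal length")
  }
  for (ch in list(cfp = cfp, yfp = yfp)) {
    if (!is.null(ch) && length(ch) != length(frame)) {
      stop_invalid("channel series must match frame length")
    }
  }
  structure(list(
    cell_id = as.character(cell_id),
    colony_id = as.character(colony_id),
    frame = frame,
    time_min = FRAME_INTERVAL_MIN * frame,
    ratio = as.numeric(ratio),
    cfp = if (is.null(cfp)) NULL else as.numeric(cfp),
    yfp = if (is.null(yfp)) NULL else as.numeric(yfp),
    observed_frames = sum(!is.na(ratio))
  ), class = "erk_trace")
}

#' @export
print.erk_trace <- function(x, ...) {
  cat(sprintf("<erk_trace> %s / %s: %d frames (%d observed), %s channels\n",
              x$colony_id, x$cell_id, length(x$frame), x$observed_frames,
              if (is.null(x$cfp)) "no raw" else "cfp/yfp"))
  invisible(x)
}

#' Construct a colony dataset
#'
#' The unit of analysis: a set of single-cell traces from one or more
#' colonies imaged under a common condition, with optional perturbation
#' metadata.
#'
#' @param traces list of [new_trace()] objects.
#' @param condition `"+LIF"` (maintenance) or `"-LIF"` (differentiating).
#' @param perturbation a [perturbation_spec()] or `NULL`.
#' @return An object of class `colony_dataset`.
#' @export
colony_dataset <- function(traces, condition = "+LIF", perturbation = NULL) {
  if (!length(traces)) stop_invalid("dataset must contain at least one trace")
  names(traces) <- vapply(traces, function(tr) {
    paste(tr$colony_id, tr$cell_id, sep = "/")
  }, character(1))
  if (anyDuplicated(names(traces))) {
    stop_invalid("duplicate (colony_id, cell_id) in dataset")
  }
  structure(list(traces = traces, condition = condition,
                 perturbation = perturbation),
            class = "colony_dataset")
}

#' @export
print.colony_dataset <- function(x, ...) {
  cols <- unique(vapply(x$traces, `[[`, character(1), "colony_id"))
  cat(sprintf("<colony_dataset> %d traces in %d colon%s, condition %s\n",
              length(x$traces), length(cols),
              if (length(cols) == 1L) "y" else "ies", x$condition))
  invisible(x)
}

#' @export
length.colony_dataset <- function(x) length(x$traces)

#' @export
as.data.frame.colony_dataset <- function(x, ...) {
  has_ch <- all(vapply(x$traces, function(tr) !is.null(tr$cfp) && !is.null(tr$yfp),
                       logical(1)))
  rows <- lapply(x$traces, function(tr) {
    df <- data.frame(colony_id = tr$colony_id, cell_id = tr$cell_id,
                     frame = tr$frame, time_min = tr$time_min,
                     ratio = tr$ratio, stringsAsFactors = FALSE)
    if (has_ch) {
      df$cfp <- tr$cfp
      df$yfp <- tr$yfp
    }
    df
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$colony_id, out$cell_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a long-format trace table
#'
#' Expects a CSV with header columns `colony_id, cell_id, frame, ratio`
#' and optionally `cfp`, `yfp` (and `time_min`, which is recomputed from
#' the frame index). One trace is built per `(colony_id, cell_id)`;
#' frames are sorted and missing frames remain gaps.
#'
#' @param path path to the CSV file.
#' @param condition condition label to attach; defaults to `"+LIF"`.
#' @return A [colony_dataset()].
#' @export
read_traces <- function(path, condition = "+LIF") {
  if (!file.exists(path)) stop_format(sprintf("no such file: %s", path))
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = TRUE, strip.white = TRUE)
  need <- c("colony_id", "cell_id", "frame", "ratio")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop_format(sprintf("missing required column(s): %s",
                        paste(miss, collapse = ", ")))
  }
  if (nrow(raw) == 0L) stop_format("trace file contains no data rows")

  num_col <- function(col) {
    v <- raw[[col]]
    v[v == ""] <- NA_character_
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad)) {
      stop_format(sprintf("non-numeric %s value '%s' at data row %d",
                          col, v[bad[1]], bad[1]))
    }
    out
  }
  frame <- num_col("frame")
  if (anyNA(frame)) stop_format("missing frame index in trace file")
  ratio <- num_col("ratio")
  cfp <- if ("cfp" %in% names(raw)) num_col("cfp") else NULL
  yfp <- if ("yfp" %in% names(raw)) num_col("yfp") else NULL

  key <- paste(raw$colony_id, raw$cell_id, sep = "/")
  dup <- duplicated(paste(key, frame))
  if (any(dup)) {
    i <- which(dup)[1]
    stop_format(sprintf("duplicate frame %d for cell %s", frame[i], key[i]))
  }

  traces <- lapply(split(seq_len(nrow(raw)), key), function(idx) {
    ord <- idx[order(frame[idx])]
    new_trace(cell_id = raw$cell_id[ord[1]], colony_id = raw$colony_id[ord[1]],
              frame = frame[ord], ratio = ratio[ord],
              cfp = if (is.null(cfp)) NULL else cfp[ord],
              yfp = if (is.null(yfp)) NULL else yfp[ord])
  })
  colony_dataset(traces, condition = condition)
}

#' Write a colony dataset as a long-format CSV
#'
#' The inverse of [read_traces()]: columns
#' `colony_id,cell_id,frame,time_min,ratio[,cfp,yfp]`, sorted by colony,
#' cell and frame, with numeric fields printed at full double precision
#' so that a write/read round trip is lossless.
#'
#' @param dataset a [colony_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(dataset, path) {
  if (!inherits(dataset, "colony_dataset") || !length(dataset$traces)) {
    stop_invalid("write_traces requires a non-empty colony_dataset")
  }
  df <- as.data.frame(dataset)
  for (col in intersect(c("ratio", "cfp", "yfp"), names(df))) {
    v <- df[[col]]
    s <- sprintf("%.17g", v)
    s[is.na(v)] <- ""
    df[[col]] <- s
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Compute a FRET/CFP ratio series from raw channel intensities
#'
#' Elementwise acceptor/donor division with a guard against near-zero
#' donor intensity: frames where the CFP signal falls below
#' `min_intensity` (for example during a cell division, when both
#' channels collapse) are marked missing rather than producing an
#' unbounded ratio.
#'
#' @param cfp donor (CFP) intensity series.
#' @param yfp acceptor (FRET/YFP) intensity series, same length.
#' @param min_intensity minimum usable CFP intensity; defaults to 1% of
#'   the median CFP signal.
#' @return Numeric ratio series, `NA` where undefined; never non-finite.
#' @export
compute_ratio <- function(cfp, yfp, min_intensity = NULL) {
  if (length(cfp) != length(yfp)) {
    stop_invalid("cfp and yfp must have equal length")
  }
  if (is.null(min_intensity)) {
    min_intensity <- 0.01 * stats::median(cfp, na.rm = TRUE)
  }
  ok <- !is.na(cfp) & !is.na(yfp) & cfp >= min_intensity
  out <- rep(NA_real_, length(cfp))
  out[ok] <- yfp[ok] / cfp[ok]
  out[!is.finite(out)] <- NA_real_
  out
}
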