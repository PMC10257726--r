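#' Classify a cell as active, inactive, unclassifiable or excluded
#'
#' Duration-based rules: a cell observed for at least
#' `active_min_min` minutes (default 120) showing at least `min_pulses`
#' pulses is *active*; a cell observed for at least `inactive_min_min`
#' minutes (default 160) with no pulses is *inactive*; QC-excluded
#' cells (divisions) are *excluded* outright; anything else — too short
#' a recording to qualify either way — is *unclassifiable*. Observed
#' duration is 3 min times the number of non-missing ratio samples.
#'
#' @param trace an [new_trace()] object.
#' @param pulses peak table for this cell (any data frame with a
#'   `peak_frame` column; row count is what matters).
#' @param qc optional QC row from [flag_division()].
#' @param min_pulses pulses required for "active" (default 1).
#' @param active_min_min,inactive_min_min minimum observed minutes for
#'   the active and inactive rules.
#' @return One-row data frame: `cell_id`, `status`, `n_pulses`,
#'   `observed_min`.
#' @export
classify_cell <- function(trace, pulses, qc = NULL, min_pulses = 1L,
                          active_min_min = 120, inactive_min_min = 160) {
  n_pulses <- if (is.null(pulses)) 0L else nrow(pulses)
  observed_min <- FRAME_INTERVAL_MIN * trace$observed_frames
  status <- if (!is.null(qc) && isTRUE(qc$excluded[1])) {
    "excluded"
  } else if (n_pulses >= min_pulses && observed_min >= active_min_min) {
    "active"
  } else if (n_pulses == 0L && observed_min >= inactive_min_min) {
    "inactive"
  } else {
    "unclassifiable"
  }
  data.frame(cell_id = trace$cell_id, status = status,
             n_pulses = n_pulses, observed_min = observed_min,
             stringsAsFactors = FALSE)
}

#' Classify every cell in a dataset
#'
#' @param dataset a [colony_dataset()].
#' @param peaks colony-wide peak table from [detect_pulses()].
#' @param qc QC table from [qc_dataset()], or `NULL` to skip exclusion.
#' @param ... passed to [classify_cell()].
#' @return Data frame with one row per cell, plus `colony_id`.
#' @export
classify_cells <- function(dataset, peaks, qc = NULL, ...) {
  rows <- lapply(dataset$traces, function(tr) {
    pk <- peaks[peaks$colony_id == tr$colony_id &
                  peaks$cell_id == tr$cell_id, , drop = FALSE]
    qr <- if (is.null(qc)) NULL else {
      qc[qc$colony_id == tr$colony_id & qc$cell_id == tr$cell_id, ,
         drop = FALSE]
    }
    cbind(colony_id = tr$colony_id,
          classify_cell(tr, pk, qr, ...), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise active/inactive composition of a colony
#'
#' Either pass the per-cell status table, or raw counts directly (as
#' when reproducing published active/inactive ratios). The percentage
#' active is computed among classified cells only
#' (`100 * n_active / (n_active + n_inactive)`) and reported at two
#' precisions, integer and one decimal, both rounded half-up (10/6
#' active/inactive gives 62.5 -> 63%).
#'
#' @param statuses status table from [classify_cells()], or `NULL`.
#' @param n_active,n_inactive direct counts (used when `statuses` is
#'   `NULL`).
#' @param colony_id label for the output row.
#' @return One-row data frame: counts by status, `pct_active`
#'   (one-decimal) and `pct_active_int`.
#' @export
summarize_colony <- function(statuses = NULL, n_active = NULL,
                             n_inactive = NULL, colony_id = NA_character_) {
  if (!is.null(statuses)) {
    if (!nrow(statuses)) stop_invalid("no cells to summarise")
    if (!is.na(colony_id)) {
      statuses <- statuses[statuses$colony_id == colony_id, , drop = FALSE]
    }
    n_active <- sum(statuses$status == "active")
    n_inactive <- sum(statuses$status == "inactive")
    n_uncl <- sum(statuses$status == "unclassifiable")
    n_excl <- sum(statuses$status == "excluded")
  } else {
    if (is.null(n_active) || is.null(n_inactive)) {
      stop_invalid("supply either statuses or n_active and n_inactive")
    }
    n_uncl <- 0L
    n_excl <- 0L
  }
  n_cls <- n_active + n_inactive
  pct <- if (n_cls > 0) 100 * n_active / n_cls else NA_real_
  data.frame(colony_id = colony_id,
             n_active = n_active, n_inactive = n_inactive,
             n_unclassifiable = n_uncl, n_excluded = n_excl,
             pct_active = round_half_up(pct, 1L),
             pct_active_int = round_half_up(pct, 0L),
             stringsAsFactors = FALSE)
}

#' Summarise every colony in a status table
#'
#' @param statuses status table from [classify_cells()].
#' @return Data frame with one row per colony.
#' @export
summarize_colonies <- function(statuses) {
  out <- do.call(rbind, lapply(unique(statuses$colony_id), function(cid) {
    summarize_colony(statuses, colony_id = cid)
  }))
  rownames(out) <- NULL
  out
}
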