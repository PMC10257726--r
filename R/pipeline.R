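#' Read a simulation/analysis configuration file
#'
#' Configurations are plain JSON mirroring [sim_colony_config()] (with a
#' nested `perturbation` object) plus optional analysis settings
#' (`detector`, `sync`, `boundary_frame`). Every field is optional and
#' falls back to the package defaults.
#'
#' @param path path to a JSON config file.
#' @return Named list of raw settings.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("no such config file: %s", path))
  tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
           error = function(e) stop_config(
             sprintf("cannot parse config %s: %s", path, conditionMessage(e))))
}

resolve_sim_config <- function(cfg, seed = NULL) {
  pert_args <- cfg$perturbation
  pert <- if (is.null(pert_args)) {
    perturbation_spec("none")
  } else if (inherits(pert_args, "perturbation_spec")) {
    pert_args
  } else {
    do.call(perturbation_spec, as.list(pert_args))
  }
  known <- setdiff(names(formals(sim_colony_config)), "perturbation")
  args <- cfg[intersect(names(cfg), known)]
  args$perturbation <- pert
  if (!is.null(seed)) args$seed <- seed
  bad <- setdiff(names(cfg), c(known, "perturbation", "detector", "sync",
                               "boundary_frame"))
  if (length(bad)) {
    stop_config(sprintf("unknown config field(s): %s",
                        paste(bad, collapse = ", ")))
  }
  do.call(sim_colony_config, args)
}

write_csv_out <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Simulate a colony and write its files
#'
#' Writes `traces.csv` (long-format trace table), `ground_truth.csv`
#' and `config_resolved.json` (every default made explicit) under
#' `out_dir`. Deterministic per seed.
#'
#' @param config a [sim_colony_config()], or the path to a JSON config.
#' @param out_dir output directory (created if needed).
#' @param seed optional seed overriding the config's.
#' @return Invisibly, a named list of the written paths.
#' @export
run_simulate <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- resolve_sim_config(read_config(config),
                                                         seed)
  if (!inherits(config, "sim_colony_config")) {
    config <- resolve_sim_config(config, seed)
  } else if (!is.null(seed)) {
    config$seed <- as.integer(seed)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_colony(config)
  paths <- list(
    traces = file.path(out_dir, "traces.csv"),
    ground_truth = file.path(out_dir, "ground_truth.csv"),
    config = file.path(out_dir, "config_resolved.json"))
  write_traces(sim$dataset, paths$traces)
  write_csv_out(sim$truth, paths$ground_truth)
  jsonlite::write_json(unclass_deep(config), paths$config, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  message(sprintf("simulate: %d cells x %d frames -> %s",
                  config$n_cells, config$duration_frames, out_dir))
  invisible(paths)
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_deep)
  } else {
    x
  }
}

#' Run the full analysis pipeline on a trace table
#'
#' Orchestrates QC -> pulse detection -> classification -> colony
#' summaries -> frequency/perturbation statistics -> synchrony, writing
#' one file per stage plus a run manifest under `out_dir`:
#' `qc.csv`, `peaks.csv`, `episodes.csv`, `cell_status.csv`,
#' `colony_summary.csv`, `stats.json`, `sync_pairs.csv`,
#' `sync_groups.csv`, `manifest.json`. Stage record counts are logged
#' to stderr. Re-running on the same input and config is byte-identical
#' (the pipeline itself is deterministic).
#'
#' @param traces a [colony_dataset()] or the path to a trace CSV.
#' @param out_dir output directory.
#' @param config optional list (or JSON path) with `detector`, `sync`
#'   and `boundary_frame` settings.
#' @return Invisibly, a list with every stage's in-memory result.
#' @export
run_analyze <- function(traces, out_dir, config = list()) {
  if (is.character(config)) config <- read_config(config)
  dataset <- if (is.character(traces)) read_traces(traces) else traces
  if (!inherits(dataset, "colony_dataset")) {
    stop_format("traces must be a colony_dataset or a CSV path")
  }
  det_cfg <- do.call(detector_config, as.list(config$detector %||% list()))
  sy_cfg <- do.call(sync_config, as.list(config$sync %||% list()))
  boundary <- config$boundary_frame %||% 40L
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  qc <- qc_dataset(dataset)
  message(sprintf("qc: %d cells, %d excluded", nrow(qc), sum(qc$excluded)))
  det <- detect_pulses(dataset, det_cfg)
  message(sprintf("detect: %d peaks, %d episodes",
                  nrow(det$peaks), nrow(det$episodes)))
  statuses <- classify_cells(dataset, det$peaks, qc)
  message(sprintf("classify: %d active / %d inactive / %d unclassifiable / %d excluded",
                  sum(statuses$status == "active"),
                  sum(statuses$status == "inactive"),
                  sum(statuses$status == "unclassifiable"),
                  sum(statuses$status == "excluded")))
  summaries <- summarize_colonies(statuses)

  n_frames <- max(vapply(dataset$traces, function(tr) max(tr$frame),
                         integer(1)))
  act <- statuses[statuses$status == "active", , drop = FALSE]
  act_keys <- paste(act$colony_id, act$cell_id, sep = "/")
  freq <- pulse_frequency(det$peaks,
                          c(1L, min(40L, n_frames)), act_keys)
  stats_out <- list(
    n_cells = nrow(statuses),
    mean_pulses_per_hour_active_first_window =
      if (nrow(freq)) mean(freq$pulses_per_hour) else NA)
  if (n_frames > boundary && nrow(act) >= 2L) {
    pt <- perturbation_table(det$peaks, statuses, boundary, n_frames)
    bt <- before_after_test(pt$before_per_hour, pt$after_per_hour)
    stats_out$before_after <- unclass(bt)
    stats_out$before_after_table <- pt
  }
  ipi <- tryCatch(fit_ipi_exponential(det$peaks), error = function(e) NULL)
  if (!is.null(ipi)) {
    stats_out$ipi <- ipi[c("n_intervals", "mean_ipi_min", "rate_per_hour",
                           "ks_statistic", "ks_p")]
  }

  sync_by_colony <- lapply(unique(statuses$colony_id), function(cid) {
    sub <- dataset$traces[vapply(dataset$traces, function(tr) {
      tr$colony_id == cid
    }, logical(1))]
    pairwise_sync(structure(list(traces = sub, condition = dataset$condition),
                            class = "colony_dataset"),
                  statuses, sy_cfg)
  })
  sync_pairs <- do.call(rbind, lapply(sync_by_colony, `[[`, "pairs"))
  sync_groups <- do.call(rbind, lapply(seq_along(sync_by_colony), function(i) {
    g <- sync_by_colony[[i]]$groups
    if (nrow(g)) cbind(colony_id = unique(statuses$colony_id)[i], g,
                       stringsAsFactors = FALSE) else NULL
  }))
  if (is.null(sync_groups)) {
    sync_groups <- data.frame(colony_id = character(0), group_id = integer(0),
                              cell_id = character(0))
  }
  message(sprintf("synchrony: %d pairs, %d strong", nrow(sync_pairs),
                  sum(sync_pairs$is_strong)))

  write_csv_out(qc, file.path(out_dir, "qc.csv"))
  write_csv_out(det$peaks, file.path(out_dir, "peaks.csv"))
  write_csv_out(det$episodes, file.path(out_dir, "episodes.csv"))
  write_csv_out(statuses, file.path(out_dir, "cell_status.csv"))
  write_csv_out(summaries, file.path(out_dir, "colony_summary.csv"))
  jsonlite::write_json(stats_out, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", null = "null", na = "null")
  write_csv_out(sync_pairs, file.path(out_dir, "sync_pairs.csv"))
  write_csv_out(sync_groups, file.path(out_dir, "sync_groups.csv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("erkpulse")),
    detector = unclass(det_cfg), sync = unclass(sy_cfg),
    boundary_frame = boundary,
    counts = list(cells = nrow(statuses), peaks = nrow(det$peaks),
                  episodes = nrow(det$episodes),
                  sync_pairs = nrow(sync_pairs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(qc = qc, peaks = det$peaks, episodes = det$episodes,
                 statuses = statuses, summaries = summaries,
                 stats = stats_out, sync_pairs = sync_pairs,
                 sync_groups = sync_groups))
}

#' Print a human-readable summary of an analysis bundle
#'
#' @param bundle_dir directory written by [run_analyze()].
#' @return Invisibly, the parsed manifest.
#' @export
run_report <- function(bundle_dir) {
  man_path <- file.path(bundle_dir, "manifest.json")
  if (!file.exists(man_path)) {
    stop_format(sprintf("no manifest.json in %s", bundle_dir))
  }
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  cat(sprintf("analysis bundle %s (erkpulse %s)\n", bundle_dir,
              man$package_version))
  cat(sprintf("  cells: %d, peaks: %d, episodes: %d, sync pairs: %d\n",
              man$counts$cells, man$counts$peaks, man$counts$episodes,
              man$counts$sync_pairs))
  summ <- utils::read.csv(file.path(bundle_dir, "colony_summary.csv"))
  for (i in seq_len(nrow(summ))) {
    cat(sprintf("  %s: %d active / %d inactive (%.1f%% active)\n",
                summ$colony_id[i], summ$n_active[i], summ$n_inactive[i],
                summ$pct_active[i]))
  }
  invisible(man)
}

cli_opts <- function(args) {
  out <- list(positional = character(0))
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i == length(args) || startsWith(args[i + 1L], "--")) {
        out[[key]] <- TRUE
        i <- i + 1L
      } else {
        out[[key]] <- args[i + 1L]
        i <- i + 2L
      }
    } else {
      out$positional <- c(out$positional, a)
      i <- i + 1L
    }
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `simulate --config FILE --out DIR [--seed N]`,
#' `analyze --traces FILE [--config FILE] --out DIR`, and
#' `report --bundle DIR`. Exit codes: 0 on success, 2 for data/format
#' errors, 3 for configuration errors. Run via
#' `Rscript -e 'quit(status = erkpulse::pulse_cli())' simulate ...`.
#'
#' @param args character vector of CLI arguments; defaults to the
#'   process arguments.
#' @return Integer exit status, invisibly.
#' @export
pulse_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args)) {
      stop_config("usage: simulate|analyze|report [--options]")
    }
    cmd <- args[1]
    opt <- cli_opts(args[-1])
    switch(cmd,
      simulate = {
        if (is.null(opt$config) || is.null(opt$out)) {
          stop_config("simulate requires --config FILE and --out DIR")
        }
        run_simulate(opt$config, opt$out,
                     seed = if (is.null(opt$seed)) NULL else
                       as.integer(opt$seed))
      },
      analyze = {
        if (is.null(opt$traces) || is.null(opt$out)) {
          stop_config("analyze requires --traces FILE and --out DIR")
        }
        run_analyze(opt$traces, opt$out, config = opt$config %||% list())
      },
      report = {
        if (is.null(opt$bundle)) stop_config("report requires --bundle DIR")
        run_report(opt$bundle)
      },
      stop_config(sprintf("unknown subcommand '%s'", cmd)))
    0L
  },
  erkpulse_format_error = function(e) {
    message("format error: ", conditionMessage(e))
    2L
  },
  erkpulse_config_error = function(e) {
    message("config error: ", conditionMessage(e))
    3L
  },
  error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
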