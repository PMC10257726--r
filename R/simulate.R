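#' Perturbation specification
#'
#' Describes a pharmacological perturbation applied between two frames
#' (default between frames 40 and 41, i.e. at 120 min). Each kind sets a
#' regime for pulse generation after the boundary:
#'
#' * `mek_inhibitor` — pulse generation abolished and the baseline ratio
#'   shifted down (default by 0.10), since basal ERK activity is also
#'   MEK-dependent.
#' * `fgfr_inhibitor` — pulse generation abolished, baseline unchanged.
#' * `egfr_inhibitor` — no effect.
#' * `fgf4` — excess ligand; pulse rate multiplied by `rate_multiplier`
#'   (default 2) in maintenance (+LIF) conditions, no effect in -LIF.
#' * `raf_inhibitor` — ordinary pulse generation stops and, after a
#'   delay (default 60 min), a single wide (18--20 min FWHM) pulse fires
#'   simultaneously in every cell, active and inactive alike
#'   (paradoxical Raf activation).
#'
#' @param kind one of `"none"`, `"mek_inhibitor"`, `"fgfr_inhibitor"`,
#'   `"egfr_inhibitor"`, `"fgf4"`, `"raf_inhibitor"`.
#' @param applied_after_frame last pre-perturbation frame (>= 1).
#' @param rate_multiplier post-boundary multiplier on the pulse rate;
#'   kind-specific default.
#' @param baseline_shift additive shift of the baseline ratio after the
#'   boundary; default -0.10 for `mek_inhibitor`, else 0.
#' @param wide_pulse_delay_min delay of the Raf-induced wide pulse after
#'   the boundary, minutes.
#' @param wide_pulse_width_range FWHM range (min) for the wide pulse;
#'   drawn uniformly per cell.
#' @param wide_pulse_amplitude amplitude of the wide pulse above
#'   baseline, ratio units. The default 0.30 places the detection
#'   threshold (1.2, with baseline 1.05) exactly at half maximum, so the
#'   suprathreshold episode lasts as long as the pulse's FWHM.
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(kind = c("none", "mek_inhibitor", "fgfr_inhibitor",
                                       "egfr_inhibitor", "fgf4", "raf_inhibitor"),
                              applied_after_frame = 40L,
                              rate_multiplier = NULL,
                              baseline_shift = NULL,
                              wide_pulse_delay_min = 60,
                              wide_pulse_width_range = c(18, 20),
                              wide_pulse_amplitude = 0.30) {
  kind <- match.arg(kind)
  applied_after_frame <- as.integer(applied_after_frame)
  if (is.na(applied_after_frame) || applied_after_frame < 1L) {
    stop_config("applied_after_frame must be >= 1")
  }
  if (is.null(rate_multiplier)) {
    rate_multiplier <- switch(kind,
      none = 1, egfr_inhibitor = 1, fgf4 = 2,
      mek_inhibitor = 0, fgfr_inhibitor = 0, raf_inhibitor = 0)
  }
  if (is.null(baseline_shift)) {
    baseline_shift <- if (kind == "mek_inhibitor") -0.10 else 0
  }
  if (kind == "raf_inhibitor") {
    if (length(wide_pulse_width_range) != 2L ||
        wide_pulse_width_range[1] > wide_pulse_width_range[2] ||
        wide_pulse_width_range[1] <= 0) {
      stop_config("wide_pulse_width_range must be a valid positive range")
    }
  }
  structure(list(kind = kind,
                 applied_after_frame = applied_after_frame,
                 rate_multiplier = rate_multiplier,
                 baseline_shift = baseline_shift,
                 wide_pulse_delay_min = wide_pulse_delay_min,
                 wide_pulse_width_range = wide_pulse_width_range,
                 wide_pulse_amplitude = wide_pulse_amplitude),
            class = "perturbation_spec")
}

#' Colony simulation configuration
#'
#' Bundles every tunable of the synthetic-trace generator. Defaults state
#' the conditions the analysis assumes: an active/inactive mixture
#' (55.3% active in +LIF, 43.5% in -LIF), Poisson pulse generation in
#' active cells at 0.69 (+LIF) or 0.81 (-LIF) pulses/hour, ~10-min-wide
#' Gaussian pulses of amplitude 0.2--0.4 above a baseline of 1.05,
#' Gaussian measurement noise (sd 0.02), 80 frames at 3 min/frame
#' (240 min), and an optional perturbation applied after frame 40.
#'
#' @param n_cells number of cells in the colony.
#' @param condition `"+LIF"` or `"-LIF"`; sets the defaults of
#'   `frac_active` and `lambda_active`.
#' @param frac_active fraction of truly pulsing cells.
#' @param lambda_active target *detected* pulse frequency of active
#'   cells, pulses/hour. The detector's minimum-peak-distance rule
#'   merges pulses closer than `mpd + 1` frames, so the generator draws
#'   latent pulse trains at the dead-time-inverted rate
#'   `lambda / (1 - lambda * dead_time_min / 60)`; see
#'   `dead_time_min`.
#' @param dead_time_min effective detector dead time in minutes used
#'   for the latent-rate inversion; default 12 min = (mpd + 1) frames
#'   at the default mpd of 3. Set to 0 to make `lambda_active` the
#'   latent rate itself.
#' @param duration_frames recording length in frames.
#' @param frame_interval_min sampling interval; fixed at 3 min.
#' @param baseline baseline ratio of every cell.
#' @param amp_range range for per-pulse amplitudes (uniform draw), ratio
#'   units above baseline.
#' @param pulse_width_min pulse full width at half maximum, minutes.
#' @param noise_sigma sd of i.i.d. Gaussian measurement noise, ratio
#'   units.
#' @param trigger_groups list of shared-trigger groups, each a list with
#'   `n_members`, `rate_per_hour` and `fire_prob` (default 1): a
#'   colony-level Poisson event stream whose events are added, with no
#'   time lag, to each firing member's private pulse train. Members are
#'   taken from the active cells.
#' @param frac_dividing fraction of cells that undergo a division event
#'   (both channels halved for two frames; ratio depressed by 0.1).
#' @param perturbation a [perturbation_spec()].
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param colony_id colony label.
#' @return An object of class `sim_colony_config`.
#' @export
sim_colony_config <- function(n_cells,
                              condition = c("+LIF", "-LIF"),
                              frac_active = NULL,
                              lambda_active = NULL,
                              dead_time_min = 12,
                              duration_frames = 80L,
                              frame_interval_min = 3,
                              baseline = 1.05,
                              amp_range = c(0.2, 0.4),
                              pulse_width_min = 10,
                              noise_sigma = 0.02,
                              trigger_groups = list(),
                              frac_dividing = 0,
                              perturbation = perturbation_spec("none"),
                              seed = 1L,
                              colony_id = "colony1") {
  condition <- match.arg(condition)
  if (is.null(frac_active)) {
    frac_active <- if (condition == "+LIF") 0.553 else 0.435
  }
  if (is.null(lambda_active)) {
    lambda_active <- if (condition == "+LIF") 0.69 else 0.81
  }
  n_cells <- as.integer(n_cells)
  duration_frames <- as.integer(duration_frames)
  if (is.na(n_cells) || n_cells < 1L) stop_config("n_cells must be >= 1")
  if (frac_active < 0 || frac_active > 1) {
    stop_config("frac_active must lie in [0, 1]")
  }
  if (duration_frames < 1L) stop_config("duration_frames must be >= 1")
  if (frame_interval_min != FRAME_INTERVAL_MIN) {
    stop_config("frame_interval_min is fixed at 3 min")
  }
  if (lambda_active < 0) stop_config("lambda_active must be >= 0")
  if (dead_time_min < 0 || lambda_active * dead_time_min / 60 >= 1) {
    stop_config("dead_time_min must be >= 0 and < 60/lambda_active")
  }
  lambda_latent <- lambda_active / (1 - lambda_active * dead_time_min / 60)
  if (pulse_width_min <= 0) stop_config("pulse_width_min must be > 0")
  if (noise_sigma < 0) stop_config("noise_sigma must be >= 0")
  if (!inherits(perturbation, "perturbation_spec")) {
    stop_config("perturbation must be a perturbation_spec")
  }
  n_active <- as.integer(round_half_up(n_cells * frac_active))
  for (g in trigger_groups) {
    if (is.null(g$n_members) || is.null(g$rate_per_hour)) {
      stop_config("each trigger group needs n_members and rate_per_hour")
    }
  }
  n_grouped <- sum(vapply(trigger_groups, function(g) as.integer(g$n_members),
                          integer(1)))
  if (n_grouped > n_active) {
    stop_config(sprintf(
      "trigger groups require %d active cells but only %d are active",
      n_grouped, n_active))
  }
  structure(list(n_cells = n_cells, condition = condition,
                 frac_active = frac_active, lambda_active = lambda_active,
                 dead_time_min = dead_time_min, lambda_latent = lambda_latent,
                 duration_frames = duration_frames,
                 frame_interval_min = frame_interval_min,
                 baseline = baseline, amp_range = amp_range,
                 pulse_width_min = pulse_width_min, noise_sigma = noise_sigma,
                 trigger_groups = trigger_groups,
                 frac_dividing = frac_dividing,
                 perturbation = perturbation,
                 seed = as.integer(seed), colony_id = colony_id),
            class = "sim_colony_config")
}

#' Draw pulse times from a homogeneous Poisson process
#'
#' Successive inter-pulse gaps are i.i.d. Exponential(rate), giving the
#' exponential inter-pulse-interval distribution characteristic of
#' stochastic (memoryless) pulse generation.
#'
#' @param rate_per_hour event rate, pulses/hour (>= 0).
#' @param duration_min observation window length in minutes (>= 0).
#' @param rng_seed optional integer seed; when supplied, the caller's
#'   RNG state is left untouched.
#' @return Strictly increasing numeric vector of event times (minutes)
#'   in `[0, duration_min)`; empty for a zero rate or empty window.
#' @export
draw_pulse_times <- function(rate_per_hour, duration_min, rng_seed = NULL) {
  if (rate_per_hour < 0) stop_invalid("rate_per_hour must be >= 0")
  if (duration_min < 0) stop_invalid("duration_min must be >= 0")
  if (rate_per_hour == 0 || duration_min == 0) return(numeric(0))
  rate_min <- rate_per_hour / 60
  with_seed(rng_seed, {
    mu <- rate_min * duration_min
    gaps <- stats::rexp(max(8L, ceiling(mu + 6 * sqrt(mu) + 4)), rate_min)
    while (sum(gaps) <= duration_min) {
      gaps <- c(gaps, stats::rexp(max(8L, length(gaps)), rate_min))
    }
    tt <- cumsum(gaps)
    tt[tt < duration_min]
  })
}

# Sum of Gaussian pulse kernels evaluated at times t (minutes).
# widths are FWHMs; the kernel peaks at exactly `amplitude` at its
# pulse time.
pulse_kernel_sum <- function(t, pulse_times, amplitudes, widths) {
  if (!length(pulse_times)) return(rep(0, length(t)))
  widths <- rep_len(widths, length(pulse_times))
  amplitudes <- rep_len(amplitudes, length(pulse_times))
  sig <- widths / FWHM_CONST
  out <- rep(0, length(t))
  for (i in seq_along(pulse_times)) {
    out <- out + amplitudes[i] * exp(-((t - pulse_times[i])^2) / (2 * sig[i]^2))
  }
  out
}

#' Render a ratio trace from pulse times
#'
#' The trace model: baseline + a sum of unimodal Gaussian pulse kernels
#' (parameterised by FWHM; kernel maximum = baseline + amplitude at the
#' pulse time) + i.i.d. Gaussian noise, sampled every 3 minutes on the
#' 1-based frame grid (frame T is at 3T minutes).
#'
#' @param baseline baseline ratio (scalar, or one value per frame).
#' @param pulse_times pulse centre times in minutes.
#' @param amplitudes per-pulse amplitudes above baseline (recycled).
#' @param width per-pulse FWHM in minutes (recycled); must be > 0.
#' @param noise_sigma sd of additive Gaussian noise; 0 for noiseless.
#' @param duration_frames number of frames (>= 1).
#' @param rng_seed optional seed for the noise draw.
#' @param cell_id,colony_id labels for the returned trace.
#' @return An [new_trace()] object of length `duration_frames`.
#' @export
render_trace <- function(baseline, pulse_times = numeric(0),
                         amplitudes = numeric(0), width = 10,
                         noise_sigma = 0, duration_frames = 80L,
                         rng_seed = NULL, cell_id = "cell", colony_id = "sim") {
  duration_frames <- as.integer(duration_frames)
  if (is.na(duration_frames) || duration_frames < 1L) {
    stop_invalid("duration_frames must be >= 1")
  }
  if (any(width <= 0)) stop_invalid("pulse width must be > 0")
  frames <- seq_len(duration_frames)
  t <- FRAME_INTERVAL_MIN * frames
  signal <- rep_len(baseline, duration_frames) +
    pulse_kernel_sum(t, pulse_times, amplitudes, width)
  if (noise_sigma > 0) {
    signal <- signal + with_seed(rng_seed,
                                 stats::rnorm(duration_frames, 0, noise_sigma))
  }
  new_trace(cell_id = cell_id, colony_id = colony_id,
            frame = frames, ratio = signal)
}

# Split a Poisson draw at the perturbation boundary, applying the
# post-boundary rate multiplier.
draw_piecewise_pulses <- function(rate, duration_min, boundary_min, mult, seed) {
  if (is.null(boundary_min) || boundary_min >= duration_min || mult == 1) {
    return(draw_pulse_times(rate, duration_min, seed))
  }
  before <- draw_pulse_times(rate, boundary_min, seed)
  after <- boundary_min +
    draw_pulse_times(rate * mult, duration_min - boundary_min,
                     derive_seed(seed, "after"))
  c(before, after)
}

#' Simulate a colony of pulsatile ratio traces with known ground truth
#'
#' Generates `n_cells` traces under the stated configuration: an
#' active/inactive mixture, private Poisson pulse trains in active
#' cells, optional shared-trigger groups producing zero-lag synchronised
#' pulses, optional division events, and one of the five perturbation
#' regimes. Raw CFP/YFP channels are emitted (CFP ~ 1000 with 1%
#' multiplicative noise; YFP = ratio x CFP) so channel-based QC is
#' exercisable. Per-cell RNG substreams are derived by stable hashing of
#' `(seed, colony_id, cell_id)`, so the same seed reproduces the colony
#' bit-for-bit and adding a cell does not perturb the others.
#'
#' @param config a [sim_colony_config()].
#' @return A list with elements `dataset` (a [colony_dataset()]) and
#'   `truth` (a data frame with one row per cell: `cell_id`,
#'   `true_active`, `true_pulse_times` as semicolon-joined minutes,
#'   `trigger_group`, `division_frame`).
#' @export
simulate_colony <- function(config) {
  if (!inherits(config, "sim_colony_config")) {
    stop_config("config must be a sim_colony_config")
  }
  pert <- config$perturbation
  n <- config$n_cells
  duration_min <- config$duration_frames * FRAME_INTERVAL_MIN
  boundary_min <- if (pert$kind == "none") NULL else {
    pert$applied_after_frame * FRAME_INTERVAL_MIN
  }
  if (!is.null(boundary_min) && boundary_min >= duration_min) {
    stop_config("perturbation boundary lies outside the recording")
  }
  # excess FGF4 raises the pulse rate only under +LIF
  eff_mult <- if (pert$kind == "fgf4" && config$condition == "-LIF") {
    1
  } else {
    pert$rate_multiplier
  }

  cell_ids <- sprintf("cell%03d", seq_len(n))
  n_active <- as.integer(round_half_up(n * config$frac_active))
  colony_seed <- derive_seed(config$seed, config$colony_id, "colony")
  active_idx <- with_seed(colony_seed, sort(sample.int(n, n_active)))
  is_active <- seq_len(n) %in% active_idx

  # trigger groups claim active cells in order; events are a colony-level
  # Poisson stream subject to the same perturbation regime
  group_of <- rep(NA_character_, n)
  group_events <- list()
  taken <- 0L
  for (gi in seq_along(config$trigger_groups)) {
    g <- config$trigger_groups[[gi]]
    gname <- g$name %||% sprintf("group%d", gi)
    members <- active_idx[seq.int(taken + 1L, taken + g$n_members)]
    taken <- taken + as.integer(g$n_members)
    group_of[members] <- gname
    group_events[[gname]] <- list(
      times = draw_piecewise_pulses(g$rate_per_hour, duration_min,
                                    boundary_min, eff_mult,
                                    derive_seed(config$seed, config$colony_id,
                                                "trigger", gname)),
      fire_prob = g$fire_prob %||% 1)
  }

  # Raf regime: one synchronised wide pulse in every cell after a delay
  wide_time <- if (pert$kind == "raf_inhibitor") {
    boundary_min + pert$wide_pulse_delay_min
  } else NULL

  frames <- seq_len(config$duration_frames)
  t_grid <- FRAME_INTERVAL_MIN * frames
  baseline_vec <- rep(config$baseline, config$duration_frames)
  if (!is.null(boundary_min) && pert$baseline_shift != 0) {
    baseline_vec[frames > pert$applied_after_frame] <-
      config$baseline + pert$baseline_shift
  }

  traces <- vector("list", n)
  truth <- data.frame(cell_id = cell_ids, true_active = is_active,
                      true_pulse_times = NA_character_,
                      trigger_group = group_of,
                      division_frame = NA_integer_,
                      stringsAsFactors = FALSE)

  for (i in seq_len(n)) {
    cseed <- derive_seed(config$seed, config$colony_id, cell_ids[i])
    lambda <- if (is_active[i]) config$lambda_latent else 0
    times <- draw_piecewise_pulses(lambda, duration_min, boundary_min,
                                   eff_mult, cseed)
    res <- with_seed(derive_seed(cseed, "cellrng"), {
      if (!is.na(group_of[i])) {
        ge <- group_events[[group_of[i]]]
        fired <- ge$times[stats::runif(length(ge$times)) <= ge$fire_prob]
        times <- sort(c(times, fired))
      }
      widths <- rep(config$pulse_width_min, length(times))
      amps <- stats::runif(length(times), config$amp_range[1],
                           config$amp_range[2])
      if (!is.null(wide_time)) {
        times <- c(times, wide_time)
        widths <- c(widths, stats::runif(1, pert$wide_pulse_width_range[1],
                                         pert$wide_pulse_width_range[2]))
        amps <- c(amps, pert$wide_pulse_amplitude)
      }
      ratio <- baseline_vec + pulse_kernel_sum(t_grid, times, amps, widths) +
        stats::rnorm(config$duration_frames, 0, config$noise_sigma)
      cfp <- 1000 * (1 + stats::rnorm(config$duration_frames, 0, 0.01))
      div_frame <- NA_integer_
      if (config$frac_dividing > 0 &&
          stats::runif(1) < config$frac_dividing &&
          config$duration_frames >= 20L) {
        div_frame <- sample.int(config$duration_frames - 19L, 1L) + 9L
        dd <- div_frame:min(div_frame + 1L, config$duration_frames)
        cfp[dd] <- cfp[dd] * 0.5
        ratio[dd] <- ratio[dd] - 0.1
      }
      list(times = times, ratio = ratio, cfp = cfp, div_frame = div_frame)
    })
    traces[[i]] <- new_trace(cell_id = cell_ids[i],
                             colony_id = config$colony_id,
                             frame = frames, ratio = res$ratio,
                             cfp = res$cfp, yfp = res$ratio * res$cfp)
    truth$true_pulse_times[i] <- paste(sprintf("%.6g", sort(res$times)),
                                       collapse = ";")
    truth$division_frame[i] <- res$div_frame
  }

  list(dataset = colony_dataset(traces, condition = config$condition,
                                perturbation = pert),
       truth = truth)
}

#' Parse semicolon-joined ground-truth pulse times
#'
#' @param x character vector as stored in the `true_pulse_times` column
#'   of the ground-truth table.
#' @return A list of numeric vectors (minutes).
#' @export
parse_pulse_times <- function(x) {
  lapply(strsplit(x, ";", fixed = TRUE), function(v) {
    v <- v[nzchar(v)]
    as.numeric(v)
  })
}
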