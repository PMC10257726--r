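test_that("draw_pulse_times edge cases and parameter validation", {
  expect_identical(draw_pulse_times(0, 600, rng_seed = 1), numeric(0))
  expect_identical(draw_pulse_times(2, 0, rng_seed = 1), numeric(0))
  expect_error(draw_pulse_times(-1, 100), class = "erkpulse_invalid_error")
  expect_error(draw_pulse_times(1, -5), class = "erkpulse_invalid_error")
  tt <- draw_pulse_times(2, 600, rng_seed = 7)
  expect_true(all(diff(tt) > 0))
  expect_true(all(tt >= 0 & tt < 600))
  expect_identical(tt, draw_pulse_times(2, 600, rng_seed = 7))
})

test_that("draw_pulse_times matches the Poisson mean-count oracle", {
  # oracle: E[count] = rate x duration = 2/60 * 600 = 20
  set.seed(101)
  counts <- vapply(1:4000, function(i) length(draw_pulse_times(2, 600)),
                   numeric(1))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 20), 3 * se + 1e-9)
})

test_that("pooled inter-pulse gaps are exponential (KS vs Exponential(rate))", {
  # long windows keep the window-truncation size bias (gaps near the
  # window end are under-sampled) negligible relative to the KS critical
  # value at this n
  set.seed(77)
  gaps <- unlist(lapply(1:6, function(i) diff(draw_pulse_times(2, 60000))))
  expect_gt(length(gaps), 5000)
  ks <- suppressWarnings(ks.test(gaps, pexp, rate = 2 / 60))
  expect_gt(ks$p.value, 0.01)
})

test_that("render_trace reproduces baseline, kernel peaks and FWHM", {
  tr <- render_trace(1.05, duration_frames = 30)
  expect_equal(tr$ratio, rep(1.05, 30))

  tr <- render_trace(1.05, pulse_times = 60, amplitudes = 0.30, width = 10,
                     duration_frames = 80)
  expect_equal(max(tr$ratio), 1.35)
  expect_equal(tr$frame[which.max(tr$ratio)], 20L)  # frame nearest 60 min

  # dense-grid FWHM oracle: rendered width parameter 10 -> measured 10 +- 1.5
  expect_equal(oracle_fwhm(60, 0.3, 10), 10, tolerance = 1e-3)
  tr2 <- render_trace(1.05, pulse_times = 61.4, amplitudes = 0.3, width = 10,
                      duration_frames = 80)
  w <- measure_width(tr2, detect_peaks(tr2)$peak_frame[1])
  expect_lt(abs(w - 10), 1.5)

  expect_error(render_trace(1, width = 0), class = "erkpulse_invalid_error")
  expect_error(render_trace(1, duration_frames = 0),
               class = "erkpulse_invalid_error")
})

test_that("simulate_colony honours the active fraction and is deterministic", {
  cfg <- sim_colony_config(n_cells = 16, frac_active = 0.625, seed = 3)
  sim <- simulate_colony(cfg)
  expect_equal(sum(sim$truth$true_active), 10L)  # 10/6 split of 16

  sim2 <- simulate_colony(cfg)
  expect_identical(sim$truth, sim2$truth)
  expect_identical(sim$dataset$traces, sim2$dataset$traces)

  # different seed, different noise
  sim3 <- simulate_colony(sim_colony_config(n_cells = 16, frac_active = 0.625,
                                            seed = 4))
  expect_false(identical(sim$dataset$traces[[1]]$ratio,
                         sim3$dataset$traces[[1]]$ratio))
})

test_that("inactive traces almost never cross the detection threshold", {
  cfg <- sim_colony_config(n_cells = 150, frac_active = 0, seed = 8)
  sim <- simulate_colony(cfg)
  ratios <- unlist(lapply(sim$dataset$traces, `[[`, "ratio"))
  expect_lt(mean(ratios > 1.2), 0.001)
})

test_that("mek_inhibitor abolishes pulses after 120 min and drops the baseline", {
  cfg <- sim_colony_config(n_cells = 20, seed = 2,
                           perturbation = perturbation_spec("mek_inhibitor"))
  sim <- simulate_colony(cfg)
  times <- parse_pulse_times(sim$truth$true_pulse_times)
  expect_true(all(vapply(times, function(tt) all(tt < 120), logical(1))))
  post <- unlist(lapply(sim$dataset$traces, function(tr) tr$ratio[60:80]))
  expect_lt(abs(mean(post) - 0.95), 0.02)  # baseline 1.05 shifted by -0.10
})

test_that("raf_inhibitor inserts one synchronized 18-20 min pulse in all cells", {
  cfg <- sim_colony_config(n_cells = 15, seed = 6,
                           perturbation = perturbation_spec("raf_inhibitor"))
  sim <- simulate_colony(cfg)
  times <- parse_pulse_times(sim$truth$true_pulse_times)
  # every cell, active and inactive, has a pulse at exactly 180 min
  expect_true(all(vapply(times, function(tt) any(abs(tt - 180) < 1e-9),
                         logical(1))))
  # inactive cells have no other post-boundary pulse
  ina <- !sim$truth$true_active
  expect_true(all(vapply(times[ina], length, integer(1)) == 1L))

  # measured width of the noiseless wide pulse is in the sampled-FWHM band
  cfg0 <- sim_colony_config(n_cells = 8, seed = 6, noise_sigma = 0,
                            perturbation = perturbation_spec("raf_inhibitor"))
  det <- detect_pulses(simulate_colony(cfg0)$dataset)
  wide <- det$peaks[det$peaks$peak_frame == 60, ]
  expect_equal(nrow(wide), 8L)
  expect_true(all(wide$width_min > 16.5 & wide$width_min < 21.5))
})

test_that("fgf4 multiplies the pulse rate in +LIF but not in -LIF", {
  count_after <- function(cond) {
    cfg <- sim_colony_config(n_cells = 120, condition = cond, frac_active = 1,
                             seed = 9, perturbation = perturbation_spec("fgf4"))
    times <- parse_pulse_times(simulate_colony(cfg)$truth$true_pulse_times)
    c(before = sum(unlist(times) < 120), after = sum(unlist(times) >= 120))
  }
  plus <- count_after("+LIF")
  minus <- count_after("-LIF")
  expect_gt(plus["after"] / plus["before"], 1.5)        # rate doubled
  expect_lt(abs(minus["after"] / minus["before"] - 1), 0.35)  # unchanged
})

test_that("trigger-group members share event times with no lag", {
  cfg <- sim_colony_config(n_cells = 6, frac_active = 1, lambda_active = 0.3,
                           seed = 12,
                           trigger_groups = list(list(n_members = 3,
                                                      rate_per_hour = 2)))
  sim <- simulate_colony(cfg)
  members <- sim$truth$cell_id[!is.na(sim$truth$trigger_group)]
  expect_length(members, 3L)
  tms <- parse_pulse_times(
    sim$truth$true_pulse_times[match(members, sim$truth$cell_id)])
  shared <- Reduce(intersect, lapply(tms, function(x) round(x, 9)))
  expect_gt(length(shared), 0)

  # oversized groups are a configuration error
  expect_error(sim_colony_config(n_cells = 4, frac_active = 0.5,
                                 trigger_groups = list(list(n_members = 3,
                                                            rate_per_hour = 1))),
               class = "erkpulse_config_error")
})

test_that("division events are visible in both channels", {
  cfg <- sim_colony_config(n_cells = 30, seed = 21, frac_dividing = 1)
  sim <- simulate_colony(cfg)
  expect_true(all(!is.na(sim$truth$division_frame)))
  tr <- sim$dataset$traces[[1]]
  d <- sim$truth$division_frame[1]
  expect_lt(tr$cfp[d] / tr$cfp[d - 1], 0.6)
  expect_lt(tr$yfp[d] / tr$yfp[d - 1], 0.6)
})
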