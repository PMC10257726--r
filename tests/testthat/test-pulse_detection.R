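test_that("detect_peaks handles the canonical small cases", {
  pk <- detect_peaks(c(1.0, 1.1, 1.3, 1.1, 1.0))
  expect_equal(pk$peak_frame, 3L)
  expect_equal(pk$height, 1.3)
  expect_equal(pk$peak_time_min, 9)

  expect_equal(nrow(detect_peaks(rep(1.3, 10))), 0L)      # constant
  expect_equal(nrow(detect_peaks(seq(1, 2, by = 0.1))), 0L)  # monotone
  expect_equal(nrow(detect_peaks(c(1.0, 1.1))), 0L)       # too short

  # exactly 1.20 is not "above 1.2" under strict semantics
  x <- c(1.0, 1.1, 1.20, 1.1, 1.0)
  expect_equal(nrow(detect_peaks(x)), 0L)
  expect_equal(nrow(detect_peaks(x, detector_config(strict_above = FALSE))), 1L)

  # plateau: first sample of the flat top is the peak
  pk <- detect_peaks(c(1.0, 1.3, 1.3, 1.3, 1.0, 1.0))
  expect_equal(pk$peak_frame, 2L)

  # NA breaks eligibility at its neighbours
  pk <- detect_peaks(c(1.0, 1.3, NA, 1.0, 1.25, 1.0, 1.0))
  expect_equal(pk$peak_frame, 5L)
})

test_that("detect_peaks equals the exhaustive oracle on 1000 random series", {
  set.seed(1234)
  for (rep in 1:1000) {
    n <- sample(3:100, 1)
    x <- runif(n, 1.0, 1.45)
    if (rep %% 3 == 0) x <- round(x, 2)  # force ties and plateaus
    if (rep %% 7 == 0) x[sample(n, max(1, n %/% 10))] <- NA
    mpd <- sample(0:5, 1)
    got <- detect_peaks(x, detector_config(mpd = mpd))$peak_frame
    want <- oracle_peaks(x, mpd = mpd)
    if (!identical(as.integer(got), as.integer(want))) {
      fail(sprintf("oracle mismatch at rep %d (n=%d, mpd=%d)", rep, n, mpd))
    }
  }
  succeed()
})

test_that("any two reported peaks are separated by more than mpd frames", {
  set.seed(99)
  for (rep in 1:200) {
    x <- runif(sample(10:80, 1), 1.0, 1.5)
    mpd <- sample(1:6, 1)
    pk <- detect_peaks(x, detector_config(mpd = mpd))
    if (nrow(pk) > 1L) expect_true(all(diff(pk$peak_frame) > mpd))
  }
})

test_that("raising the baseline weakly increases the peak count", {
  set.seed(7)
  for (rep in 1:50) {
    x <- 1 + 0.3 * abs(sin(seq(0, 20, length.out = 60))) + rnorm(60, 0, 0.03)
    n0 <- nrow(detect_peaks(x))
    for (shift in c(0.05, 0.1, 0.2)) {
      n1 <- nrow(detect_peaks(x + shift))
      expect_gte(n1, n0)
      n0 <- n1
    }
  }
})

test_that("measure_width matches analytic and dense-grid oracles", {
  # symmetric triangle rising 2 frames each side: FWHM = half the base = 6 min
  x <- c(1, 1, 1, 1.0, 1.2, 1.4, 1.2, 1.0, 1, 1)
  pk <- detect_peaks(x)
  expect_equal(measure_width(x, pk$peak_frame), 6.0)

  # rendered noiseless Gaussian, sigma_t = 4.25 min -> FWHM 2.355*4.25 ~ 10
  w_true <- 4.25 * 2 * sqrt(2 * log(2))
  tr <- render_trace(1.0, 120.5, 0.4, w_true, 0, 80)
  w <- measure_width(tr, detect_peaks(tr)$peak_frame[1])
  expect_lt(abs(w - oracle_fwhm(120.5, 0.4, w_true)), 1.5)

  # Raf-type wide pulse, width parameter 18, noiseless
  tr <- render_trace(1.05, 121, 0.3, 18, 0, 80)
  w <- measure_width(tr, detect_peaks(tr)$peak_frame[1])
  expect_true(w >= 16.5 && w <= 19.5)

  # peak at the series edge: no left crossing -> NA
  y <- c(1.4, 1.38, 1.3, 1.1, 1.0, 1.0, 1.0, 1.0)
  expect_true(is.na(measure_width(y, 1)))
  expect_error(measure_width(y, 99), class = "erkpulse_invalid_error")
})

test_that("find_episodes builds maximal suprathreshold runs", {
  x <- rep(1.1, 20)
  ep <- find_episodes(x, detect_peaks(x))
  expect_equal(nrow(ep$episodes), 0L)

  x <- c(1.0, 1.3, 1.0, 1.0, 1.0, 1.25, 1.0)  # peaks 4 frames apart survive mpd
  pk <- detect_peaks(x)
  ep <- find_episodes(x, pk)
  expect_equal(nrow(ep$episodes), 2L)
  expect_false(any(ep$episodes$is_wide))
  expect_equal(ep$episodes$duration_min, c(3, 3))
  expect_equal(sum(ep$episodes$n_peaks), nrow(pk))
  expect_equal(ep$pulses$episode_id, c(1L, 2L))

  # wide by duration: a 5-frame (15 min) suprathreshold run
  x <- c(1.0, 1.25, 1.3, 1.28, 1.32, 1.25, 1.0)
  ep <- find_episodes(x, detect_peaks(x))
  expect_equal(nrow(ep$episodes), 1L)
  expect_true(ep$episodes$is_wide)
  expect_equal(ep$episodes$duration_min, 15)

  # wide by aggregation: two peaks in one episode, even when the
  # duration rule alone would not trigger
  x <- c(1.0, 1.3, 1.21, 1.21, 1.21, 1.28, 1.0)
  cfg7 <- detector_config(wide_min_frames = 7L)
  ep <- find_episodes(x, detect_peaks(x, cfg7), cfg7)
  expect_equal(ep$episodes$n_peaks, 2L)
  expect_true(ep$episodes$is_wide)
})

test_that("episode peak counts total the reported peaks on simulated data", {
  cfg <- sim_colony_config(n_cells = 40, seed = 31)
  det <- detect_pulses(simulate_colony(cfg)$dataset, measure_widths = FALSE)
  expect_equal(sum(det$episodes$n_peaks), nrow(det$peaks))
  expect_true(all(!is.na(det$peaks$episode_id)))
})

test_that("noiseless raf traces contain exactly one wide episode after the boundary", {
  cfg <- sim_colony_config(n_cells = 40, seed = 17, noise_sigma = 0,
                           perturbation = perturbation_spec("raf_inhibitor"))
  det <- detect_pulses(simulate_colony(cfg)$dataset, measure_widths = FALSE)
  ep <- det$episodes
  wide_after <- ep[ep$is_wide & ep$start_frame > 40, ]
  per_cell <- table(wide_after$cell_id)
  expect_equal(length(per_cell), 40L)
  expect_true(all(per_cell == 1L))
})
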