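# Independent oracles used to freeze expected values. Deliberately
# written in a different style from the package internals (explicit
# loops, repeated scans) so they share no code path with what they
# check.

# exhaustive peak detection: enumerate every local maximum above the
# threshold, then repeatedly keep the highest remaining candidate
# (earlier frame on ties) and discard all others within mpd frames.
oracle_peaks <- function(x, mph = 1.2, mpd = 3L, strict = TRUE) {
  n <- length(x)
  cand <- integer(0)
  if (n >= 3L) {
    for (i in 2:(n - 1L)) {
      if (anyNA(x[(i - 1L):(i + 1L)])) next
      if (!(x[i] > x[i - 1L] && x[i] >= x[i + 1L])) next
      if (strict) {
        if (x[i] > mph) cand <- c(cand, i)
      } else if (x[i] >= mph) {
        cand <- c(cand, i)
      }
    }
  }
  kept <- integer(0)
  while (length(cand)) {
    best <- cand[x[cand] == max(x[cand])]
    best <- min(best)
    kept <- c(kept, best)
    cand <- cand[abs(cand - best) > mpd]
  }
  sort(kept)
}

# brute-force centred sliding-window median (windows shrink at edges)
oracle_rolling_median <- function(x, window) {
  half <- window %/% 2L
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    w <- x[max(1, i - half):min(n, i + half)]
    out[i] <- median(w, na.rm = TRUE)
  }
  out
}

# textbook paired t: t = mean(d) / (sd(d)/sqrt(n)), two-sided p
oracle_paired_t <- function(before, after) {
  d <- after - before
  n <- length(d)
  t_stat <- mean(d) / (sd(d) / sqrt(n))
  list(t = t_stat, p = 2 * pt(-abs(t_stat), df = n - 1))
}

# textbook Welch t with Welch-Satterthwaite df
oracle_welch_t <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t_stat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t_stat, p = 2 * pt(-abs(t_stat), df = df))
}

# FWHM of a sum of Gaussian kernels by dense-grid evaluation of the
# half-maximum crossings around one pulse (true baseline known)
oracle_fwhm <- function(centre, amplitude, width, baseline = 0,
                        span = 3 * width, dt = 1e-3) {
  tt <- seq(centre - span, centre + span, by = dt)
  y <- baseline + amplitude * exp(-(tt - centre)^2 /
                                    (2 * (width / (2 * sqrt(2 * log(2))))^2))
  half <- baseline + amplitude / 2
  above <- which(y >= half)
  tt[above[length(above)]] - tt[above[1]]
}

# per-lag Pearson cross-correlation computed with explicit sums on the
# same preprocessed (detrended, z-scored) window the package uses
oracle_xcorr <- function(xi, xj, max_lag) {
  pearson <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    a <- a[ok]; b <- b[ok]
    am <- sum(a) / length(a); bm <- sum(b) / length(b)
    sum((a - am) * (b - bm)) /
      sqrt(sum((a - am)^2) * sum((b - bm)^2))
  }
  n <- length(xi)
  lags <- -max_lag:max_lag
  r <- numeric(length(lags))
  for (li in seq_along(lags)) {
    k <- lags[li]
    a <- c(); b <- c()
    for (t in seq_len(n)) {
      if (t + k >= 1 && t + k <= n) {
        a <- c(a, xi[t]); b <- c(b, xj[t + k])
      }
    }
    r[li] <- pearson(a, b)
  }
  data.frame(lag = lags, r = r)
}

# shorthand: simulate, detect, classify in one go
run_pipeline <- function(cfg, widths = FALSE) {
  sim <- simulate_colony(cfg)
  det <- detect_pulses(sim$dataset, measure_widths = widths)
  st <- classify_cells(sim$dataset, det$peaks)
  list(sim = sim, det = det, statuses = st)
}
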