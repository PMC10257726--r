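---
title: "Models and methods: pulsatile ERK activity quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: pulsatile ERK activity quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erkpulse)
```

# The measurement model

A nuclear FRET biosensor reports ERK kinase activity as the ratio
$R(T)$ of acceptor (YFP) to donor (CFP) emission, sampled at 3-minute
frames in live imaging of embryonic stem cell colonies. Undifferentiated
cells fall into two phenotypes: *active* cells that fire transient
ERK pulses — excursions of $R$ about 10 min wide rising well above the
interpulse baseline ($\approx 1.05$) — and *inactive* cells whose ratio
stays flat. Pulse timing in active cells is memoryless: inter-pulse
intervals are exponentially distributed, i.e. pulse generation is well
described by a homogeneous Poisson process with per-cell rate $\lambda$
(pulses/hour).

`erkpulse` implements the downstream quantification pipeline — pulse
detection, cell classification, frequency and perturbation statistics,
and cross-correlation synchrony — plus a generative simulator of the
whole measurement process, so every stage can be validated against a
known ground truth without access to raw imaging data.

# Pulse detection

A frame is a *peak* when its ratio exceeds the detection threshold
`mph = 1.2` and is a local maximum (strictly greater than its
predecessor, greater than or equal to its successor; a flat-topped
plateau yields its first frame). Candidates are pruned by the minimum
peak distance `mpd = 3` frames: processing candidates from highest to
lowest (ties to the earlier frame), a candidate within `mpd` frames of
an already-kept peak is discarded. Survivors are therefore separated by
strictly more than `mpd` frames (9 min). Both `mph` and `mpd` follow
the reference detector conventions used in the field; `strict_above`
toggles `>` vs `>=` at the threshold, which differ only on exact ties.

Numerical choices worth stating:

* **Missing samples** (`NA`) break peak eligibility at their
  neighbours: a local maximum is only certified when both neighbours
  are observed.
* **Widths** (FWHM) are measured per pulse as the time between the
  linearly interpolated crossings of the half level
  $b + (h - b)/2$, where $h$ is the peak ratio and $b$ a local
  baseline. The baseline is the median of up to three sub-threshold
  samples flanking the suprathreshold episode, *capped at the global
  10th percentile of the trace*. The cap matters: flanking samples sit
  on the measured pulse's own Gaussian skirt, and the flank median
  alone overestimates the baseline of wide pulses, biasing FWHM low by
  2–3 min at 18–20 min widths. With the cap, rendered noiseless pulses
  of FWHM 10 and 18 min measure 10.1 and 18.2 min against a dense-grid
  oracle. Edge pulses missing a crossing on one side get `NA` width.
* **Episodes** are maximal runs of consecutive suprathreshold frames.
  An episode is *wide* when it spans at least `wide_min_frames = 5`
  frames (15 min) or contains two or more detected peaks — the
  "aggregate of pulses" signature by which a widened pulse is
  recognised. Classification and frequency statistics use peak counts
  only; widths are reported but never fed back into counting.

# Classification and colony summaries

Observed duration is `3 ×` (non-missing samples), so gaps shorten the
effective recording. A cell is **active** with at least one pulse over
at least 120 min observed, **inactive** with zero pulses over at least
160 min, **excluded** when QC flags a division, otherwise
**unclassifiable**. The asymmetric duration rules mean short recordings
can assert activity but not inactivity. "At least one pulse" is the
adopted reading of the activity rule; the pulse-count threshold is a
`min_pulses` argument for users who prefer a stricter definition.

Dividing cells are excluded outright (not truncated): both fluorescence
channels collapse at division, so a cell is flagged when CFP *and* YFP
drop by ≥ 40% between consecutive frames. A single-channel drop is
treated as a ratio artifact and kept. On ratio-only data a fallback
applies (drop ≥ 0.15 sustained ≥ 2 frames), which is deliberately
conservative.

Colony summaries report the percentage of active cells among classified
(active + inactive) cells at two precisions, integer and one decimal,
both rounded half-up — 10/6 gives 62.5 → 63%, matching conventional
reporting of published counts.

# Statistics

Pulse frequency is pulses/hour over a frame window (frames 1–40 = the
first 120 min, i.e. 2 h). Perturbation analyses use frames 1–40 vs
41–80 around a perturbation applied between frames 40 and 41, and
include only cells classified active over the full recording, since
before/after plots of published analyses are restricted to active
cells. The paired before/after test is a two-sided paired t-test;
group comparisons default to Welch's two-sided t-test (the unequal
variance form is the safer default where only "t-test" is specified;
Student's is available via `var_equal = TRUE`). Zero-variance paired
differences are reported as `p_below_1e6` rather than NaN, so a
uniform, deterministic shift in every cell is printed as "P < 1e-6".

Inter-pulse intervals are gaps between consecutive peaks *within* a
cell, pooled across cells; censored gaps at the recording edges are
dropped, as in standard renewal analysis. The exponential rate is the
MLE `60 / mean(IPI)` and a one-sample KS test against that exponential
is reported. Two caveats are deliberate: the KS test uses an estimated
rate (slightly conservative), and intervals between *detected* peaks
are left-truncated at roughly the detector dead time (~12 min), so
exponentiality should be asserted on generative (ground-truth) gaps,
not detector output — detected-gap KS failure at large n reflects the
dead time, not non-Poisson biology.

# Synchrony

For two cells of one colony, both traces are restricted to the analysis
window (default the first 120 min), detrended with a centred rolling
median (21 frames, long relative to a pulse so pulses survive) and
z-scored. For each lag $k \in [-8, +8]$ frames (±24 min, the largest
frame multiple inside the ±25 min synchrony window), $r(k)$ is the
Pearson correlation of the overlapping aligned samples; the normalised
form is what makes the reported $r$ comparable across pairs. A pair is
*strong* when $\max_k r(k) > 0.7$; synchronised groups are connected
components of the strong-pair graph. Ties in $r$ resolve to the
smallest absolute lag. At least 30 overlapping complete frames are
required per evaluated lag.

A property the simulator makes explicit: maximising $r$ over 17 lags on
*sparse* trains is permissive. At the default detected rate
(~1.4 pulses per 120-min window) many cells carry a single pulse, and
two single-pulse traces align at some lag with high probability,
z-scoring to $r$ near 1. Colonies of independently pulsing simulated
cells therefore show many spuriously strong pairs. Strong pairs on
sparse data are evidence of *candidate* synchrony, not proof; the
zero-lag structure of genuinely shared triggers is the discriminating
signature, and lag-0 recovery is what the validation suite asserts
(≥ 95% on shared-dominated pairs with at least two shared events in
the window — below two aligned events a lag is unidentifiable).

# The simulator

The generator states the world the analysis assumes, cell by cell:

| parameter | default | meaning |
|---|---|---|
| `baseline` | 1.05 | interpulse ratio level |
| `noise_sigma` | 0.02 | i.i.d. Gaussian measurement noise (7.5σ below threshold) |
| `pulse_width_min` | 10 | pulse FWHM, minutes |
| `amp_range` | 0.2–0.4 | per-pulse amplitude above baseline (uniform) |
| `frac_active` | 0.553 (+LIF) / 0.435 (−LIF) | published aggregate active fractions |
| `lambda_active` | 0.69 (+LIF) / 0.81 (−LIF) | target *detected* pulses/hour |
| `duration_frames` | 80 | 240 min at 3 min/frame |

Pulses are Gaussian kernels in time (FWHM $= 2\sqrt{2\ln 2}\,\sigma_t$)
— only widths, not shapes, are published, and a smooth unimodal kernel
with an analytic FWHM is the simplest faithful choice. Amplitudes
0.2–0.4 guarantee threshold crossing while varying peak heights; the
noise floor makes a false threshold crossing in an inactive cell a
$<10^{-13}$ event per frame. Neither amplitudes nor noise are published
quantities; both are modelling choices.

**Latent rate vs detected frequency.** The published pulse frequencies
are *detector outputs*. A detector with minimum peak distance `mpd`
cannot report two pulses closer than `mpd + 1` frames, which removes
~13–16% of latent Poisson pulses at these rates — more than the +4–7%
upward bias from conditioning on observing an active cell. Setting the
latent rate equal to the printed frequency therefore undershoots the
detected mean. The generator instead treats `lambda_active` as the
target detected frequency and draws at the dead-time-inverted latent
rate $\lambda^* = \lambda / (1 - \lambda\,\tau/60)$ with
$\tau = (\text{mpd}+1) \times 3 = 12$ min — the closed-form
non-paralyzable dead-time correction, not a fitted constant. Simulated
detected means land at ~0.70 (+LIF) and ~0.80 (−LIF), inside the ±0.1
validation bands.

**Perturbations** are applied between frames 40 and 41 (120 min):

* *MEK inhibitor*: pulse generation stops; baseline shifts −0.10
  (basal ERK activity is MEK-dependent too).
* *FGFR inhibitor*: pulse generation stops; baseline unchanged.
* *EGFR inhibitor*: no effect.
* *Excess FGF4*: rate × 2 in +LIF; no effect in −LIF.
* *Raf inhibitor*: generation stops and 60 min later a single wide
  pulse (FWHM drawn uniformly 18–20 min per cell) fires simultaneously
  in **every** cell, active and inactive (paradoxical Raf activation).
  Its amplitude is fixed at 0.30 so that the 1.2 threshold sits exactly
  at half maximum (baseline 1.05 + 0.15): the suprathreshold episode
  then lasts as long as the pulse's FWHM, 18–20 min ≥ the 15-min wide
  rule, which reproduces the published wide-pulse phenomenology — all
  cells classified active, a wide episode detected in every cell.

**Synchrony** is generated by shared triggers only: a colony-level
Poisson event stream per group, each member firing at each event with
probability `fire_prob` at exactly the event time (zero lag). No
spatial geometry or ligand diffusion is modelled, so the simulator can
validate lag recovery and grouping but says nothing about which cells
of a real colony should synchronise.

**Divisions** halve both synthetic channels for two frames and depress
the ratio by 0.1, giving the QC rule something concrete to detect;
`frac_dividing` defaults to 0 and is switched on per experiment.

Reproducibility: per-cell RNG substreams are derived by stable hashing
of `(seed, colony_id, cell_id)`, so a seed pins the whole colony
bit-for-bit and adding a cell never perturbs existing traces.

# What a green test does and does not establish

The simulator emulates the statistical skeleton of the data — baseline,
noise, pulse shape and rate, mixtures, shared triggers, perturbation
regimes. It does not emulate photobleaching or drift (detrending is
exercised on synthetic ramps instead), segmentation or tracking errors,
spatial structure, amplitude autocorrelation within cells, or any
coupling between division and pulse dynamics. Validation on simulated
colonies therefore establishes that the pipeline recovers the
parameters of this stated world (≥ 95% active/inactive recovery,
frequency calibration within ±0.1 pulses/hour, exact oracle agreement
of the detector) — not that the biological conclusions drawn from the
original imaging data would reproduce.

# Known limitations

* Published per-cell measurements derive from unreleased imaging data;
  worked examples reproduce printed counts and simulator-constrained
  phenomenology only.
* The strong-pair criterion $r > 0.7$ over a lag search is permissive
  on sparse traces (see Synchrony above); pair counts at a secondary,
  stricter threshold can be obtained by passing a different
  `r_threshold`.
* The dead-time inversion is first-order; residual calibration error
  (~±0.02 pulses/hour at default rates) is well inside the validation
  bands but would grow at rates several-fold higher.
* KS exponentiality on detected (rather than latent) inter-pulse
  intervals fails by construction at large n; use ground-truth gaps or
  a shifted-exponential model for detector output.
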