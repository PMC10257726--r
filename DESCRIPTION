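Package: erkpulse
Title: Quantification of Pulsatile ERK Activity in Single-Cell FRET Time Series
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying pulsatile ERK kinase activity from
    single-cell FRET biosensor ratio time series sampled at 3-minute
    intervals. Provides threshold-based peak detection with a minimum
    peak distance rule, pulse width (FWHM) measurement, suprathreshold
    episode analysis for wide "aggregate" pulses, active/inactive cell
    classification by observation-duration rules, pulse-frequency and
    before/after perturbation statistics (paired and Welch t-tests),
    exponential inter-pulse-interval fitting, and lagged
    cross-correlation synchrony analysis within colonies. A seeded
    stochastic simulator generates colonies of pulsatile ratio traces
    with known ground truth, including five pharmacological
    perturbation regimes (MEK, FGFR, EGFR and Raf inhibitors, and
    excess FGF4), so the full pipeline can be exercised and validated
    without raw imaging data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
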