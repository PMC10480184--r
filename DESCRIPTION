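Package: sptfcs
Title: Combined Single-Particle Tracking and Fluorescence Correlation
    Spectroscopy Diffusion Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-trajectory mean-squared-displacement analysis for
    single-particle tracking (instantaneous diffusion coefficients,
    anomalous exponents, immobile-fraction classification, detection
    density maps), Gaussian-mixture subpopulation discrimination over
    (log10 D, alpha) with BIC/AIC model selection, fluorescence
    correlation spectroscopy autocorrelation computation and normal or
    anomalous model fitting with focal-volume calibration, and
    cross-method unification through transit times and molecule-budget
    bookkeeping.  Includes seeded generators for Brownian and fractional
    Brownian trajectories and for photon-count traces of emitters
    crossing a Gaussian focal volume, so the full pipeline can be
    exercised and validated against theory without instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    mclust,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
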