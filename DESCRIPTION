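Package: nirphantom
Title: Synthetic Tissue-Phantom NIR Spectra, Noise Benchmarking and PLS
    Glucose Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking near-infrared diffuse-reflectance
    spectrometers on tissue-simulating phantoms. Builds 7x7 glucose-by-scatterer
    phantom designs with gravimetric recipe math, forward-simulates single-beam
    spectra and pulsed-laser modulation cycles with configurable noise, drift
    and temperature effects, harmonizes raw data (demodulation, pairwise scan
    averaging, duration trimming, shape-preserving wavelength interpolation,
    absorbance transform), computes 100% line RMS noise and signal-to-noise
    benchmarks with quadratic detrending, and fits in-house SIMPLS partial
    least squares calibration models with leave-one-phantom-out
    cross-validation, wavelength-window grid search, noise-injection
    experiments and randomized-label selectivity controls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
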