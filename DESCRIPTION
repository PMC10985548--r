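Package: cortexwave
Title: Quantification of Cortical Travelling Waves in Fluorescence Time-Lapse Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify cortical travelling waves of cytoskeletal
    regulators observed by TIRF time-lapse microscopy: FFT-based oscillation
    calling on region-of-interest intensity traces, cross-correlation phase-lag
    estimation with sub-frame refinement, peak-aligned average cycle profiles,
    waveform asymmetry and anti-phase scoring, kymograph construction and
    wave-speed estimation, photoconverted-punctum displacement classification,
    FRAP recovery fitting, cell-track velocimetry, and population statistics
    (per-experiment wave fractions, t-tests, one-way ANOVA with Sidak-adjusted
    pairwise comparisons). Includes a phenomenological synthetic-movie
    generator with full ground truth for validating every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    tiff,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
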