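Package: serscal
Title: Quantitative SERS Calibration and Interlaboratory Figures of Merit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative surface-enhanced Raman spectroscopy
    (SERS) interlaboratory studies: reading and validating per-laboratory
    spectral collections, a data-analysis pipeline (Savitzky-Golay
    smoothing, resampling, range selection, baseline correction, extended
    multiplicative signal correction), inverse least-squares calibration on
    the adenine ring-breathing band (715-750 1/cm) with system-suitability
    checks, ISO 5725 accuracy decomposition of pooled prediction residuals
    into RMSEP, SEP and BIAS with range normalization and 1/SEP quality
    classes, and a seeded synthetic multi-laboratory spectrum generator for
    validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
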