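Package: thawspec
Title: Bioimpedance Analysis of Freeze-Thaw Damage in Muscle Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for multi-frequency electrical impedance
    spectra recorded along freeze-thaw trajectories of muscle tissue.
    Fits the single-dispersion Cole relaxation model to complex spectra by
    weighted complex nonlinear least squares, derives the Py membrane
    integrity parameter, computes impedance descriptors (magnitude, phase,
    relative change, fresh-vs-thawed indices, impedance change rate),
    compares thawing treatment groups per temperature with exact and
    approximate Mann-Whitney U tests, and classifies thawing method from
    36-point spectra with a from-scratch two-layer LSTM network. Includes a
    calibrated synthetic freeze-thaw generator (lumped thermal model with a
    latent-heat plateau, membrane-damage dynamics, noisy Cole spectra) that
    reproduces the statistical structure the analyses assume.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
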