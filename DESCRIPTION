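Package: palmspec
Title: Raman and NMR Chemometrics for Palm Oil Authentication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric analysis of vibrational spectra of edible oils,
    built around the problem of tracing crude palm oil to its source.
    Provides a seeded simulator for palm-oil Raman spectra (Lorentzian
    bands on a fluorescence-like baseline, beta-carotene bands scaling
    with concentration) and for lipid 1H-NMR integrals; spectral
    preprocessing (asymmetric-least-squares baseline correction,
    Savitzky-Golay smoothing, vector normalization); principal component
    analysis for origin discrimination; a NIPALS partial least squares
    regression with grouped cross-validation, calibration metrics (R2,
    Q2, RMSECV, RMSEP) and a restricted-range limit-of-detection
    procedure for beta-carotene quantification; ranking of oils by
    predicted carotene content against their PC-1 position; and
    estimation of oleic, linoleic and saturated fatty-acid chain
    percentages from three 1H-NMR integrals with palm vs palm-kernel
    classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics
Config/testthat/edition: 3
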