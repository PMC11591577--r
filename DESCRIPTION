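Package: ftirchemo
Title: Chemometric Classification Workflows for ATR-FTIR Fingerprint Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for discriminant analysis of attenuated-total-reflection
    Fourier-transform infrared (ATR-FTIR) spectra of biofluids in the
    1500-1000 cm-1 fingerprint region. Implements a spectral preprocessing
    chain (region cropping, normalization, moving-average smoothing,
    Savitzky-Golay second derivatives, training-set autoscaling), SELECT
    stepwise-orthogonalization variable selection with linear discriminant
    analysis, SIMCA class modelling with modelling and discriminant power,
    PLS-DA and OPLS-DA with VIP scores, cross-validated Q2Y, permutation
    tests and a cross-validated-residual ANOVA, and single-wavenumber ROC
    diagnostics with Youden-index cut points. Ships a synthetic cohort
    generator that plants group-specific absorbance effects at marker
    wavenumbers so the full workflow can be exercised against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
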