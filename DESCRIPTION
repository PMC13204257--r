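Package: carotidscreen
Title: Carotid Vibration Screening with Wavelet Scalogram Biomarkers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for screening carotid artery
    pathology from single-channel neck-surface vibration recordings captured
    by wearable accelerometers. Provides a synthetic bilateral cohort
    simulator emulating cardiac-cycle-locked pulse and stenosis-dependent
    turbulence spectra, signal preprocessing (decimation, Butterworth
    band-pass, normalization, smoothing, windowed segmentation), analytic
    Morse-wavelet scalograms restricted to the 5-60 Hz band, interpretable
    time-frequency biomarkers (fractional high-frequency energy ratios,
    spectral centroid/spread/roll-off, spectral-image entropy, Sobel edge
    energy, Gini sparsity), univariate feature screening and grouped
    patient-side cross-validation, an L2-regularized logistic classifier
    with out-of-fold threshold prespecification at a sensitivity floor, and
    exact additive (linear SHAP) attribution.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
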