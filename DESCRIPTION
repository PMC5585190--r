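Package: phaseamp
Title: Phase-Amplitude Coupling Detection for Trial-Based Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and validation of phase-amplitude coupling (PAC) in
    trial-epoched single-channel electrophysiological recordings such as
    MEG virtual-electrode time series. Provides zero-phase Butterworth
    band-pass filtering via second-order sections, Hilbert analytic-signal
    phase and envelope extraction with edge trimming, four modulation-index
    estimators (two mean-vector-length variants, a phase-locking-value
    variant and a Kullback-Leibler variant), phase-frequency by
    amplitude-frequency comodulograms with trial-shuffled surrogate
    normalization, cluster-based permutation comparison of conditions,
    a rise/decay-time diagnostic for non-sinusoidal oscillations, and a
    validated simulator of alpha-phase-modulated gamma-band activity for
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
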