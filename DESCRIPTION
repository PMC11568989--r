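Package: gaitfall
Title: Fall-Risk Classification from Waist-Worn Accelerometer Gait Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for fall-risk screening of older adults from a
    single waist-worn tri-axial accelerometer recorded during a short walk.
    Preprocesses vertical, mediolateral and anterior-posterior acceleration
    (median filtering, gravity removal, zero-phase 0.5-3 Hz and 0.5-15 Hz
    bandpass, max-normalization), detects steps from vertical-axis local
    maxima, extracts a fixed registry of 168 gait features (gait-cycle timing,
    cross-axis correlation/covariance, per-axis time-domain statistics and
    Tukey-windowed periodogram spectral descriptors), ranks features with a
    from-scratch two-class ReliefF over a neighbor-count sweep, and evaluates
    faller/non-faller multilayer-perceptron classifiers under stratified
    10-fold cross-validation with pooled confusion-matrix metrics. Includes a
    seeded synthetic gait cohort generator with controllable step-timing and
    amplitude jitter for fully reproducible end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
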