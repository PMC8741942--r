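Package: rppgaf
Title: Contactless Atrial Fibrillation Detection from Remote Photoplethysmography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, signal processing, and deep-learning tools for
    camera-based (contactless) atrial fibrillation screening. Generates
    synthetic facial RGB traces driven by rhythm-specific RR-interval
    processes (atrial fibrillation, normal sinus rhythm, ectopy, flutter and
    other abnormalities), extracts the remote-photoplethysmography (rPPG)
    pulse signal by chrominance projection, applies a Chebyshev type-II
    bandpass filter, cuts recordings into fixed-length normalized segments,
    classifies each segment with a sample-level 1-D deep convolutional
    network trained in-package, and aggregates segment calls into a
    per-subject atrial fibrillation vote. Includes stratified k-fold
    cross-validation with subject-level grouping, confusion-matrix metrics,
    ROC/AUC, and a segment-length sensitivity sweep.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
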