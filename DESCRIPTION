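Package: sonostate
Title: Dynamic Brain-State Analysis for Functional Ultrasound Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end resting-state functional connectivity analysis for
    functional ultrasound (fUS) Power-Doppler time series. Implements canonical
    correlation analysis (CCA) denoising of pixel time series against a
    designated noise region with motion-anchored threshold selection,
    zero-phase Butterworth bandpass filtering, static pixel-correlation
    quantification and seed-based maps, Hilbert-phase synchronicity matrices,
    L1-norm k-means brain-state clustering with leave-one-out cross-validation,
    dynamic connectivity biomarkers (fractional occupancy, mean dwell time,
    transition probabilities), group statistics with family-specific Bonferroni
    correction, and a logistic-regression biomarker classifier with ROC/AUC and
    Youden operating point. A synthetic-cohort simulator with known latent
    state sequences and planted noise sources makes every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    signal,
    pROC,
    jsonlite,
    EBImage,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
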