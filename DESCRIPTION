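Package: dbstheta
Title: Conflict-Task EEG and Behavioral Biomarker Pipeline for DBS Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for within-subject deep brain stimulation
    (DBS) ON/OFF experiments using a conflict task with emotional
    distractors. Covers trial-level quality control and gamma GLM reaction
    time modelling with stepwise AIC selection, induced (non-phase-locked)
    theta power via ERP subtraction and Morlet wavelet decomposition with
    dB baseline normalization, single-trial sliding regression with
    cluster-mass permutation inference and FDR correction, resting-state
    multitaper spectral comparison, and subject-level biomarker statistics
    (integrated theta change, Fisher-Z correlation, robust regression,
    bootstrap confidence intervals, ROC/AUC responder classification).
    Includes a synthetic-data module that emulates the full experimental
    design so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    lme4,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml,
    ggplot2,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
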