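Package: roidecode
Title: ROI-Based fMRI Task Decoding with Correlation-Aware Feature Importance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decoding working-memory task conditions from
    region-of-interest (ROI) averaged BOLD time series. Provides an
    event-locked segmentation pipeline that concatenates per-phase
    (encoding/retrieval) stimulus segments, assembly of two- to five-class
    classification problems from task and resting-state sessions, a uniform
    benchmark over classical discriminators and gradient-boosted trees with
    support-weighted F1 evaluation, compact convolutional and residual
    network classifiers for short multichannel time series, and two
    explainability procedures: a correlation-aware iterative-pruning ROI
    importance score for tree ensembles and a subset-zeroing prediction-flip
    perturbation importance applicable to any fitted model. A synthetic
    ROI-BOLD generator with planted class-discriminative activations and
    duplicated (highly correlated) regions supports end-to-end validation
    and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    e1071,
    nnet,
    rpart,
    ranger,
    glmnet,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
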