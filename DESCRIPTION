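Package: radsig
Title: MRI Radiomics Signatures of Medication Usage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end, reproducible radiomics pipeline for studying
    associations between MRI texture and binary patient-level exposures
    (statin, omega-3 and ACEI usage in prostate cancer). Provides IBSI-style
    extraction of 944 features per region of interest (first-order, shape,
    GLCM, GLRLM, GLSZM, GLDM and NGTDM classes on original,
    Laplacian-of-Gaussian and 8 wavelet-derived images), bias-field
    correction and histogram-matching preprocessing, a resampling-based
    feature-selection procedure (ANOVA screen, FDR filter, correlation
    clustering, sequential floating forward selection with a
    gradient-boosting learner), repeated stratified k-fold cross-validated
    evaluation with ROC/PR metrics, a negative-control mode, and synthetic
    phantom and cohort generators so the whole pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    RNifti,
    igraph,
    xgboost,
    jsonlite,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
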