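Package: sagesurv
Title: Population-Graph Neural Survival Models for Early Stage Lung Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds patient population graphs from clinical similarity
    (demographics, tumour location, histology, pathological stage), attaches
    tumour-image node features, and trains an edge-weighted two-layer
    GraphSAGE network with a Cox proportional-hazards partial-likelihood
    loss to produce per-patient risk scores for overall and recurrence-free
    survival. Includes a CT tumour-volume preprocessing path (windowing,
    standard crop, resampling, slice montage, pluggable featurizers), a
    synthetic cohort generator with Weibull proportional-hazards survival,
    and a survival evaluation stack: bootstrap AUC, Kaplan-Meier curves with
    training-median risk stratification, log-rank tests, continuous net
    reclassification improvement, integrated discrimination improvement,
    and decision curve analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Matrix,
    survival,
    jsonlite,
    RNifti,
    png
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
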