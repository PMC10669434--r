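Package: octsrn
Title: Sparse Residual Networks for Multi-Label Retinal OCT Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds, trains and interprets lightweight sparse residual
    networks (SRN) and their dual-branch multi-scale variant (MS-SRN) for
    multi-label classification of retinal optical coherence tomography
    (OCT) B-scans over the classes AMD, ERM, ME and Normal. Includes exact
    learnable-parameter and multiply-accumulate accounting for the SRN
    family and reference residual-network topologies, kernel factorization
    utilities (5x5 into stacked 3x3), a sigmoid multi-label loss, seeded
    SGD training with rotation/flip augmentation, per-class and
    micro-averaged diagnostic metrics with patient-level exact-match
    accuracy and across-seed t-tests, Grad-CAM heatmaps, and a seedable
    synthetic OCT phantom generator with known lesion coordinates for
    end-to-end testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: C++17
Config/testthat/edition: 3
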