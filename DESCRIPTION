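Package: habitatct
Title: Habitat Imaging and Radiomic Signatures for Multi-Phase CT Tumor Grading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end habitat-imaging analysis pipeline for preoperative
    tumor grading from multi-phase CT. Partitions tumor volumes into
    texturally homogeneous subregions (habitats) by voxel-wise K-means with
    Calinski-Harabasz cluster-number selection, constructs peritumoral ring
    masks at fixed physical radii, extracts an IBSI-style radiomic feature
    inventory (shape, first-order, GLCM, GLRLM, GLSZM, GLDM, NGTDM over
    wavelet and Laplacian-of-Gaussian filtered images), reduces features via
    an ICC / Pearson / mRMR / LASSO cascade, trains class-balanced signature
    models, and evaluates them with DeLong AUC inference, calibration and
    decision-curve analysis. Ships a synthetic multi-phase CT cohort
    generator so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    glmnet,
    ranger,
    xgboost,
    igraph,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
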