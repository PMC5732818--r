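Package: crtradiomics
Title: CT Radiomics Pipeline for Chemoradiotherapy Response Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end contrast-enhanced CT radiomics analysis for predicting
    tumor response to chemoradiotherapy in esophageal carcinoma. Implements
    isotropic resampling and finite gray-level quantization of contoured tumor
    regions, a canonical 214-feature inventory (shape, histogram, GLCM, GLRLM,
    GLSZM, NGTDM, GLGCM, Laplacian-of-Gaussian and Gabor transform features in
    2D and 3D), inter-observer reproducibility filtering by intraclass
    correlation, univariate screening (Kruskal-Wallis, ROC with Youden
    cut-offs, DeLong comparison of AUCs), wrapper-based feature selection with
    cross-validated SVM and neural-network classifiers, McNemar model
    comparison, and hold-out validation. Includes a seeded synthetic CT cohort
    generator so the whole pipeline is testable without clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    e1071,
    nnet,
    igraph,
    jsonlite,
    RNifti,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
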