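Package: osteotex
Title: Radiomic Texture Features, Resampling and Classifier Benchmarking for
    Spine DXA Bone-Quality Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully synthetic-data-driven workflow for classifying
    lumbar-spine dual-energy X-ray absorptiometry (DXA) images into healthy and
    degraded trabecular bone classes. Provides a generator of annotated DXA-like
    images with known ground truth, a rule-based L1-L4 region-of-interest mask
    algorithm driven by scanner-style overlay annotations, computation of 93
    radiomic texture features across six families (first-order statistics, grey
    level co-occurrence, run-length, size-zone, dependence and neighbouring grey
    tone difference matrices), five class-imbalance resampling techniques
    (random undersampling, SMOTE, ADASYN, SMOTETomek, SMOTEENN) with a
    post-synthesis range constraint, and a stratified cross-validated grid-search
    benchmark of logistic regression, support vector machine and gradient
    boosting classifiers over the resulting 45 dataset-resampler combinations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    glmnet,
    e1071,
    xgboost,
    png,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
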