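Package: lesionbench
Title: Bounded-Histogram Features, Classifier Benchmarking and
    Explanations for Breast Ultrasound Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Extracts two weakly dependent intensity feature classes from
    grayscale breast-ultrasound lesion images with binary ground-truth
    masks: bounded-histogram features (CHi), the fraction of image pixels
    whose intensity falls in each of eight contiguous 32-level gray bins,
    and grayscale-density features (Ci), the same bin occupancy restricted
    to the lesion mask and normalised by lesion area. Benchmarks four
    classifiers (random forest, two gradient-boosting configurations and
    L1-penalised logistic regression) on the 16-feature table with a
    confusion-matrix metric chain (accuracy, F1, AUC, McNemar chi-squared,
    stratified cross-validation) and impurity-importance feature selection
    at the mean-weight threshold. Ships its own exact tree-Shapley and
    tabular LIME explainers plus per-class rank-agreement reports, and a
    seeded synthetic lesion-image generator so the full pipeline runs
    without the external image dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    png,
    randomForest,
    Rcpp,
    stats,
    tools,
    utils,
    xgboost
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr,
    yaml
Config/testthat/edition: 3
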