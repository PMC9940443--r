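Package: cardiorisk
Title: ECG Feature Extraction and Stacked-Ensemble Cardiovascular Risk Zoning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for cardiovascular disease risk-zone
    prediction from wearable-grade data. Implements the Pan-Tompkins QRS
    detection chain (cascaded low-pass/high-pass filters, five-point
    derivative, squaring, 150 ms moving-window integration) and adaptive
    thresholding for single-channel ECG; post-R ST-segment extraction and
    slope measurement; derivation of the oldpeak (support-vector regression)
    and restecg (support-vector classification) attributes; a preprocessing
    recipe for the 14-attribute UCI heart-disease table (chained-equation
    imputation, robust median/IQR scaling, ordinal encoding, random
    oversampling, stratified 70/30 splits); and stacking ensembles of up to
    ten tuned base learners under a logistic-regression meta-classifier, for
    two-level (green/red) and three-level (green/yellow/red) risk zoning,
    with macro-averaged confusion-matrix metrics and one-vs-rest ROC-AUC.
    Synthetic generators for parametric PQRST waveforms and patient cohorts
    with known ground truth make the whole chain testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    signal,
    e1071,
    randomForest,
    xgboost,
    nnet,
    rpart,
    caret,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
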