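Package: faimspipe
Title: Machine-Learning Classification Pipelines for FAIMS Volatile
    Organic Compound Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying disease status from Field Asymmetric Ion
    Mobility Spectrometry (FAIMS) measurements of volatile organic compounds
    in biological samples such as urine.  Provides a data model and plain-text
    I/O for per-run dispersion matrices, linearisation into feature vectors,
    one- and two-dimensional discrete wavelet transform feature extraction
    with least-asymmetric Daubechies wavelets, cross-validation-safe Wilcoxon
    rank-sum filter selection (plus PCA, stepwise-AIC wrapper and embedded
    comparison modes), five reference classifiers under a stratified 10-fold
    cross-validation harness, ROC/AUC evaluation with stratified bootstrap
    confidence intervals and a balanced sensitivity/specificity threshold
    rule, run-level and probability-level ensembling, and a synthetic FAIMS
    cohort generator with planted class signal, run-to-run sample degradation
    and controllable demographic confounding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    Matrix,
    jsonlite,
    kernlab,
    randomForest,
    stats,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
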