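Package: rslpnet
Title: Constructive Neural Networks for Serial Electrocardiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grows problem-specific feed-forward neural networks for
    case/control classification of serial electrocardiogram (ECG) difference
    features by a repeated structuring and learning procedure: one-neuron
    architecture growth alternating with scaled-conjugate-gradient learning
    phases under validation-based early stopping, with inverse-prevalence
    class weighting.  Includes the 13 vectorcardiographic difference
    features computed from baseline/follow-up ECG pairs, fixed-architecture
    and weighted logistic-regression comparators, ROC/AUC evaluation with
    DeLong confidence intervals and paired tests, and a quartile-calibrated
    synthetic cohort generator for heart-failure- and ischemia-like
    serial-ECG populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    pROC,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
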