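Package: genescreen
Title: Two-Stage Multifilter Gene Selection for Binary Expression
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Feature selection for binary (for example tumour versus normal)
    gene-expression classification by a two-stage multifilter procedure:
    stage one combines Fayyad-Irani minimum-description-length entropy
    discretization, information-gain ranking with a zero threshold, and a
    genetic-algorithm subset search; stage two refines the surviving subset
    by greedy minimum-redundancy-maximum-relevance (mRMR) selection on
    discrete mutual information.  Includes a leakage-safe evaluation
    harness (stratified k-fold, leave-one-out, and hold-out protocols) with
    SVM, naive-Bayes, decision-tree and k-nearest-neighbour classifier
    adapters, the usual confusion-matrix metric suite (accuracy,
    sensitivity, specificity, Matthews correlation coefficient, weighted
    TPR/FPR, ROC points), and a synthetic microarray-like data generator
    with known informative, redundant and noise genes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    class,
    e1071,
    graphics,
    pROC,
    rpart,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
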