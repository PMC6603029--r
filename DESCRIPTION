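Package: radiolik
Title: Radiomics-Driven Likelihood Functions for CT Tumor Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for building and applying two-feature radiomic
    diagnostic signatures from precomputed CT feature tables. Provides
    test-retest reliability screening via Lin's concordance correlation
    coefficient and Kruskal-Wallis discriminability filtering, a pluggable
    bank of supervised and unsupervised feature-ranking algorithms with
    equal-weight consensus averaging, selection of one-shape-plus-one-texture
    signatures, evaluation and least-squares fitting of two published
    nonlinear likelihood functional forms (MLF I and MLF II) with their exact
    printed coefficients, threshold classification with confusion-matrix
    metrics and ROC/AUC, a synthetic cohort generator for validation, and a
    reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, jsonlite, yaml
Suggests: testthat (>= 3.0.0), pROC, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
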