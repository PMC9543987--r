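Package: MultiMorbML
Title: Multilabel Machine Learning for Multimorbidity Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting multimorbidity (the co-occurrence of two or
    more chronic conditions) with multilabel classifiers. Provides a
    participant-by-condition multilabel data container with CSV ingestion,
    fold-safe imputation and encoding; example-based multilabel evaluation
    metrics (Hamming loss, subset accuracy, accuracy, F-measure); imbalance
    characterization (label cardinality, density, per-label imbalance ratio,
    MeanIR) with IRLbl-driven random oversampling (ML-ROS); problem
    transformation classifiers (binary relevance, classifier chain, dependent
    binary relevance) over pluggable random-forest and support-vector base
    learners; a multivariate random forest with a composite normalized Gini
    splitting rule and generalized permutation variable importance;
    information-gain feature ranking (BR+IG); a repeated stratified
    cross-validation harness with nested hyperparameter tuning; and a
    latent-factor generator of synthetic cohorts emulating a large Brazilian
    adult-health cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    ranger,
    e1071,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
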