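Package: i6maVote
Title: Majority-Voting Ensemble Prediction of Plant DNA N6-Methyladenine Sites
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies DNA N6-methyladenine (6mA) sites in fixed-length
    (41 nt) adenine-centered plant DNA windows. Provides six sequence
    feature encoders (mono- and di-nucleotide one-hot, accumulated mono-
    and di-nucleotide frequencies, and di-/tri-nucleotide physicochemical
    property descriptors), a five-learner ensemble classifier (random
    forest, linear discriminant analysis, multi-layer perceptron,
    stochastic-gradient-descent logistic regression, extreme gradient
    boosting) combined by majority voting, grid-search hyperparameter
    optimization, cross-validated evaluation with accuracy, Matthews
    correlation, sensitivity and specificity, and a synthetic-data
    generator that plants position-specific nucleotide enrichment so the
    full train/predict/evaluate cycle is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    MASS,
    nnet,
    ranger,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
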