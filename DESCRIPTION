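Package: imotifr
Title: DNA i-Motif Detection, Stability Scoring and AutoML Model Training
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects putative i-motif forming sequences (C-rich quadruplex
    motifs) in DNA under configurable structural constraints (C-tract count
    and length, side/middle loop bounds, greedy or minimal motif calls,
    overlap handling), resolves loop boundaries by an explicit placement
    objective, and scores candidates with a feature-based regression model
    predicting a quantitative stability label such as the transition pH.
    Includes a 33-dimensional sequence feature extractor, a bi-level AutoML
    engine (Tabu search over feature-selection by regressor combinations
    with Tree-structured Parzen Estimator hyperparameter tuning, R-squared
    objective), portable single-file model bundles for end-to-end
    prediction, genome-scale density statistics (C density, i-motifs per
    million nucleotides), and a synthetic-data generator producing
    motif-spiked genomes with ground truth and labelled feature-response
    training sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    methods,
    nnet,
    purrr,
    ranger,
    readr,
    rlang,
    rpart,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
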