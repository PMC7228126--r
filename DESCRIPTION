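Package: pseterm
Title: Prediction of Bacterial Transcription Terminators from Sequence Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A toolkit for classifying bacterial DNA sequences as
    rho-independent transcription terminators or background sequence. Provides
    five feature encoders (length-normalised position-weight-matrix log-odds
    scores, base-content statistics, per-position nucleotide property
    encodings, and parallel- and series-correlation pseudo K-tuple nucleotide
    composition), two-step feature selection (F-score or binomial-confidence
    ranking followed by incremental feature selection), repeated stratified
    cross-validation over a zoo of single and ensemble classifiers with
    grid search, and a synthetic generator of hairpin/poly-T terminator-like
    sequences so the whole pipeline runs offline. All user-facing functions
    take and return data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
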