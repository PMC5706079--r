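Package: profgram
Title: Profile Monogram and Bigram Features for DNA-Binding Protein
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts DNA-binding proteins from evolutionary sequence
    profiles. Parses HHblits '.hhm' profile files and PSI-BLAST ASCII
    position-specific scoring matrices (PSSMs), converts both to linear
    substitution-probability matrices, and summarises each protein as
    monogram (20), bigram (400) or combined (420) feature vectors.
    Provides maximum-margin classifiers (linear and RBF kernel SVM) and
    ensemble comparators (Random Forest, AdaBoost), an evaluation suite
    (accuracy, sensitivity, specificity, MCC, auROC, auPR) under
    stratified 10-fold cross-validation and jack-knife protocols, a
    synthetic profile generator with controllable class separation for
    end-to-end testing without external databases, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
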