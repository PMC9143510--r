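Package: phenodnn
Title: Deep Feedforward Classification of Host Phenotype from Taxonomic
    Abundance Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts taxonomic abundance profiles (generic OTU tables,
    Kraken2 report files, or MetaPhlAn-style merged tables) into filtered,
    cumulative-sum-scaling normalized feature matrices, trains a configurable
    deep feedforward network to predict host phenotype, tunes it with a
    randomized hyperparameter search with validation-accuracy early stopping,
    and classifies unlabeled samples with a saved model. Includes a seeded
    synthetic case/control profile generator for benchmarking, and the usual
    evaluation machinery (confusion matrix, precision/recall/F1, ROC/AUC,
    stratified cross-validation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    nnet,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
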