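Package: gwgendrug
Title: Genetic and Epigenetic Network Identification and Systematic Drug Combination Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Identifies genome-wide genetic and epigenetic networks (protein-protein
    interaction plus gene/lncRNA/miRNA regulatory networks) from expression data by
    constrained least-squares system identification, prunes false-positive edges by
    AIC order detection, extracts core networks by principal network projection
    (SVD node scoring at an 85% energy threshold), and compares disease versus
    control cores. Includes a deep neural network drug-target interaction
    classifier (standardization, PCA, a 618-512-256-128-64-1 network trained with
    Adam on binary cross-entropy, ten-fold cross-validation, ROC/AUC) and a
    drug-design-specification screen (regulation ability, LD50 toxicity, EC50
    sensitivity, side-effect count) that selects a multiple-molecule drug
    combination. Ships a synthetic-data module with planted ground truth so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    quadprog,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
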