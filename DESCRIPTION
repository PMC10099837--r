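Package: snprex
Title: Ranked SNP-Phenotype Association Extraction from Biomedical Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining sentence-level associations between single
    nucleotide polymorphisms (SNPs) and phenotypes from biomedical
    abstracts.  Implements a rule-based association classifier built on
    negation-scope position features and neutral-candidate detection, a
    modality-based supervised classifier that grades the certainty of
    positive associations (weak, moderate, strong), shallow machine
    learning baselines with inverse-frequency class weighting and grid
    search, an evaluation harness (precision/recall/F1, Cohen's kappa,
    ROC/AUC, stratified k-fold, paired significance tests), XML and JSONL
    corpus input/output, and a seeded generator of annotated synthetic
    corpora with a recorded ground-truth ledger.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    ranger,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    xml2
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
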