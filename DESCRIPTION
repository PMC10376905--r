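Package: myelotune
Title: Metaheuristic-Tuned Gradient Boosting for Myeloid Variant Pathogenicity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Classifies onco-somatic variants from targeted myeloid NGS panels
    as benign or pathogenic with a gradient-boosted tree model whose
    hyperparameters are tuned by metaheuristic search. Provides a 14-feature
    variant encoder (variant type, exon, allele frequencies, coverage,
    amino-acid identity and side-chain polarity codes, Grantham distance,
    variant-effect class), four bounded maximization metaheuristics
    (differential evolution, particle swarm optimization, a genetic algorithm,
    and simulated annealing) whose objective is mean accuracy under repeated
    stratified k-fold cross-validation, smoothed-bootstrap minority
    oversampling for the heavily imbalanced benign/pathogenic labels, a full
    binary-classification evaluation suite (confusion matrix, precision,
    recall, specificity, MCC, Cohen's kappa, ROC/AUC), a five-tier probability
    classification of predictions, and a seeded synthetic-cohort generator so
    the whole pipeline runs without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    caret,
    jsonlite,
    xgboost
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
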