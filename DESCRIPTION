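Package: evsig
Title: Proteo-Metabolomic Signature Discovery for Plasma Extracellular Vesicles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Biomarker-signature discovery for plasma extracellular-vesicle
    (EV) proteomics and targeted metabolomics. Implements a seeded synthetic
    cohort generator with known ground truth, readers for MaxQuant
    proteinGroups tables and generic feature tables, the preprocessing chain
    (missingness filtering, immunoglobulin removal, iterative random-forest
    imputation, log transformation with median centring, technical-replicate
    averaging), empirical-Bayes moderated t-statistics and classical tests,
    consensus feature selection by serial k-nearest-neighbour grids,
    L1-penalised logistic regression and random-forest importance,
    evaluation of signatures by unsupervised hierarchical clustering against
    a No-Information-Rate exact binomial null with Clopper-Pearson
    intervals, exhaustive grid search over candidate subsets, and
    multi-omic integration with Spearman similarity-matrix partitioning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    ranger,
    stats,
    utils,
    yaml
Suggests:
    limma,
    mclust,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
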