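Package: guildscope
Title: Gut Microbiome Co-Abundance Guild Analysis and Prospective Anemia
    Risk Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for genus-level gut microbiome cohort
    studies of gestational anemia: participant-flow exclusion cascades and
    descriptive cohort tables, alpha/beta diversity with rarefaction,
    UniFrac and PERMANOVA, LEfSe-style differential abundance with
    covariate-adjusted linear-model confirmation, Kendall co-abundance
    group (guild) discovery with permutation-based cluster-number
    selection, lasso-regularized partial-correlation networks selected by
    EBIC, taxon-clinical correlation structure, and discovery/validation
    case prediction with ROC/AUC and DeLong confidence intervals. Includes
    a seeded synthetic-cohort generator with planted block-correlated
    compositional structure so every stage is testable against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ape,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    glmnet,
    pROC,
    phyloseq,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'cag.R'
    'clinassoc.R'
    'cohort.R'
    'diffabund.R'
    'diversity.R'
    'guildscope-package.R'
    'predict.R'
    'synthio.R'
    'tabio.R'
    'utils.R'
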