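Package: qsarStack
Title: Two-Source Bioactivity Curation, Stacked-Ensemble QSAR Modeling, and
    Shapley Explanation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for building quantitative structure-activity relationship
    (QSAR) models of receptor binding affinity (pKi) from multi-source ligand
    bioactivity records. Implements a reproducible curation procedure for
    merging two bioactivity sources with per-source deduplication and
    difference-threshold resolution of cross-source duplicates; a native
    2D molecular descriptor engine emitting the standard 1613-column 2D
    descriptor schema; drug-likeness profiling (Lipinski rule of five, Veber
    rules), Tanimoto similarity and correlation analysis; a four-stage
    automated modeling workflow (feature selection, algorithm selection,
    random hyperparameter search, super-learner stacking with a non-negative
    regularized linear metalearner) evaluated by 10-fold cross-validation;
    and exact or sampling-based Shapley-value attribution with importance
    ranking and dependence profiles. Seeded synthetic-data generators provide
    ground-truth test inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    igraph,
    glmnet,
    ranger,
    xgboost,
    nnet,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Cheminformatics, MachineLearning, Regression
RoxygenNote: 7.3.3
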