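Package: esis
Title: Model-Free Sure Independence Screening for Right-Censored Survival Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Kernel-based sure independence screening for high-dimensional
    right-censored outcomes. Genes (or other features) are ranked by the
    ECCFIC correlation, a kernel dependence measure between the
    Kaplan-Meier-transformed observed survival time and the rank-transformed
    feature, estimated with a Nadaraya-Watson plug-in smoother. Includes the
    screening driver with the usual n/log(n)-type screening sizes, a
    synthetic-data generator with known active gene sets for power studies,
    and a downstream risk-stratification stage (stratified train/test split,
    penalized Cox risk scores via glmnet, median dichotomization, log-rank
    comparison). Expression data are carried in SummarizedExperiment objects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    survival,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Survival, GeneExpression, FeatureExtraction, DimensionReduction
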