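Package: owclust
Title: Outcome-Weighted Integrative Clustering of Multimodal Radiomic Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers prognostic phenotypic subtypes from multimodal feature
    matrices (for example CE-T1 and T2FLAIR radiomic blocks) by outcome-weighted
    integrative clustering: per-feature univariate Cox log-hazard weights scale
    a Euclidean metric, per-modality distances are averaged, and cross-validated
    k-means with consensus voting yields subtype labels. Includes cluster-number
    selection by the clustering prediction index and the gap statistic, subtype
    evaluation statistics (contingency tables, Kaplan-Meier/log-rank with a
    five-year cutoff, multivariable Cox with Schoenfeld diagnostics and events
    per variable), Z-score/hypergeometric feature-enrichment rules, lasso
    stability selection with a repeated-split multi-classifier benchmark for
    binary molecular markers, pathway-activity scoring by a multivariate linear
    model on pathway-gene weights, and a synthetic-cohort generator that
    emulates the assumed data structure for testing every stage.
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
    multcomp,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
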