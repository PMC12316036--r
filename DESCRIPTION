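Package: reposcreen
Title: Transcriptional Reversal Screening and Fingerprint QSAR for Drug Repositioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end computational drug-repositioning funnel for
    neuroprotection discovery. Builds disease gene signatures from microarray
    expression cohorts (log2 quantile normalisation, probe collapse, moderated
    t-tests, multi-cohort intersection), scores compound perturbation profiles
    for transcriptional reversal of the disease signature with
    Kolmogorov-Smirnov connectivity enrichment, predicts compound potency
    (pEC50) with a random-forest / support-vector / gradient-boosting ensemble
    on molecular fingerprints tuned by a tree-structured Parzen estimator,
    gates predictions by a Tanimoto applicability domain, and explains them
    with exact tree Shapley values and kernel SHAP mapped back to molecular
    substructures. Ships synthetic-data generators with planted ground truth
    so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    limma,
    ChemmineR,
    ChemmineOB,
    randomForest,
    e1071,
    xgboost,
    data.table,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
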