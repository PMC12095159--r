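Package: pwabs
Title: Proteome-Wide Autoantibody Screening Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for serum autoantibody profiling on protein
    microarrays: control-spot normalization of per-spot fluorescence to
    autoantibody levels in arbitrary units (AU), volcano-style differential
    elevation screening (Mann-Whitney U plus fold change), a cross-validated
    classifier bench with feature-importance consensus selection, a small
    fully connected network for three-class dementia classification with
    one-vs-rest ROC and precision-recall evaluation, clinical trait
    association (Spearman correlation, adjusted regression), and
    cross-reactivity screening by global-alignment percent identity.
    Includes a seeded synthetic-cohort generator with planted group effects
    and a ground-truth ledger for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    glmnet,
    e1071,
    randomForest,
    rpart,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
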