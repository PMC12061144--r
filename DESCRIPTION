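Package: invrisk
Title: Niche-Transfer Invasion Risk Assessment with Ensemble Species
    Distribution Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the invasion risk of a species outside its
    native range by transferring ensemble species distribution models (SDMs)
    between regions. Implements spatial thinning of occurrence records,
    permutation-based predictor importance with Pearson collinearity pruning,
    multi-algorithm ensemble SDMs with pseudo-absences, repeated 70/30
    validation with TSS/AUC quality gates, maximum sensitivity-plus-specificity
    (MSS) threshold binarization, null-model significance testing, and a
    range-shift decomposition of an introduced-versus-native pair of binary
    range maps into expansion, stabilization, and unfilling components with
    the range ratio (RR) and index of range similarity (IRS). A virtual-species
    simulator with known ground truth supports end-to-end validation of the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    geosphere,
    jsonlite,
    yaml,
    nnet,
    rpart,
    MASS,
    glmnet,
    ranger,
    mgcv,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr
Config/testthat/edition: 3
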