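Package: flavorcast
Title: Multi-Label Flavor Profile Prediction from Molecular Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Predicts seven binary flavor labels (bitter, floral, fruity,
    off-flavor, nutty, sour, sweet) with probabilities for molecules given
    as isomeric SMILES. Provides the full workflow: curation of raw
    flavor-compound tables into labelled records, featurization as filtered
    physicochemical descriptors or radius-2 circular fingerprints,
    imbalance correction by SMOTE oversampling or k-means cluster-centroid
    undersampling, per-flavor binary classifier training with
    cross-validated grid search, a metric suite (recall, specificity, ROC
    AUC, majority-class bias, overfit score) with feature-importance and
    fingerprint-bit fragment analysis, and a lookup-and-predict deployment
    pipeline. A rule-labelled synthetic molecule generator with
    configurable class imbalance and label noise supports fully offline
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    ranger,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
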