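Package: pharmfunnel
Title: Pharmacophore-Based Virtual Screening Funnel with ML Triage and
    Trajectory Energetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A staged virtual-screening funnel for G-protein-coupled
    receptor agonist discovery: five-feature pharmacophore perception and
    k-of-n distance-constraint matching, decoy-set validation with
    enrichment-factor and Guener-Henry statistics, EC50-thresholded
    machine-learning triage over descriptor and fingerprint features,
    Tanimoto fingerprint novelty filtering, molecular-dynamics trajectory
    analytics (superposition RMSD, RMSF, hydrogen bonds, contacts,
    covariance PCA and Boltzmann-inverted free-energy landscapes) and
    MM-PBSA-style energy-ledger scoring against a control compound.
    Synthetic-data generators with planted ground truth exercise every
    stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    bio3d,
    methods,
    stats,
    utils,
    randomForest,
    ranger,
    xgboost,
    e1071,
    rpart,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
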