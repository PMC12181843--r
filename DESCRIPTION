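Package: dmrpipe
Title: Discovery, Validation and Diagnostic Modelling of Differentially
    Methylated Regions from Bisulfite Sequencing Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Blood-based DNA methylation marker analysis from bisulfite
    sequencing methylation calls. Provides per-CpG differential methylation
    calling under coverage, effect-size and q-value thresholds; sliding-window
    detection of differentially methylated regions (DMRs) with a brute-force
    reference implementation; covariate-adjusted burden score tests with
    false-discovery-rate control and cross-cohort meta-analysis for targeted
    amplicon validation; and exhaustive-combination elastic-net logistic
    modelling with cross-validated AUC for diagnostic marker-panel selection.
    A beta-binomial cohort simulator with configurable implanted DMRs,
    overdispersion and capture- or amplicon-like coverage supplies fully
    specified synthetic cohorts for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    data.table,
    glmnet,
    pROC,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    optparse
Config/testthat/edition: 3
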