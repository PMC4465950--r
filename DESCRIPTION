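Package: rotsf
Title: Rotation Survival Forests for Right-Censored Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Rotation survival forest ensembles for right-censored
    time-to-event data. Each ensemble member trains a log-rank survival
    tree with Nelson-Aalen leaf cumulative hazard estimates on a
    double-bagged, block-PCA-rotated view of the covariates. Includes
    out-of-bag permutation variable importance on the mean C-index
    decrease scale, Harrell's concordance index, Friedman and Nemenyi
    rank tests for model comparison, a proportional-hazards simulator
    with calibrated censoring, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
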