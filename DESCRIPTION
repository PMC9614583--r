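Package: infantfc
Title: Seed-Based Functional Connectivity Group Classification for Infant Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Pipeline for detecting group differences in seed-based
    resting-state functional connectivity (FC) patterns between infant
    cohorts (e.g. infants with vs without a familial history of
    developmental dyslexia). Per-subject parcellated BOLD time series are
    converted to seed-specific Fisher-z FC patterns; a bootstrapped,
    balanced linear support-vector-machine analysis with
    leave-one-pair-out (or stratified k-fold) cross-validation and a
    paired within-iteration permutation null quantifies how well each
    seed's FC pattern separates the groups; seeds are selected by the
    conjunction of a Monte-Carlo family-wise corrected paired test, a
    positive confidence interval on the true-minus-null accuracy
    difference, and a Cohen d threshold. Classifier weights are converted
    to forward-model activation patterns (Haufe transformation) for
    path-level interpretation. Includes framewise-displacement motion QC,
    cohort demographic tables, and a synthetic two-group cohort generator
    with controllable seed-targeted effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    e1071,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
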