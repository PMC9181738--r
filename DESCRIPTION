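Package: dualbench
Title: Double-Fold Perioperative Risk Models and Center Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Develops paired pre-operative and post-operative logistic
    risk models for in-hospital mortality after cardiac surgery and
    benchmarks centers and patient subgroups through the relative
    difference in expected deaths d = (e_post - e_pre)/e_pre, with
    percentile bootstrap confidence intervals. Includes the full model
    development protocol (rare-variable screening, bivariate screening,
    piecewise-linear logit transforms, forward/backward stepwise
    selection, categorical level merging), model evaluation (ROC/AUC and
    a polynomial-recalibration calibration belt and test), cohort
    filtering with flowchart reporting, and a synthetic multi-center
    cohort generator with known ground truth for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
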