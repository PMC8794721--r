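Package: smrflow
Title: Standard Metabolic Rate from Intermittent-Flow Respirometry with
    Mixed-Model Inference and Power Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for intermittent-flow
    respirometry studies of standard metabolic rate (SMR) in small fish.
    Generates cohorts and raw oxygen-concentration traces with known ground
    truth, extracts per-cycle oxygen-consumption slopes, corrects for
    microbial background respiration, estimates SMR by the mean of the
    lowest normal distribution (MLND) of a Gaussian mixture fitted by EM,
    fits allometric linear mixed models with crossed family and batch random
    effects (Satterthwaite tests, AIC comparison, held-out-batch
    cross-validation), and bounds minimum detectable genotype effect sizes
    by simulation-based power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    lme4,
    lmerTest,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    mclust,
    jsonlite,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
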