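Package: srmsig
Title: Plasma SRM Biomarker Signature Discovery and Evaluation
Version: 0.1.0
Authors@R:
    person("srmsig", "maintainers", email = "srmsig@example.org", role = c("aut", "cre"))
Description: A tested pipeline for targeted (selected reaction monitoring)
    plasma proteomics biomarker studies. Implements two-stage normalization
    against stable-isotope reference peptides and spiked standard proteins,
    additive-model protein summarization, differential abundance with
    Benjamini-Hochberg adjustment, limit-of-detection imputation, consensus
    cross-validated signature discovery with stepwise AIC logistic
    regression, exhaustive bootstrapped subset search, and ROC-based
    evaluation with stratified subgroup analyses. Ships a synthetic cohort
    generator that emulates the data structure of a phased case-control
    plasma study so that every stage can be scored against planted ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
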