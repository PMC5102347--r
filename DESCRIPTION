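Package: stagecost
Title: Stage-Stratified Long-Term Hospital Costs and Survival for Endometrial Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating long-term secondary-care costs of endometrial
    cancer by stage at diagnosis from hospital-episode-style activity data.
    Includes a synthetic cohort generator calibrated to published stage-specific
    treatment patterns, an episode-to-cost engine implementing casemix (HRG)
    tariff rules with excess bed days, dominant-episode spell costing and
    discounting, multiple imputation of administratively censored cost histories
    by chained equations with predictive mean matching, Rubin-rule pooling,
    bootstrap confidence intervals for mean costs, and Kaplan-Meier and
    cause-specific Cox survival analysis with proportional-hazards diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    survival,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
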