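Package: indebtr
Title: Computational Models of Indebtedness in Social Exchange
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Utility-based models of how beneficiaries respond to favors:
    appraisal formation (second-order beliefs about expected repayment and
    perceived care), reciprocity decisions traded off between self-interest,
    communal concern and obligation, and binary help-acceptance choices.
    Provides a synthetic interpersonal-task simulator, per-participant model
    fitting by sum-of-squared-error or maximum likelihood with AIC model
    comparison across an alternative-model family, parameter-recovery and
    model-simulation tools, mixed-effects linkage of model appraisals to
    trial-wise self-reports, and a neural-utility pipeline in which
    cross-validated pattern-regression predictions of the appraisals replace
    the model terms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
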