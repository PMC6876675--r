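Package: ipwdid
Title: Inverse-Probability-Weighted Difference-in-Differences for
    Household Panel Impact Evaluation
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quasi-experimental impact evaluation of
    nutrition-sensitive agricultural interventions on two-wave household
    panels. Builds composite nutrition and food-security indicators
    (inverse-probability-weighted knowledge exam scores, household and
    child dietary diversity, food consumption score, months of inadequate
    household food provisioning), fits a probit participation model with
    average marginal effects and common-support trimming, matches or
    weights control households on the propensity score (nearest
    neighbour, radius, Epanechnikov kernel) with covariate balance
    diagnostics, and estimates treatment effects by weighted
    difference-in-differences with village-clustered standard errors and
    placebo checks. A synthetic household-panel generator with known
    selection and outcome structure makes the whole pipeline testable
    without survey microdata.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
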