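Package: gtbiomark
Title: Group Testing Designs for Prospective-Retrospective Biomarker Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and estimation tools for evaluating dichotomous prognostic
    and predictive biomarkers with group testing (physical pooling of archived
    specimens) in prospective-retrospective clinical studies. Provides
    maximum-likelihood estimation of stratum-specific marker prevalence from
    pooled binary assay results, with optional adjustment for assay
    misclassification via known sensitivity and specificity; per-assay Fisher
    information and cost-efficiency-optimal pool-size selection; conversion of
    prevalence estimates to association measures (log odds ratio, log ratio,
    risk difference) and treatment-by-marker interaction coefficients under
    logit, log, and identity links via Bayes' theorem, with delta-method and
    bootstrap standard errors; and a Monte-Carlo simulator comparing standard,
    random-sampling, and group-testing designs by relative efficiency and
    relative cost-efficiency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
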