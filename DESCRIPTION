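Package: benzrisk
Title: Leukemia Risk Assessment for Occupational Benzene Exposure via the
    Linearized Multistage Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits the linearized multistage (LMS) quantal dose-response model
    to grouped cohort leukemia incidence data by constrained binomial maximum
    likelihood, and turns airborne or urinary-biomarker benzene exposure
    measurements into excess leukemia risk estimates. Includes the ln-ln
    regressions linking urinary S-phenylmercapturic acid (S-PMA) and
    trans,trans-muconic acid (t,t-MA) to airborne benzene with a smoking
    covariate, inversion of those regressions for biomarker-based risk
    assessment, the EPA inhalation-unit-risk model and the Singapore
    semi-quantitative risk matrix for cross-validation, sample quality
    control with limit-of-detection handling, cumulative-exposure
    aggregation and quartile grouping, an ANOVA trend test, and a synthetic
    worker-data generator so the whole pipeline is testable without access
    to the original worker records.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
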