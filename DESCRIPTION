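Package: attriweight
Title: Non-Response Weights for Attrition in Longitudinal Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Develops and evaluates inverse-probability-of-participation
    (non-response) weights for longitudinal cohort studies with attrition.
    Implements theme-wise LASSO variable screening with ROC-gated forward
    inclusion, a-priori (curated) participation models, discrimination and
    calibration assessment (AUROC with DeLong confidence intervals and paired
    tests, Hosmer-Lemeshow goodness of fit, mean calibration, loess calibration
    curves), stabilized and percentile-truncated weights, and standardized
    difference balance diagnostics across follow-up waves. Ships a synthetic
    multi-wave pregnancy-cohort generator with covariate-driven dropout so the
    whole pipeline is testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    broom,
    withr
Config/testthat/edition: 3
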