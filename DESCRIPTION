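Package: bcsdqi
Title: Decision Quality Audit for Breast Cancer Surgery Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scoring, concordance modelling and psychometric evaluation for a
    breast cancer surgery decision quality instrument. Implements the bespoke
    knowledge-score rules (one point per correct response, "I am not sure"
    scored incorrect, missing responses scored 1/k, multi-part items weighted
    to sum to one, a 50% completion floor), a goals-to-treatment concordance
    score built from EM imputation of goal ratings under joint normality and
    a multivariable logistic treatment model with a rank-based c-statistic,
    and the full validation battery: test-retest intraclass correlation,
    content, discriminant and predictive validity, and feasibility metrics.
    Includes a calibrated synthetic-cohort generator (patients, providers,
    healthy controls, retest waves) so the whole audit pipeline can be
    exercised end to end without access to the original registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
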