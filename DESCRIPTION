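Package: nbrcea
Title: Person-Level Cost-Effectiveness Analysis via Net Benefit Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for person-level cost-effectiveness analysis of cancer
    treatment strategies from administrative cohort data, built around the
    net benefit regression framework. Provides a synthetic cohort generator
    emulating registry-linked person-level records (confounded treatment
    assignment, survival, per-year cost ledgers, monotone missingness),
    monotone multiple imputation by sequential logistic regression with
    Rubin's-rules pooling, life-table effectiveness measures (potential
    years of life lost and quality-adjusted life years lost, with
    discounting), cost deflation and currency conversion, propensity-score
    adjusted net benefit regression over a willingness-to-pay grid,
    incremental cost-effectiveness ratios with confidence bounds from
    incremental-net-benefit sign crossings, cost-effectiveness
    acceptability curves, and efficiency-frontier reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
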