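Package: rwcea
Title: Real-World Cost-Effectiveness Analysis with Genetic Matching and
    Censoring-Weighted Cost Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-based cost-effectiveness analysis of a
    two-arm diagnostic or treatment strategy observed in administrative
    data: genetic-algorithm covariate matching on a generalized weighted
    Mahalanobis distance with exact-matching strata and lexical
    optimization of bootstrapped balance p-values; covariate balance
    diagnostics (standardized mean differences, variance ratios,
    Kolmogorov-Smirnov statistics); Kaplan-Meier and Weibull
    proportional-hazards survival estimation; partitioned estimation of
    censored mean costs and life-years over monthly intervals with
    inverse probability of censoring weights from a reverse Kaplan-Meier
    estimator; and nonparametric paired bootstrap of incremental net
    monetary benefit with bias-corrected intervals, cost-effectiveness
    acceptability curves, and cost-effectiveness-plane summaries.
    Includes a synthetic administrative-cohort generator with a known
    data-generating process for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tools,
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
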