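Package: psmcea
Title: Partitioned Survival Cost-Effectiveness Modelling of Trastuzumab
    Deruxtecan for HER2-Low Advanced Breast Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Three-state partitioned survival cost-effectiveness analysis
    comparing trastuzumab deruxtecan (T-DXd) with physician's-choice
    chemotherapy in previously treated HER2-low advanced breast cancer.
    Provides parametric survival curve objects for seven families with
    censored maximum-likelihood fitting and information-criterion ranking,
    reconstruction of pseudo individual-patient data from digitized
    Kaplan-Meier curves with numbers at risk, a weekly-cycle partitioned
    survival engine with discounting, cost and QALY accrual with incremental
    cost-effectiveness measures (ICER, INHB, INMB), one-way and probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves,
    threshold price search, hazard-ratio-based subgroup analysis, and a
    synthetic trial generator for end-to-end validation without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    flexsurv,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
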