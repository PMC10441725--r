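Package: oncocea
Title: Cost-Effectiveness Modelling of Maintenance Olaparib plus
    Bevacizumab in Advanced Ovarian Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A partitioned-survival cohort model for the health-economic
    evaluation of first-line maintenance olaparib plus bevacizumab versus
    bevacizumab alone in advanced ovarian cancer, parameterized per
    molecular subgroup (overall, BRCA-mutated, HRD-positive,
    HRD-positive/BRCA-wild-type). Provides parametric survival curves
    with maximum-likelihood fitting and AIC/BIC model selection,
    right-censored synthetic individual-patient-data generation,
    per-cycle cost and QALY accrual with discounting and half-cycle
    correction, incremental cost-effectiveness ratios and net monetary
    benefit, and one-way (tornado), two-way and probabilistic
    sensitivity analyses with cost-effectiveness acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    flexsurv,
    jsonlite,
    stats,
    survival,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
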