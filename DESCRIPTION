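Package: uccea
Title: Cost-Effectiveness Modelling of First-Line Regimens in Advanced
    Urothelial Carcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A partitioned-survival cohort model comparing first-line
    enfortumab vedotin plus pembrolizumab against nivolumab plus
    gemcitabine-cisplatin for locally advanced or metastatic urothelial
    carcinoma, from the US and Chinese healthcare payer perspectives.
    Provides pseudo individual-patient-data reconstruction from digitized
    Kaplan-Meier curves (Guyot algorithm), parametric survival fitting over
    six candidate families with AIC/BIC selection, a 21-day-cycle cohort
    trace over a 50-year horizon with half-cycle correction and discounting,
    country-specific costing with vial rounding and treatment caps, ICER and
    net-monetary-benefit computation, and deterministic (tornado),
    probabilistic (CEAC) and drug-price threshold sensitivity analyses.
    Includes a synthetic-data generator for right-censored survival samples
    and digitized-curve fixtures with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    flexsurv,
    survival,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
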