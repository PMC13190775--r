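Package: zostercea
Title: Cost-Effectiveness Modelling of Herpes Zoster Vaccination
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A Markov cohort model for the economic evaluation of the two-dose
    adjuvanted recombinant zoster vaccine (RZV) against no vaccination in an
    elderly population, from a healthcare-payer perspective. Eight five-year
    age cohorts (65 to 100+) are simulated in annual cycles to age 105,
    accumulating herpes zoster (HZ) and post-herpetic neuralgia (PHN)
    episodes, quality-adjusted life years and direct healthcare costs.
    Vaccine protection follows either a trial-based efficacy curve or an
    observational effectiveness curve with annual waning. The package
    computes incremental cost-effectiveness ratios (ICERs), threshold
    vaccine prices at a given willingness-to-pay, population-weighted
    combined-cohort ICERs, one-way sensitivity analyses, probabilistic
    sensitivity analysis with credible intervals, cost-effectiveness
    acceptability curves and tornado summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
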