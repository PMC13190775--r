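# zostercea

A Markov cohort model for the health-economic evaluation of two-dose
vaccination with the adjuvanted recombinant zoster vaccine (RZV) against no
vaccination in the Swedish elderly population, from a healthcare-payer
perspective. It is written for health economists and public-health analysts
who need a transparent, scriptable implementation of a zoster
cost-effectiveness model — one whose every input, assumption and sensitivity
switch is inspectable and testable rather than buried in a spreadsheet.

## The model

Eight five-year age cohorts (65–69 through 100+), each split by sex, are
projected in annual cycles from the band's lower age to age 105. In each
cycle, deaths occur first at the all-cause probability `q(a, s)`; survivors
face a herpes zoster (HZ) episode with probability
`inc(a, s) · m(t)`, where the vaccinated arm's incidence multiplier is

```
m(t) = 1 − c · [ q · VE₂(t) + (1 − q) · VE₁(t) ]
```

with coverage `c = 0.63`, second-dose compliance `q = 0.749`, two-dose
protection `VE₂(t)` waning linearly by 3.1 percentage points per year from
97.7% (trial-based scenario I) or 79.2% (observational scenario II), and a
one-dose effect `VE₁` applied in year 1 only. Recurrent episodes carry the
same probability as first ones, so the whole surviving cohort remains at
risk every cycle.

An episode bundles sub-annual tunnel states: one acute month with an
age-group-specific pain-severity mix, and — with the age-specific
post-herpetic neuralgia (PHN) probability — a 7/10/13-month pain spell. QALY
losses are multiplicative: a pain state of severity `s` retains fraction
`m(s)` of the age- and sex-specific baseline utility
(mild 0.91, moderate 0.71, severe 0.32), so a `D`-month spell loses
`u · (1 − m(s)) · D/12` QALYs. Costs per episode combine mean primary-care,
outpatient and inpatient visits by ICD-10 category with 2021 unit costs,
plus antiviral and analgesic medication. Both doses are delivered and costed
in cycle 1; cycle `t` is discounted by `1.03^−(t−1)`.

Outputs are incremental QALYs, net costs, the ICER (EUR per QALY), the
threshold vaccine price at a willingness-to-pay, population-weighted
combined-cohort ICERs, one-way sensitivity analyses, a 1,000-draw
probabilistic sensitivity analysis with 95% credible intervals, CEAC curves
and tornado tables.

## Worked example

```r
library(zostercea)

params <- basecase_fixture()
r <- run_comparison(65, params, scenario = "rct")
r
#> <ce_result> cohort 65+ scenario rct
#>   HZ episodes averted: 27,144; PHN averted: 3,876
#>   incremental QALYs: 737
#>   vaccination cost: 109,288,306; HZ cost offset: 11,952,829
#>   net cost: 97,335,477
#>   ICER: 132,070 EUR/QALY

threshold_price(params, 65, "rct", wtp = 80000)
#> <threshold_price_result> WTP 80,000 EUR/QALY
#>   threshold price per dose: 111.93 EUR (doses delivered: 595,252)
```

Reading: vaccinating 63% of the 540,220 Swedes aged 65–69 (with 74.9%
completing both doses) costs ~109 M EUR, averts ~27,000 HZ episodes over the
cohort's remaining lifetime and gains 737 discounted QALYs, at a net cost of
~97 M EUR — an ICER of ~132,000 EUR per QALY at the 176.4 EUR list price,
well above the 80,000 EUR willingness-to-pay. The price per dose would have
to fall to ~112 EUR (scenario I) or ~78 EUR (scenario II) to be
cost-effective.

The command line mirrors the package:

```sh
Rscript inst/cli/zostercea basecase --cohort 65-69 --scenario both --out out/
Rscript inst/cli/zostercea psa --seed 7 --draws 1000 --out out/
```

## Package tour

| | |
|---|---|
| `basecase_fixture()`, `fixture_manifest()` | shipped base-case inputs with per-field provenance |
| `load_parameters()`, `write_parameters()` | YAML config round trip, validation |
| `ve_two_dose()`, `build_protection_profile()` | efficacy trajectories and incidence multipliers |
| `run_cohort()`, `run_comparison()` | the Markov engine and arm comparison |
| `threshold_price()`, `combined_cohort_icer()`, `price_sweep()` | price and aggregation analyses |
| `run_one_way()`, `run_psa()`, `ceac()`, `tornado()` | sensitivity analyses |
| `random_parameter_set()` | valid random inputs for property testing |

See `vignettes/model-methods.Rmd` for the modelling assumptions, parameter
provenance (including the three reconstructed inputs) and known limitations.
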