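---
title: "Model structure, inputs and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, inputs and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zostercea)
```

# The decision problem

`zostercea` compares two strategies for the Swedish population aged 65 and
over: a two-dose program with the adjuvanted recombinant zoster vaccine
(RZV), and no vaccination. The payoff space is discounted quality-adjusted
life years (QALYs) and discounted direct healthcare costs in 2021 euro, from
a healthcare perspective (no productivity losses — the population is
retired). The headline outputs are the incremental cost-effectiveness ratio
(ICER) at the 176.4 EUR list price and the *threshold price*: the price per
dose at which the ICER equals a willingness-to-pay of 80,000 EUR per QALY.

# Model structure

Each of the eight five-year age cohorts (65–69 … 100+) is simulated
separately by sex, in annual cycles from the band's lower age to age 105.
A cycle applies, in order:

1. **Death** at the all-cause probability of the current age band and sex.
   Herpes zoster (HZ) itself carries no excess mortality in the model.
2. **HZ episode** among survivors, at the age- and sex-specific annual
   incidence multiplied by the arm's protection multiplier. Recurrence is
   treated identically to first occurrence (the incidence source counts
   both), so the whole surviving cohort stays at risk every cycle.
3. **Accrual**: survivors earn one year of baseline utility; each incident
   episode immediately subtracts its expected QALY loss and adds its
   expected cost.

An episode is a bundle of sub-annual tunnel states rather than a persistent
Markov state: one acute month with an age-group pain-severity mix, plus —
with the age-specific probability of post-herpetic neuralgia (PHN) — a
severity-dependent pain spell of 7, 10 or 13 months. Individuals return to
baseline utility immediately afterwards.

Deaths-first ordering is deliberate: it is the conservative convention (no
episodes among those who die in the cycle), it keeps occupancy conservation
exact (`alive(t) = alive(1) − Σ deaths`), and because HZ carries no
mortality the ordering has only a second-order effect on results.

**Aging through bands.** Each cohort starts at its band's lower age (65,
70, …) and tracks integer age every cycle, switching parameter bands as age
crosses their boundaries; the printed cohort size covers the whole band.
The alternative — freezing each cohort at its band's parameters — would
understate both mortality and the age gradient of incidence. Starting
everyone at the band's lower bound does overstate person-years relative to
a cohort whose true ages are spread across the band; this is visible as a
~10–15% overshoot in lifetime case counts relative to an age-spread start
and is the price of keeping the cohort definition simple and reproducible.

**Onset-cycle attribution.** PHN spells of 10 or 13 months overrun the
annual cycle, but all losses and costs of an episode are charged to the
onset cycle at its discount factor. The error is bounded by one year of
discounting (3%) on at most a few months of spillover — well below other
input uncertainties — and avoids fractional tunnel-occupancy bookkeeping.
No half-cycle correction is applied anywhere.

**Discounting** uses `(1 + r)^−(t−1)` with `r = 0.03`, so the first model
year is undiscounted; both doses are delivered, and costed, in cycle 1.

# Vaccine protection

The two-dose protection curve starts at 97.7% (scenario `rct`, trial-based
efficacy) or 79.2% (scenario `observational`, register-based effectiveness)
in year 1 and declines *linearly by 3.1 absolute percentage points per
year*, floored at zero. Three points deserve emphasis:

* Waning is absolute, not relative: the 3.1 figure is defined as the
  average first-decade decline of the trial curve (97.7% → 69.8% over nine
  waning steps), which a relative rule would not reproduce.
* The trial curve's individual year-2…10 values are not published in the
  main source; the linear reconstruction can be overridden by an explicit
  `ve_vector` in the configuration, and the waning rule continues from the
  vector's last value.
* The one-dose effect applies in year 1 only (its longer-term waning is too
  uncertain to extrapolate). Its year-1 value is **not published anywhere in
  the main source**; the fixture default of 0.70 sits between published
  single-dose estimates and is flagged as a reconstruction in
  `fixture_manifest()`. Only the 25.1% of vaccinees who skip dose 2 are
  affected.

The `post10 = "zero"` switch implements the conservative
no-protection-after-year-10 sensitivity analysis.

Coverage (63%) and compliance (74.9%) enter only through the
population-average multiplier `m(t) = 1 − c(q·VE₂(t) + (1−q)·VE₁(t))`.
A consequence worth knowing: with this linear structure the ICER is
*invariant to first-dose coverage* — coverage scales doses, averted cases
and QALY gains equally — so coverage sensitivity analyses affect budget
impact, not cost-effectiveness.

# Inputs and their uncertainty distributions

All inputs live in one YAML document (`inst/extdata/basecase.yaml`); every
value is validated on load (probability bounds, Beta feasibility,
multiplier ordering, monotone mortality, distribution sums). The acute
pain-severity row for under-70s sums to 1.01 as printed and is renormalized
on load (tolerance 0.02).

| group | values (base case) | PSA distribution |
|---|---|---|
| cohort sizes, death probabilities | per band × sex | fixed |
| HZ incidence | 0.0042–0.0131 per year | fixed |
| PHN proportion given HZ | 0.12–0.16 (SE 0.015–0.022) | Beta (mean, SE) |
| pain-severity mixes | per age group; PHN 0.89/0.11 | fixed |
| baseline utility | 0.57–0.78 (SE 0.01–0.027) | Beta (mean, SE) |
| pain multipliers | 0.91 / 0.71 / 0.32 | Beta (explicit shapes) |
| visit counts per episode | per ICD-10 category | Binomial(1000, mean/1000) |
| medication uptake, unit costs, program, discounting | see fixture | fixed |

Beta shapes for "mean (SE)" inputs come from the method of moments
(`beta_from_mean_se()`), the conventional CEA choice; where explicit shape
pairs are published (the pain multipliers) those are used directly.

The binomial visit-count distribution is applied literally as printed:
a draw is the success count of Binomial(1000, mean/1000), used as the
sampled mean visit count. Its expectation equals the reported mean but the
draws are integers, so for small means (e.g. 0.05 inpatient episodes) the
distribution is very coarse and dominates the spread of the cost offset in
the PSA. The incremental-QALY credible interval is unaffected (visits do
not touch QALYs). Visit counts are drawn once per PSA draw, not per cohort.

Two further reconstructions are flagged in the manifest:

* **Complication-category mix.** The share of HZ episodes falling in each
  ICD-10 category is not published. The fixture assigns 95% to
  uncomplicated B02.9 and splits the remaining 5% equally across
  B02.2/B02.3/B02.7/B02.8 (complications are described as rare). The mix is
  a configurable vector; its influence is easily explored with
  `modify_parameters()`.
* **Male 100+ incidence** is blank in the source and carried forward from
  the 95–99 value (436 persons; negligible).

The single published B02.9 outpatient cost (369 EUR) is used for all ages
and sexes, although the source describes it as age- and sex-specific; the
underlying registry values are not recoverable. Baseline utilities beyond
the 80+ band reuse the 80+ values. PHN-specific healthcare utilization
beyond the per-episode visit counts is likewise unpublished; the model's
absolute cost offset is therefore lower than the original analysis's, which
mainly lowers the threshold price of the observational scenario.

# Economic outputs

`incremental_result()` differences discounted totals; a non-positive QALY
gain flags the ICER as undefined (`NA`) rather than producing an infinity,
so aggregation fails loudly. The combined catch-up ICER is the
population-weighted *mean of per-cohort ICERs* — the aggregation rule used
for the published combined cohorts — with the pooled-sums ratio
(`pooled_icer()`) available as the alternative, since the two differ
whenever ICERs vary across cohorts.

`threshold_price()` exploits linearity of net cost in price
(`net(p) = doses·p + constant`, QALY gain price-free) to solve the
threshold in closed form, verifies it by re-running the model at the
solution (relative ICER error < 1e-6), and falls back to bisection if an
enabled add-on ever breaks linearity.

# Sensitivity analyses

`standard_one_way_scenarios()` builds the deterministic battery: discount
0%/5%, first-dose coverage 50%/70%, compliance 50%/100%, protection
truncation after year 10, PHN proportion at its 95% bounds, unit costs
±40% (all healthcare unit costs including administration; the vaccine price
itself is the quantity under negotiation and stays fixed). The published
PHN confidence bounds live only in supplementary material, so the package
reconstructs them as normal-approximation bounds, mean ± 1.96·SE — exact
for the symmetric intervals a meta-analysis on this scale produces.
Scenarios that need unpublished value sets (the stroke add-on, age-specific
efficacy vectors, alternative pain-decrement sets) are mechanically
supported — `one_way_scenario()` accepts user-supplied values — but ship
empty rather than with invented numbers.

The stroke add-on, when enabled with user values, converts each incident
episode into `(RR − 1) · p_stroke` excess first-year strokes, each charged
a per-stroke cost and one year at a stroke utility multiplier; it is off in
the base case because stroke sequelae (mortality, multi-year disability)
would need a richer model to be credible.

The PSA (`run_psa()`, default 1,000 draws) re-evaluates the full model per
draw. One master seed generates a deterministic substream seed per draw, so
individual draws can be reproduced in isolation and adding a parameter to
the draw step cannot silently shift other draws. Credible intervals are the
empirical 2.5th/97.5th percentiles of the incremental quantities (not of
the ICER ratio, whose per-draw distribution is heavy-tailed; both the
per-draw ICER mean and the ratio-of-means are reported).

# The synthetic parameter generator

`random_parameter_set()` perturbs every input within its type invariants
(probabilities clamped to [0, 1], mortality kept monotone by cumulative
maximum, severity mixes renormalized, Beta feasibility preserved, the
multiplier ordering restored by sorting). It emulates the *statistical
shape* of the real inputs — not their joint epidemiological plausibility —
so the property tests built on it demonstrate that the engine is
arithmetically sound (conservation, linearity, sign-correctness,
finiteness) on a broad input family, not that any particular random set
describes Sweden.

# Verification

The test suite checks the engine against independent oracles rather than
against itself: per-episode QALY losses and costs are re-derived by
exhaustive enumeration over every pathway combination, and cohort totals
are compared with a per-person stochastic microsimulation (10^6 individuals
on a three-cycle model in the acceptance suite, 2×10^5 in the unit tests)
within three Monte Carlo standard errors. Property tests run the full
battery on 100 random parameter sets over a shortened ten-cycle horizon to
keep the suite fast; the full model (41 cycles × 2 sexes × 2 arms) runs in
~15 ms, so all headline analyses use the complete horizon.

# Known limitations

* Cohorts start at their band's lower age (see above): absolute case counts
  and QALYs run high relative to an age-spread cohort; incremental ratios
  are much less affected.
* The one-dose effect, complication mix and trial-curve shape are
  reconstructions; results involving them carry that uncertainty even
  though each is individually small.
* The absolute cost offset omits unpublished PHN-specific utilization and
  age-specific B02.9 costs and is therefore conservative (too low), which
  raises ICERs and lowers threshold prices slightly.
* No vaccine side effects, no breakthrough-case utility differences, no
  indirect costs, no dynamic transmission (zoster is reactivation), and no
  HZ-attributable mortality.
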