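fixture_id: sweden-rzv-basecase-2021
checksum: 57003dcb50598dc96b13846ad5806107
provenance:
  - field: demography
    status: published
    note: 2021 population sizes and all-cause death probabilities per 5-year band and sex
  - field: incidence
    status: published
    note: annual HZ incidence probabilities per 5-year band and sex, regional healthcare data
  - field: incidence.p_hz_male.100+
    status: reconstructed
    note: not reported; carried forward from the 95-99 male value (0.0042)
  - field: phn
    status: published
    note: meta-analytic PHN proportions given HZ, mean and SE per band
  - field: hz_severity
    status: published
    note: acute pain mix by age group; under-70 row renormalized from printed sum 1.01
  - field: phn_severity
    status: published
    note: moderate 0.89 / severe 0.11; mild kept as structural state with zero mass
  - field: utility_baseline
    status: published
    note: EQ-5D population norms by band and sex, mean and SE
  - field: utility_multipliers
    status: published
    note: pain-state multipliers 0.91/0.71/0.32 with explicit Beta shapes
  - field: visits
    status: published
    note: mean healthcare visits per episode by ICD-10 category, Binomial(1000) PSA
  - field: uptake
    status: published
    note: antiviral 62%; analgesic 20% uncomplicated / 50% complicated
  - field: complication_mix
    status: reconstructed
    note: category shares not reported; 95% B02.9, remaining 5% split equally
  - field: costs
    status: published
    note: 2021 euro unit costs; single B02.9 outpatient value used for all ages/sexes
  - field: program
    status: published
    note: coverage 63%, second-dose compliance 74.9%
  - field: economics
    status: published
    note: 3% discount, WTP 80000 EUR/QALY, horizon to age 105
  - field: scenarios.rct.ve_year1
    status: published
    note: 97.7% year-1 two-dose efficacy, 3.1 pp annual waning
  - field: scenarios.observational.ve_year1
    status: published
    note: 79.2% year-1 two-dose effectiveness, 3.1 pp annual waning
  - field: scenarios.*.one_dose_ve_year1
    status: reconstructed
    note: one-dose year-1 effectiveness never reported; default 0.70, configurable
  - field: scenarios.rct.ve_years_2_10
    status: reconstructed
    note: linear decline at the stated 3.1 pp/yr average; explicit vector configurable
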