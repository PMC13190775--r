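# Base-case model configuration: Swedish RZV vs no vaccination, 2021 euro.
# Age-band order throughout: 65-69, 70-74, 75-79, 80-84, 85-89, 90-94, 95-99, 100+
demography:
  size_female: [272568.0, 275284.0, 251189.0, 159458.0, 100350.0, 52199.0, 15643.0, 2226.0]
  size_male: [267652.0, 260832.0, 231607.0, 131553.0, 66971.0, 25549.0, 5239.0, 436.0]
  p_death_female: [0.010, 0.016, 0.027, 0.049, 0.093, 0.167, 0.251, 0.353]
  p_death_male: [0.008, 0.013, 0.022, 0.042, 0.080, 0.153, 0.315, 0.434]
incidence:
  p_hz_female: [0.0071, 0.009, 0.0119, 0.0119, 0.0117, 0.0131, 0.011, 0.0083]
  # male 100+ is not reported; carried forward from 95-99 (reconstruction)
  p_hz_male: [0.0051, 0.0068, 0.0079, 0.0092, 0.0088, 0.0089, 0.0042, 0.0042]
phn:
  # bands 65-69, 70-74, 75-79, 80-84, 85+; proportion of HZ cases developing PHN
  mean: [0.12, 0.15, 0.15, 0.15, 0.16]
  se: [0.022, 0.016, 0.016, 0.015, 0.015]
  dist: [beta_mean_se, beta_mean_se, beta_mean_se, beta_mean_se, beta_mean_se]
hz_severity:
  # acute-episode pain mix over {no pain, mild, moderate, severe};
  # the under-70 row sums to 1.01 as printed and is renormalized on load
  under70: [0.65, 0.24, 0.04, 0.08]
  over70: [0.45, 0.41, 0.05, 0.09]
phn_severity:
  # {mild, moderate, severe}; mild is a structural state with zero mass
  prob: [0.0, 0.89, 0.11]
durations:
  hz_months: 1.0
  phn_months_mild: 7.0
  phn_months_moderate: 10.0
  phn_months_severe: 13.0
utility_baseline:
  # bands 65-69, 70-79, 80+
  mean_female: [0.75, 0.66, 0.57]
  se_female: [0.010, 0.014, 0.021]
  mean_male: [0.78, 0.76, 0.68]
  se_male: [0.012, 0.013, 0.027]
  dist: [beta_mean_se, beta_mean_se, beta_mean_se]
utility_multipliers:
  # fraction of baseline utility retained in {mild, moderate, severe} pain;
  # no-pain multiplier is fixed at 1
  value: [0.91, 0.71, 0.32]
  alpha: [81.27, 153.0, 13.76]
  beta: [8.08, 62.55, 29.38]
  dist: [beta_shape, beta_shape, beta_shape]
visits:
  # categories B02.9, B02.2, B02.3, B02.7, B02.8; mean visits per episode
  primary: [1.17, 1.38, 0.87, 1.00, 1.25]
  outpatient: [0.14, 0.27, 1.82, 0.22, 0.21]
  inpatient: [0.05, 0.14, 0.17, 0.15, 0.11]
  dist: [binomial, binomial, binomial, binomial, binomial]
  n_trials: [1000, 1000, 1000, 1000, 1000]
uptake:
  antiviral_uncomplicated: 0.62
  antiviral_complicated: 0.62
  analgesic_uncomplicated: 0.20
  analgesic_complicated: 0.50
complication_mix:
  # share of HZ episodes per category B02.9, B02.2, B02.3, B02.7, B02.8;
  # not reported in the source tables -- reconstruction: 95% uncomplicated,
  # remainder split equally
  prob: [0.95, 0.0125, 0.0125, 0.0125, 0.0125]
costs:
  vaccine_price_per_dose: 176.4
  administration_per_dose: 7.2
  primary_care_visit: 182.0
  # outpatient visit cost per category B02.9, B02.2, B02.3, B02.7, B02.8
  outpatient: [369.0, 613.0, 193.0, 393.0, 384.0]
  inpatient_episode: 5180.0
  antiviral_course: 18.7
  analgesic_per_month: 16.6
  # per-dose prices retained as metadata only; aggregate figures above are used
  antiviral_per_dose: 0.72
  analgesic_per_dose: 0.18
  currency: EUR2021
program:
  coverage: 0.63
  compliance: 0.749
  doses: 2
economics:
  discount_rate: 0.03
  wtp: 80000.0
  max_age: 105
  cycle_length: 1.0
scenarios:
  rct:
    id: rct
    ve_year1: 0.977
    waning: 0.031
    # one-dose year-1 effectiveness is not reported; reconstruction (see docs)
    one_dose_ve_year1: 0.70
    post10: waning
  observational:
    id: observational
    ve_year1: 0.792
    waning: 0.031
    one_dose_ve_year1: 0.70
    post10: waning
stroke:
  enabled: no
metadata:
  fixture_id: sweden-rzv-basecase-2021
  exchange_rate_note: 100 SEK = 10.15 EUR (2021)
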