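# Independent oracles used to cross-check the expectation engine. These
# re-derive the per-episode quantities by exhaustive enumeration over pathway
# combinations, and the cohort outcomes by per-person Monte Carlo simulation;
# neither shares arithmetic with the package implementation.

# Exhaustive enumeration of expected QALY loss per episode: sums over every
# (acute severity) x (PHN yes/no) x (PHN severity) combination.
oracle_episode_qaly_loss <- function(age, sex, params) {
  ub <- params$utility_baseline
  band <- if (age < 70) "65-69" else if (age < 80) "70-79" else "80+"
  u <- ub$mean[ub$age_band == band & ub$sex == sex]
  mm <- c(no_pain = 1,
          stats::setNames(params$utility_multipliers$value,
                          params$utility_multipliers$severity))
  grp <- if (age < 70) "<70" else ">=70"
  sv <- params$hz_severity[params$hz_severity$age_group == grp, ]
  pb <- params$phn
  p_phn <- pb$mean[match(
    if (age < 70) "65-69" else if (age < 75) "70-74" else if (age < 80) "75-79"
    else if (age < 85) "80-84" else "85+", pb$age_band)]
  dur <- params$durations
  total <- 0
  for (i in seq_len(nrow(sv))) {
    acute_loss <- u * (1 - mm[[sv$severity[i]]]) * dur$hz_months / 12
    # no-PHN branch
    total <- total + sv$prob[i] * (1 - p_phn) * acute_loss
    # PHN branches
    for (j in seq_len(nrow(params$phn_severity))) {
      s2 <- params$phn_severity$severity[j]
      phn_loss <- u * (1 - mm[[s2]]) * dur$phn_months[[s2]] / 12
      total <- total + sv$prob[i] * p_phn * params$phn_severity$prob[j] *
        (acute_loss + phn_loss)
    }
  }
  total
}

# Exhaustive enumeration of expected cost per episode over
# (category) x (antiviral yes/no) x (analgesic yes/no) x (PHN pathway).
oracle_episode_cost <- function(age, params) {
  co <- params$costs
  pb <- params$phn
  p_phn <- pb$mean[match(
    if (age < 70) "65-69" else if (age < 75) "70-74" else if (age < 80) "75-79"
    else if (age < 85) "80-84" else "85+", pb$age_band)]
  dur <- params$durations
  total <- 0
  for (i in seq_len(nrow(params$visits))) {
    k <- params$visits$category[i]
    p_k <- params$complication_mix$prob[params$complication_mix$category == k]
    visits <- params$visits$primary[i] * co$primary_care_visit +
      params$visits$outpatient[i] * co$outpatient[[k]] +
      params$visits$inpatient[i] * co$inpatient_episode
    up_av <- if (k == "B02.9") params$uptake$antiviral_uncomplicated else
      params$uptake$antiviral_complicated
    up_an <- if (k == "B02.9") params$uptake$analgesic_uncomplicated else
      params$uptake$analgesic_complicated
    base_months <- dur$hz_months
    # no-PHN branch
    total <- total + p_k * (1 - p_phn) *
      (visits + up_av * co$antiviral_course +
       up_an * co$analgesic_per_month * base_months)
    for (j in seq_len(nrow(params$phn_severity))) {
      s2 <- params$phn_severity$severity[j]
      months <- base_months + dur$phn_months[[s2]]
      total <- total + p_k * p_phn * params$phn_severity$prob[j] *
        (visits + up_av * co$antiviral_course +
         up_an * co$analgesic_per_month * months)
    }
  }
  total
}

# Per-person stochastic microsimulation of one arm of one cohort. Every
# pathway element the engine treats in expectation (death, episode, ICD-10
# category, acute and PHN severity, medication uptake) is drawn per person;
# visit counts enter at their means. Returns per-person totals so the caller
# can form Monte Carlo standard errors.
oracle_microsim <- function(params, start_age, sex, arm = "no_vaccination",
                            scenario = "rct", n_persons = 1e5, seed = 1) {
  set.seed(seed)
  n_cycles <- params$economics$max_age - start_age + 1L
  mult <- if (arm == "rzv") {
    as.numeric(build_protection_profile(params$scenarios[[scenario]],
                                        params$program, n_cycles))
  } else rep(1, n_cycles)
  co <- params$costs
  mm <- c(no_pain = 1,
          stats::setNames(params$utility_multipliers$value,
                          params$utility_multipliers$severity))
  dur <- params$durations
  # per-category deterministic visit cost and uptakes
  vis_cost <- params$visits$primary * co$primary_care_visit +
    params$visits$outpatient * co$outpatient[params$visits$category] +
    params$visits$inpatient * co$inpatient_episode
  up_av <- ifelse(params$visits$category == "B02.9",
                  params$uptake$antiviral_uncomplicated,
                  params$uptake$antiviral_complicated)
  up_an <- ifelse(params$visits$category == "B02.9",
                  params$uptake$analgesic_uncomplicated,
                  params$uptake$analgesic_complicated)
  mix <- params$complication_mix$prob

  alive <- rep(TRUE, n_persons)
  qalys <- numeric(n_persons)
  costs <- numeric(n_persons)
  n_episodes <- numeric(n_persons)
  r <- params$economics$discount_rate
  for (t in seq_len(n_cycles)) {
    age <- start_age + t - 1L
    df <- (1 + r)^(-(t - 1L))
    band <- if (age < 70) "65-69" else if (age < 80) "70-79" else "80+"
    ub <- params$utility_baseline
    u <- ub$mean[ub$age_band == band & ub$sex == sex]
    dem_band <- zostercea:::demog_band(age)
    qd <- params$demography$p_death[params$demography$age_band == dem_band &
                                    params$demography$sex == sex]
    inc <- params$incidence$p_hz[params$incidence$age_band == dem_band &
                                 params$incidence$sex == sex]
    pb <- params$phn
    p_phn <- pb$mean[match(
      if (age < 70) "65-69" else if (age < 75) "70-74" else if (age < 80) "75-79"
      else if (age < 85) "80-84" else "85+", pb$age_band)]
    grp <- if (age < 70) "<70" else ">=70"
    sv <- params$hz_severity[params$hz_severity$age_group == grp, ]

    idx_alive <- which(alive)
    died <- idx_alive[stats::runif(length(idx_alive)) < qd]
    alive[died] <- FALSE
    surv <- which(alive)
    qalys[surv] <- qalys[surv] + u * df
    hz <- surv[stats::runif(length(surv)) < inc * mult[t]]
    n_hz <- length(hz)
    if (n_hz > 0) {
      n_episodes[hz] <- n_episodes[hz] + 1
      k <- sample.int(5L, n_hz, replace = TRUE, prob = mix)
      s1 <- sample(sv$severity, n_hz, replace = TRUE, prob = sv$prob)
      loss <- u * (1 - mm[s1]) * dur$hz_months / 12
      cost <- vis_cost[k] +
        (stats::runif(n_hz) < up_av[k]) * co$antiviral_course
      months <- rep(dur$hz_months, n_hz)
      has_phn <- stats::runif(n_hz) < p_phn
      if (any(has_phn)) {
        s2 <- sample(params$phn_severity$severity, sum(has_phn), replace = TRUE,
                     prob = params$phn_severity$prob)
        loss[has_phn] <- loss[has_phn] + u * (1 - mm[s2]) * dur$phn_months[s2] / 12
        months[has_phn] <- months[has_phn] + dur$phn_months[s2]
      }
      cost <- cost + (stats::runif(n_hz) < up_an[k]) * co$analgesic_per_month * months
      qalys[hz] <- qalys[hz] - loss * df
      costs[hz] <- costs[hz] + cost * df
    }
  }
  if (arm == "rzv") {
    doses <- params$program$coverage * (1 + params$program$compliance)
    costs <- costs + doses * (co$vaccine_price_per_dose + co$administration_per_dose)
  }
  list(qalys = qalys, costs = costs, episodes = n_episodes)
}

# Engine run scaled to per-person expectations, for comparison with the oracle.
engine_per_person <- function(params, start_age, sex, arm = "no_vaccination",
                              scenario = "rct") {
  tr <- run_cohort(cohort_spec(start_age, sex, size = 1, arm = arm,
                               scenario = scenario),
                   params)
  tot <- trace_totals(tr)
  list(qalys = tot[["qalys_disc"]],
       costs = tot[["cost_hz_disc"]] + tot[["cost_vaccination_disc"]],
       episodes = tot[["episodes"]])
}

# Short-horizon copy of the base case for fast property tests.
toy_params <- function(max_age = 67) {
  modify_parameters(basecase_fixture(), "economics.max_age", as.integer(max_age))
}
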