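# Per-episode expectations. An HZ episode is a bundle of sub-annual tunnel
# states: one acute month with an age-group-specific pain mix, plus (with the
# age-specific PHN probability) a 7/10/13-month PHN pain spell. Losses and
# costs are expectations over all pathway combinations, attributed wholly to
# the onset cycle.

#' Expected QALY loss per HZ episode
#'
#' Multiplicative decrement model: during a pain state of severity s the
#' individual retains fraction m(s) of the age- and sex-specific baseline
#' utility, so a D(s)-month spell loses `u_base * (1 - m(s)) * D(s)/12`
#' QALYs. The acute month uses the age group's acute pain mix; with
#' probability p_PHN the episode continues into PHN with its own severity
#' mix and durations. The no-pain state has multiplier 1 (no loss), and
#' individuals return to baseline utility immediately after the episode.
#'
#' @param age Age in years at episode onset (vectorized).
#' @param sex `"female"` or `"male"`.
#' @param params A `zoster_parameters` object.
#' @return Expected QALYs lost per episode, same length as `age`.
#' @export
episode_qaly_loss <- function(age, sex, params) {
  u <- baseline_utility(age, sex, params)
  mult <- stats::setNames(params$utility_multipliers$value,
                          params$utility_multipliers$severity)
  mult <- c(no_pain = 1, mult)
  dec <- 1 - mult

  grp <- severity_group(age)
  acute <- vapply(grp, function(g) {
    i <- params$hz_severity$age_group == g
    sum(params$hz_severity$prob[i] * dec[params$hz_severity$severity[i]])
  }, numeric(1L)) * params$durations$hz_months / 12

  phn_term <- sum(params$phn_severity$prob *
                  dec[params$phn_severity$severity] *
                  params$durations$phn_months[params$phn_severity$severity] / 12)
  p_phn <- phn_probability(age, params)
  unname(u * (acute + p_phn * phn_term))
}

#' Expected direct healthcare cost per HZ episode
#'
#' Mixes the ICD-10 complication categories by their configured shares; each
#' category contributes its mean primary-care, outpatient and inpatient
#' visits at the respective unit costs, plus medication: an antiviral course
#' per treated case and a monthly analgesic cost over the expected months of
#' pain (the acute month plus PHN-duration months weighted by the PHN
#' probability), each scaled by the category class's uptake proportion.
#'
#' @inheritParams episode_qaly_loss
#' @return Expected cost in euro per episode, same length as `age`.
#' @export
episode_cost <- function(age, sex, params) {
  v <- params$visits
  co <- params$costs
  mix <- stats::setNames(params$complication_mix$prob, params$complication_mix$category)
  visit_cost <- v$primary * co$primary_care_visit +
    v$outpatient * co$outpatient[v$category] +
    v$inpatient * co$inpatient_episode
  complicated <- v$category != "B02.9"
  antiviral_uptake <- ifelse(complicated, params$uptake$antiviral_complicated,
                             params$uptake$antiviral_uncomplicated)
  analgesic_uptake <- ifelse(complicated, params$uptake$analgesic_complicated,
                             params$uptake$analgesic_uncomplicated)
  exp_months <- params$durations$hz_months +
    phn_probability(age, params) *
      sum(params$phn_severity$prob * params$durations$phn_months[params$phn_severity$severity])
  fixed_part <- sum(mix[v$category] * (visit_cost + antiviral_uptake * co$antiviral_course))
  analgesic_part <- sum(mix[v$category] * analgesic_uptake) * co$analgesic_per_month
  unname(fixed_part + analgesic_part * exp_months)
}

baseline_utility <- function(age, sex, params) {
  i <- match(paste(utility_band(age), sex),
             paste(params$utility_baseline$age_band, params$utility_baseline$sex))
  params$utility_baseline$mean[i]
}

phn_probability <- function(age, params) {
  params$phn$mean[match(phn_band(age), params$phn$age_band)]
}

death_probability <- function(age, sex, params) {
  i <- match(paste(demog_band(age), sex),
             paste(params$demography$age_band, params$demography$sex))
  params$demography$p_death[i]
}

hz_incidence <- function(age, sex, params) {
  i <- match(paste(demog_band(age), sex),
             paste(params$incidence$age_band, params$incidence$sex))
  params$incidence$p_hz[i]
}

stroke_incidence <- function(age, sex, params) {
  i <- match(paste(demog_band(age), sex),
             paste(params$stroke$incidence$age_band, params$stroke$incidence$sex))
  params$stroke$incidence$p_stroke[i]
}

#' Cohort specification
#'
#' @param start_age Lower age of the 5-year band: one of 65, 70, ..., 100.
#' @param sex `"female"` or `"male"`.
#' @param size Initial cohort size in persons; defaults to the parameter
#'   set's value for that band and sex when `params` is given.
#' @param arm `"no_vaccination"` or `"rzv"`.
#' @param scenario Efficacy scenario id (used by the vaccinated arm).
#' @param params Optional parameter set supplying the default size.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(start_age, sex = c("female", "male"), size = NULL,
                        arm = c("no_vaccination", "rzv"), scenario = "rct",
                        params = NULL) {
  sex <- match.arg(sex)
  arm <- match.arg(arm)
  if (!start_age %in% seq(65, 100, by = 5)) {
    stop("start_age must be one of 65, 70, ..., 100")
  }
  if (is.null(size)) {
    if (is.null(params)) stop("supply 'size' or 'params'")
    i <- match(paste(demog_band(start_age), sex),
               paste(params$demography$age_band, params$demography$sex))
    size <- params$demography$size[i]
  }
  if (size <= 0) stop("cohort size must be > 0")
  structure(list(start_age = start_age, sex = sex, size = size, arm = arm,
                 scenario = scenario), class = "cohort_spec")
}

#' Run the annual-cycle Markov cohort model for one arm
#'
#' Simulates one age-sex cohort from its band's lower age to the maximum
#' model age in annual cycles. Within a cycle, deaths occur first
#' (`alive * q_death`); survivors are then at risk of an HZ episode at the
#' age- and sex-specific incidence times the arm's protection multiplier
#' (recurrence carries the same probability as first occurrence, so the
#' whole surviving cohort stays at risk every cycle). Survivors accrue the
#' baseline utility for the year; each incident episode subtracts its
#' expected QALY loss and adds its expected visit and medication costs, all
#' attributed to the onset cycle. In the vaccinated arm, both doses are
#' delivered and costed in cycle 1 (`size * coverage * (1 + compliance)`
#' doses at price plus administration). Cycle t is discounted by
#' `(1 + r)^-(t-1)`, so the first year is undiscounted. No HZ-attributable
#' mortality and no half-cycle correction are applied.
#'
#' When the stroke add-on is enabled, each incident episode additionally
#' generates `(RR - 1) * p_stroke` excess first-year strokes, each charged
#' the per-stroke cost and one year at the stroke utility multiplier.
#'
#' @param spec A [cohort_spec()].
#' @param params A `zoster_parameters` object.
#' @param protection A [build_protection_profile()] vector covering at least
#'   `max_age - start_age + 1` years; `NULL` (multiplier 1 throughout) for
#'   the no-vaccination arm.
#' @return An object of class `cohort_trace`: a per-cycle data frame with
#'   occupancies, event counts, QALYs and cost components, undiscounted and
#'   discounted, with the spec and column totals attached as attributes.
#' @export
run_cohort <- function(spec, params, protection = NULL) {
  n_cycles <- params$economics$max_age - spec$start_age + 1L
  if (spec$arm == "rzv") {
    if (is.null(protection)) {
      protection <- build_protection_profile(params$scenarios[[spec$scenario]],
                                             params$program, n_cycles)
    }
    if (length(protection) < n_cycles) {
      stop("protection horizon (", length(protection),
           ") shorter than required cycles (", n_cycles, ")")
    }
  }
  ages <- spec$start_age + seq_len(n_cycles) - 1L
  qd <- death_probability(ages, spec$sex, params)
  inc <- hz_incidence(ages, spec$sex, params)
  u <- baseline_utility(ages, spec$sex, params)
  loss <- episode_qaly_loss(ages, spec$sex, params)
  cost_case_visits <- vapply(ages, function(a) episode_cost_visits(a, params), numeric(1L))
  cost_case_meds <- vapply(ages, function(a) episode_cost_meds(a, params), numeric(1L))
  p_phn <- phn_probability(ages, params)
  mult <- if (spec$arm == "rzv") as.numeric(protection[seq_len(n_cycles)]) else rep(1, n_cycles)

  stroke_on <- isTRUE(params$stroke$enabled)
  if (stroke_on) {
    p_stroke <- stroke_incidence(ages, spec$sex, params)
    stroke_excess_per_case <- (params$stroke$relative_risk - 1) * p_stroke
  }

  alive <- numeric(n_cycles)
  deaths <- numeric(n_cycles)
  at_risk <- numeric(n_cycles)
  episodes <- numeric(n_cycles)
  a <- spec$size
  for (t in seq_len(n_cycles)) {
    alive[t] <- a
    deaths[t] <- a * qd[t]
    at_risk[t] <- a - deaths[t]
    episodes[t] <- at_risk[t] * inc[t] * mult[t]
    a <- at_risk[t]
  }
  phn_cases <- episodes * p_phn
  qalys <- at_risk * u - episodes * loss
  cost_visits <- episodes * cost_case_visits
  cost_medication <- episodes * cost_case_meds
  cost_vaccination <- numeric(n_cycles)
  if (spec$arm == "rzv") {
    doses <- spec$size * params$program$coverage * (1 + params$program$compliance)
    cost_vaccination[1L] <- doses *
      (params$costs$vaccine_price_per_dose + params$costs$administration_per_dose)
  }
  cost_stroke <- numeric(n_cycles)
  if (stroke_on) {
    excess <- episodes * stroke_excess_per_case
    cost_stroke <- excess * params$stroke$cost_per_stroke
    qalys <- qalys - excess * u * (1 - params$stroke$utility_multiplier)
  }
  df <- (1 + params$economics$discount_rate)^(-(seq_len(n_cycles) - 1L))

  trace <- data.frame(
    cycle = seq_len(n_cycles), age = ages, alive = alive, deaths = deaths,
    at_risk = at_risk, episodes = episodes, phn_cases = phn_cases,
    qalys = qalys, cost_vaccination = cost_vaccination,
    cost_visits = cost_visits, cost_medication = cost_medication,
    cost_stroke = cost_stroke, discount = df,
    qalys_disc = qalys * df, cost_vaccination_disc = cost_vaccination * df,
    cost_visits_disc = cost_visits * df,
    cost_medication_disc = cost_medication * df,
    cost_stroke_disc = cost_stroke * df
  )
  structure(trace, class = c("cohort_trace", "data.frame"), spec = spec)
}

episode_cost_visits <- function(age, params) {
  v <- params$visits
  co <- params$costs
  mix <- stats::setNames(params$complication_mix$prob, params$complication_mix$category)
  visit_cost <- v$primary * co$primary_care_visit +
    v$outpatient * co$outpatient[v$category] +
    v$inpatient * co$inpatient_episode
  sum(mix[v$category] * visit_cost)
}

episode_cost_meds <- function(age, params) {
  episode_cost(age, "female", params) - episode_cost_visits(age, params)
}

#' Totals of a cohort trace (or a list of traces)
#'
#' @param x A `cohort_trace` or list of them (e.g. both sexes of one cohort).
#' @return Named numeric vector with undiscounted episode/PHN counts and
#'   discounted and undiscounted QALYs and cost components.
#' @export
trace_totals <- function(x) {
  if (inherits(x, "cohort_trace")) x <- list(x)
  acc <- c(episodes = 0, phn_cases = 0, qalys = 0, qalys_disc = 0,
           cost_vaccination = 0, cost_vaccination_disc = 0,
           cost_hz = 0, cost_hz_disc = 0)
  for (tr in x) {
    acc["episodes"] <- acc["episodes"] + sum(tr$episodes)
    acc["phn_cases"] <- acc["phn_cases"] + sum(tr$phn_cases)
    acc["qalys"] <- acc["qalys"] + sum(tr$qalys)
    acc["qalys_disc"] <- acc["qalys_disc"] + sum(tr$qalys_disc)
    acc["cost_vaccination"] <- acc["cost_vaccination"] + sum(tr$cost_vaccination)
    acc["cost_vaccination_disc"] <- acc["cost_vaccination_disc"] +
      sum(tr$cost_vaccination_disc)
    acc["cost_hz"] <- acc["cost_hz"] +
      sum(tr$cost_visits + tr$cost_medication + tr$cost_stroke)
    acc["cost_hz_disc"] <- acc["cost_hz_disc"] +
      sum(tr$cost_visits_disc + tr$cost_medication_disc + tr$cost_stroke_disc)
  }
  acc
}

#' @export
print.cohort_trace <- function(x, ...) {
  sp <- attr(x, "spec")
  tot <- trace_totals(x)
  cat("<cohort_trace> ", sp$sex, " ", sp$start_age, "+, arm ", sp$arm,
      ", ", nrow(x), " cycles\n", sep = "")
  cat("  lifetime HZ episodes: ", format(round(tot[["episodes"]]), big.mark = ","),
      " (PHN ", format(round(tot[["phn_cases"]]), big.mark = ","), ")\n", sep = "")
  cat("  discounted QALYs: ", format(round(tot[["qalys_disc"]]), big.mark = ","),
      "; discounted HZ costs: ", format(round(tot[["cost_hz_disc"]]), big.mark = ","),
      "\n", sep = "")
  invisible(x)
}
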