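# Age-band grids used by the input tables. Demography/incidence are on 5-year
# bands to 100+, PHN risk on 5-year bands collapsing at 85+, baseline utility
# on the coarser grid its source reports.
.demog_bands <- c("65-69", "70-74", "75-79", "80-84", "85-89", "90-94", "95-99", "100+")
.demog_lower <- c(65, 70, 75, 80, 85, 90, 95, 100)
.phn_bands   <- c("65-69", "70-74", "75-79", "80-84", "85+")
.phn_lower   <- c(65, 70, 75, 80, 85)
.util_bands  <- c("65-69", "70-79", "80+")
.util_lower  <- c(65, 70, 80)
.hz_categories <- c("B02.9", "B02.2", "B02.3", "B02.7", "B02.8")
.severities  <- c("no_pain", "mild", "moderate", "severe")
.sexes       <- c("female", "male")

band_of <- function(age, lower, labels) labels[pmin(findInterval(age, lower), length(labels))]

demog_band   <- function(age) band_of(age, .demog_lower, .demog_bands)
phn_band     <- function(age) band_of(age, .phn_lower, .phn_bands)
utility_band <- function(age) band_of(age, .util_lower, .util_bands)
severity_group <- function(age) ifelse(age < 70, "<70", ">=70")

#' Load and validate a model parameter set
#'
#' Reads a hierarchical configuration document (YAML file path or an
#' already-parsed nested list) describing every model input table —
#' demography, HZ epidemiology, utilities, healthcare utilization, unit
#' costs, the vaccination program, efficacy scenarios and economic settings
#' — validates all invariants, renormalizes pain-severity distributions
#' whose printed rows do not sum exactly to one (tolerance 0.02), and
#' returns an immutable parameter set.
#'
#' @param config Path to a YAML document, or a nested list with the same
#'   structure (as produced by [write_parameters()] or [basecase_fixture()]).
#' @return An object of class `zoster_parameters`.
#' @seealso [basecase_fixture()], [write_parameters()], [draw_parameters()]
#' @export
load_parameters <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a file path or a nested list")

  need <- function(tab) {
    if (is.null(config[[tab]])) stop("missing table in config: '", tab, "'")
    config[[tab]]
  }

  dem <- need("demography")
  demography <- data.frame(
    age_band = rep(.demog_bands, 2L),
    sex = rep(.sexes, each = length(.demog_bands)),
    size = c(as.numeric(dem$size_female), as.numeric(dem$size_male)),
    p_death = c(as.numeric(dem$p_death_female), as.numeric(dem$p_death_male)),
    stringsAsFactors = FALSE
  )

  inc <- need("incidence")
  incidence <- data.frame(
    age_band = rep(.demog_bands, 2L),
    sex = rep(.sexes, each = length(.demog_bands)),
    p_hz = c(as.numeric(inc$p_hz_female), as.numeric(inc$p_hz_male)),
    stringsAsFactors = FALSE
  )

  ph <- need("phn")
  phn <- data.frame(
    age_band = .phn_bands,
    mean = as.numeric(ph$mean),
    se = as.numeric(ph$se),
    dist = as.character(ph$dist),
    stringsAsFactors = FALSE
  )

  sev <- need("hz_severity")
  hz_severity <- data.frame(
    age_group = rep(c("<70", ">=70"), each = 4L),
    severity = rep(.severities, 2L),
    prob = c(as.numeric(sev$under70), as.numeric(sev$over70)),
    stringsAsFactors = FALSE
  )
  phn_sev <- need("phn_severity")
  phn_severity <- data.frame(
    severity = c("mild", "moderate", "severe"),
    prob = as.numeric(phn_sev$prob),
    stringsAsFactors = FALSE
  )

  dur <- need("durations")
  durations <- list(
    hz_months = as.numeric(dur$hz_months),
    phn_months = c(mild = as.numeric(dur$phn_months_mild),
                   moderate = as.numeric(dur$phn_months_moderate),
                   severe = as.numeric(dur$phn_months_severe))
  )

  ub <- need("utility_baseline")
  utility_baseline <- data.frame(
    age_band = rep(.util_bands, 2L),
    sex = rep(.sexes, each = length(.util_bands)),
    mean = c(as.numeric(ub$mean_female), as.numeric(ub$mean_male)),
    se = c(as.numeric(ub$se_female), as.numeric(ub$se_male)),
    dist = rep(as.character(ub$dist), 2L),
    stringsAsFactors = FALSE
  )

  um <- need("utility_multipliers")
  utility_multipliers <- data.frame(
    severity = c("mild", "moderate", "severe"),
    value = as.numeric(um$value),
    alpha = as.numeric(um$alpha),
    beta = as.numeric(um$beta),
    dist = as.character(um$dist),
    stringsAsFactors = FALSE
  )

  vis <- need("visits")
  visits <- data.frame(
    category = .hz_categories,
    primary = as.numeric(vis$primary),
    outpatient = as.numeric(vis$outpatient),
    inpatient = as.numeric(vis$inpatient),
    dist = as.character(vis$dist),
    n = as.integer(vis$n_trials),
    stringsAsFactors = FALSE
  )

  upt <- need("uptake")
  uptake <- list(
    antiviral_uncomplicated = as.numeric(upt$antiviral_uncomplicated),
    antiviral_complicated = as.numeric(upt$antiviral_complicated),
    analgesic_uncomplicated = as.numeric(upt$analgesic_uncomplicated),
    analgesic_complicated = as.numeric(upt$analgesic_complicated)
  )

  mix <- need("complication_mix")
  complication_mix <- data.frame(
    category = .hz_categories,
    prob = as.numeric(mix$prob),
    stringsAsFactors = FALSE
  )

  co <- need("costs")
  costs <- list(
    vaccine_price_per_dose = as.numeric(co$vaccine_price_per_dose),
    administration_per_dose = as.numeric(co$administration_per_dose),
    primary_care_visit = as.numeric(co$primary_care_visit),
    outpatient = stats::setNames(as.numeric(co$outpatient), .hz_categories),
    inpatient_episode = as.numeric(co$inpatient_episode),
    antiviral_course = as.numeric(co$antiviral_course),
    analgesic_per_month = as.numeric(co$analgesic_per_month),
    antiviral_per_dose = as.numeric(co$antiviral_per_dose),
    analgesic_per_dose = as.numeric(co$analgesic_per_dose),
    currency = as.character(co$currency)
  )

  pr <- need("program")
  program <- list(
    coverage = as.numeric(pr$coverage),
    compliance = as.numeric(pr$compliance),
    doses = as.integer(pr$doses)
  )

  ec <- need("economics")
  economics <- list(
    discount_rate = as.numeric(ec$discount_rate),
    wtp = as.numeric(ec$wtp),
    max_age = as.integer(ec$max_age),
    cycle_length = as.numeric(ec$cycle_length)
  )

  sc <- need("scenarios")
  scenarios <- lapply(sc, function(s) {
    list(
      id = as.character(s$id),
      ve_year1 = as.numeric(s$ve_year1),
      waning = as.numeric(s$waning),
      one_dose_ve_year1 = as.numeric(s$one_dose_ve_year1),
      post10 = if (is.null(s$post10)) "waning" else as.character(s$post10),
      ve_vector = if (is.null(s$ve_vector)) NULL else as.numeric(s$ve_vector)
    )
  })

  st <- config$stroke
  stroke <- if (is.null(st)) {
    list(enabled = FALSE)
  } else {
    out <- list(enabled = isTRUE(st$enabled))
    if (!is.null(st$p_stroke_female)) {
      out$incidence <- data.frame(
        age_band = rep(.demog_bands, 2L),
        sex = rep(.sexes, each = length(.demog_bands)),
        p_stroke = c(as.numeric(st$p_stroke_female), as.numeric(st$p_stroke_male)),
        stringsAsFactors = FALSE
      )
      out$relative_risk <- as.numeric(st$relative_risk)
      out$cost_per_stroke <- as.numeric(st$cost_per_stroke)
      out$utility_multiplier <- as.numeric(st$utility_multiplier)
    }
    out
  }

  params <- structure(list(
    demography = demography,
    incidence = incidence,
    phn = phn,
    hz_severity = hz_severity,
    phn_severity = phn_severity,
    durations = durations,
    utility_baseline = utility_baseline,
    utility_multipliers = utility_multipliers,
    visits = visits,
    uptake = uptake,
    complication_mix = complication_mix,
    costs = costs,
    program = program,
    economics = economics,
    scenarios = scenarios,
    stroke = stroke,
    metadata = if (is.null(config$metadata)) list() else config$metadata
  ), class = "zoster_parameters")

  params <- renormalize_severity(params)
  validate_parameters(params)
  params
}

# Printed pain-severity rows may not sum exactly to 1 (rounding in the
# source); within tolerance 0.02 they are rescaled to sum exactly to 1.
renormalize_severity <- function(params) {
  for (grp in c("<70", ">=70")) {
    idx <- params$hz_severity$age_group == grp
    s <- sum(params$hz_severity$prob[idx])
    if (abs(s - 1) > 0.02) {
      stop("hz_severity[", grp, "] sums to ", s, ", beyond tolerance 0.02")
    }
    params$hz_severity$prob[idx] <- params$hz_severity$prob[idx] / s
  }
  s <- sum(params$phn_severity$prob)
  if (abs(s - 1) > 0.02) stop("phn_severity sums to ", s, ", beyond tolerance 0.02")
  params$phn_severity$prob <- params$phn_severity$prob / s
  params
}

#' Validate a parameter set against all model invariants
#'
#' Checks probability bounds, non-negative sizes and costs, Beta-distribution
#' feasibility, ordering of pain-state utility multipliers and of death
#' probabilities across age, and distribution sums. Errors name the offending
#' field.
#'
#' @param params A `zoster_parameters` object.
#' @return `params`, invisibly, if valid.
#' @export
validate_parameters <- function(params) {
  chk <- function(ok, field, msg) {
    if (!all(ok)) stop("invalid parameter '", field, "': ", msg, call. = FALSE)
  }
  p01 <- function(x) is.finite(x) & x >= 0 & x <= 1

  chk(params$demography$size >= 0, "demography.size", "cohort sizes must be >= 0")
  chk(p01(params$demography$p_death), "demography.p_death", "death probabilities must lie in [0, 1]")
  for (sx in .sexes) {
    qd <- params$demography$p_death[params$demography$sex == sx]
    chk(all(diff(qd) >= 0), paste0("demography.p_death.", sx),
        "death probability must be non-decreasing with age band")
  }
  chk(p01(params$incidence$p_hz), "incidence.p_hz", "HZ incidence probabilities must lie in [0, 1]")

  chk(params$phn$mean > 0 & params$phn$mean < 1, "phn.mean", "PHN proportions must lie in (0, 1)")
  chk(params$phn$se > 0, "phn.se", "PHN standard errors must be > 0")
  chk(params$phn$se^2 < params$phn$mean * (1 - params$phn$mean), "phn.se",
      "se^2 must be < mean*(1-mean) for a Beta distribution")

  chk(p01(params$hz_severity$prob), "hz_severity.prob", "severity probabilities must lie in [0, 1]")
  chk(p01(params$phn_severity$prob), "phn_severity.prob", "severity probabilities must lie in [0, 1]")
  chk(params$durations$hz_months > 0, "durations.hz_months", "episode durations must be > 0")
  chk(params$durations$phn_months > 0, "durations.phn_months", "episode durations must be > 0")

  chk(p01(params$utility_baseline$mean), "utility_baseline.mean", "utilities must lie in [0, 1]")
  chk(params$utility_baseline$se > 0, "utility_baseline.se", "utility SEs must be > 0")
  m <- params$utility_multipliers
  chk(p01(m$value), "utility_multipliers.value", "multipliers must lie in [0, 1]")
  chk(m$alpha > 0 & m$beta > 0, "utility_multipliers.shape", "Beta shapes must be > 0")
  ord <- stats::setNames(m$value, m$severity)
  chk(ord[["mild"]] > ord[["moderate"]] && ord[["moderate"]] > ord[["severe"]],
      "utility_multipliers.value", "must satisfy mild > moderate > severe")

  chk(params$visits$primary >= 0 & params$visits$outpatient >= 0 & params$visits$inpatient >= 0,
      "visits", "visit counts must be >= 0")
  chk(params$visits$n >= 1, "visits.n", "binomial n must be a positive integer")
  chk(p01(unlist(params$uptake)), "uptake", "medication uptake proportions must lie in [0, 1]")
  chk(abs(sum(params$complication_mix$prob) - 1) < 1e-8, "complication_mix",
      "category mix must sum to 1")
  chk(p01(params$complication_mix$prob), "complication_mix.prob", "mix must lie in [0, 1]")

  chk(unlist(params$costs[c("vaccine_price_per_dose", "administration_per_dose",
                            "primary_care_visit", "inpatient_episode",
                            "antiviral_course", "analgesic_per_month")]) >= 0,
      "costs", "all unit costs must be >= 0")
  chk(params$costs$outpatient >= 0, "costs.outpatient", "all unit costs must be >= 0")

  chk(p01(params$program$coverage), "program.coverage", "coverage must lie in [0, 1]")
  chk(p01(params$program$compliance), "program.compliance", "compliance must lie in [0, 1]")

  chk(params$economics$discount_rate >= 0, "economics.discount_rate", "discount rate must be >= 0")
  chk(params$economics$wtp > 0, "economics.wtp", "willingness-to-pay must be > 0")
  chk(params$economics$max_age > 65, "economics.max_age", "maximum model age must exceed 65")

  for (s in params$scenarios) {
    chk(p01(s$ve_year1), paste0("scenarios.", s$id, ".ve_year1"), "VE must lie in [0, 1]")
    chk(p01(s$one_dose_ve_year1), paste0("scenarios.", s$id, ".one_dose_ve_year1"),
        "VE must lie in [0, 1]")
    chk(s$waning >= 0, paste0("scenarios.", s$id, ".waning"), "waning rate must be >= 0")
    chk(s$post10 %in% c("waning", "zero"), paste0("scenarios.", s$id, ".post10"),
        "must be 'waning' or 'zero'")
    if (!is.null(s$ve_vector)) {
      chk(p01(s$ve_vector), paste0("scenarios.", s$id, ".ve_vector"), "VE must lie in [0, 1]")
      chk(all(diff(s$ve_vector) <= 0), paste0("scenarios.", s$id, ".ve_vector"),
          "explicit VE trajectory must be non-increasing")
    }
  }
  if (isTRUE(params$stroke$enabled)) {
    chk(!is.null(params$stroke$incidence), "stroke", "stroke add-on enabled without incidence table")
    chk(p01(params$stroke$incidence$p_stroke), "stroke.p_stroke", "must lie in [0, 1]")
    chk(params$stroke$relative_risk >= 1, "stroke.relative_risk", "must be >= 1")
    chk(p01(params$stroke$utility_multiplier), "stroke.utility_multiplier", "must lie in [0, 1]")
    chk(params$stroke$cost_per_stroke >= 0, "stroke.cost_per_stroke", "must be >= 0")
  }
  invisible(params)
}

#' Serialize a parameter set back to its configuration form
#'
#' Inverse of [load_parameters()]: converts a `zoster_parameters` object to
#' the nested-list configuration structure and optionally writes it as YAML.
#' `load_parameters(write_parameters(params))` reproduces `params`
#' field-by-field.
#'
#' @param params A `zoster_parameters` object.
#' @param path Optional file path; when given the configuration is written
#'   there as YAML.
#' @return The nested configuration list, invisibly when `path` is given.
#' @export
write_parameters <- function(params, path = NULL) {
  fem <- params$demography$sex == "female"
  inc_f <- params$incidence$sex == "female"
  ub_f <- params$utility_baseline$sex == "female"
  cfg <- list(
    demography = list(
      size_female = params$demography$size[fem],
      size_male = params$demography$size[!fem],
      p_death_female = params$demography$p_death[fem],
      p_death_male = params$demography$p_death[!fem]
    ),
    incidence = list(
      p_hz_female = params$incidence$p_hz[inc_f],
      p_hz_male = params$incidence$p_hz[!inc_f]
    ),
    phn = list(mean = params$phn$mean, se = params$phn$se, dist = params$phn$dist),
    hz_severity = list(
      under70 = params$hz_severity$prob[params$hz_severity$age_group == "<70"],
      over70 = params$hz_severity$prob[params$hz_severity$age_group == ">=70"]
    ),
    phn_severity = list(prob = params$phn_severity$prob),
    durations = list(
      hz_months = params$durations$hz_months,
      phn_months_mild = unname(params$durations$phn_months[["mild"]]),
      phn_months_moderate = unname(params$durations$phn_months[["moderate"]]),
      phn_months_severe = unname(params$durations$phn_months[["severe"]])
    ),
    utility_baseline = list(
      mean_female = params$utility_baseline$mean[ub_f],
      se_female = params$utility_baseline$se[ub_f],
      mean_male = params$utility_baseline$mean[!ub_f],
      se_male = params$utility_baseline$se[!ub_f],
      dist = params$utility_baseline$dist[ub_f]
    ),
    utility_multipliers = list(
      value = params$utility_multipliers$value,
      alpha = params$utility_multipliers$alpha,
      beta = params$utility_multipliers$beta,
      dist = params$utility_multipliers$dist
    ),
    visits = list(
      primary = params$visits$primary,
      outpatient = params$visits$outpatient,
      inpatient = params$visits$inpatient,
      dist = params$visits$dist,
      n_trials = params$visits$n
    ),
    uptake = params$uptake,
    complication_mix = list(prob = params$complication_mix$prob),
    costs = list(
      vaccine_price_per_dose = params$costs$vaccine_price_per_dose,
      administration_per_dose = params$costs$administration_per_dose,
      primary_care_visit = params$costs$primary_care_visit,
      outpatient = unname(params$costs$outpatient),
      inpatient_episode = params$costs$inpatient_episode,
      antiviral_course = params$costs$antiviral_course,
      analgesic_per_month = params$costs$analgesic_per_month,
      antiviral_per_dose = params$costs$antiviral_per_dose,
      analgesic_per_dose = params$costs$analgesic_per_dose,
      currency = params$costs$currency
    ),
    program = params$program,
    economics = params$economics,
    scenarios = lapply(params$scenarios, function(s) {
      s[!vapply(s, is.null, logical(1L))]
    }),
    stroke = if (is.null(params$stroke$incidence)) {
      list(enabled = params$stroke$enabled)
    } else {
      sf <- params$stroke$incidence$sex == "female"
      list(
        enabled = params$stroke$enabled,
        p_stroke_female = params$stroke$incidence$p_stroke[sf],
        p_stroke_male = params$stroke$incidence$p_stroke[!sf],
        relative_risk = params$stroke$relative_risk,
        cost_per_stroke = params$stroke$cost_per_stroke,
        utility_multiplier = params$stroke$utility_multiplier
      )
    },
    metadata = params$metadata
  )
  if (!is.null(path)) {
    yaml::write_yaml(cfg, path, precision = 15L)
    return(invisible(cfg))
  }
  cfg
}

#' Override a single scalar field of a parameter set
#'
#' Addresses a leaf by a dot-separated path (for example
#' `"economics.discount_rate"` or `"scenarios.rct.post10"`), replaces its
#' value and revalidates. Unknown paths raise an error naming the path,
#' which is what the one-way sensitivity runner relies on.
#'
#' @param params A `zoster_parameters` object.
#' @param path Dot-separated field path.
#' @param value Replacement value.
#' @return The modified, revalidated parameter set.
#' @export
modify_parameters <- function(params, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1L]]
  node <- params
  for (k in keys) {
    if (is.null(node[[k]])) stop("override path not found: '", path, "'", call. = FALSE)
    node <- node[[k]]
  }
  params[[keys]] <- value
  params <- renormalize_severity(params)
  validate_parameters(params)
  params
}

#' Export the parameter tables in tidy long form
#'
#' One row per table x age band x sex x quantity, suitable for CSV export
#' and inspection alongside the source tables.
#'
#' @param params A `zoster_parameters` object.
#' @return A data frame with columns `table`, `group`, `sex`, `quantity`,
#'   `value`.
#' @export
tidy_parameters <- function(params) {
  rows <- list(
    data.frame(table = "demography", group = params$demography$age_band,
               sex = params$demography$sex, quantity = "size",
               value = params$demography$size),
    data.frame(table = "demography", group = params$demography$age_band,
               sex = params$demography$sex, quantity = "p_death",
               value = params$demography$p_death),
    data.frame(table = "incidence", group = params$incidence$age_band,
               sex = params$incidence$sex, quantity = "p_hz",
               value = params$incidence$p_hz),
    data.frame(table = "phn", group = params$phn$age_band, sex = "both",
               quantity = "mean", value = params$phn$mean),
    data.frame(table = "phn", group = params$phn$age_band, sex = "both",
               quantity = "se", value = params$phn$se),
    data.frame(table = "hz_severity",
               group = paste(params$hz_severity$age_group, params$hz_severity$severity),
               sex = "both", quantity = "prob", value = params$hz_severity$prob),
    data.frame(table = "utility_baseline", group = params$utility_baseline$age_band,
               sex = params$utility_baseline$sex, quantity = "mean",
               value = params$utility_baseline$mean),
    data.frame(table = "utility_multipliers", group = params$utility_multipliers$severity,
               sex = "both", quantity = "value", value = params$utility_multipliers$value),
    data.frame(table = "visits",
               group = rep(params$visits$category, 3L), sex = "both",
               quantity = rep(c("primary", "outpatient", "inpatient"),
                              each = nrow(params$visits)),
               value = c(params$visits$primary, params$visits$outpatient,
                         params$visits$inpatient)),
    data.frame(table = "costs", group = c(
                 "vaccine_price_per_dose", "administration_per_dose",
                 "primary_care_visit", "inpatient_episode", "antiviral_course",
                 "analgesic_per_month", paste0("outpatient.", names(params$costs$outpatient))),
               sex = "both", quantity = "eur",
               value = c(params$costs$vaccine_price_per_dose,
                         params$costs$administration_per_dose,
                         params$costs$primary_care_visit,
                         params$costs$inpatient_episode,
                         params$costs$antiviral_course,
                         params$costs$analgesic_per_month,
                         unname(params$costs$outpatient)))
  )
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.zoster_parameters <- function(x, ...) {
  cat("<zoster_parameters>\n")
  cat("  cohorts: ", paste(.demog_bands, collapse = ", "), "\n", sep = "")
  cat("  total population: ", format(sum(x$demography$size), big.mark = ","), "\n", sep = "")
  cat("  scenarios: ", paste(names(x$scenarios), collapse = ", "), "\n", sep = "")
  cat("  vaccine price/dose: ", x$costs$vaccine_price_per_dose, " ",
      x$costs$currency, "; coverage ", x$program$coverage,
      "; compliance ", x$program$compliance, "\n", sep = "")
  cat("  discount ", x$economics$discount_rate, "; WTP ", x$economics$wtp,
      "; horizon to age ", x$economics$max_age, "\n", sep = "")
  cat("  stroke add-on: ", if (isTRUE(x$stroke$enabled)) "enabled" else "disabled",
      "\n", sep = "")
  invisible(x)
}
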