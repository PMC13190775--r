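#' Draw one probabilistic realisation of the uncertain parameters
#'
#' Samples every field carrying a non-fixed uncertainty distribution and
#' leaves fixed fields untouched: PHN proportions and baseline utilities are
#' Beta with method-of-moments shapes from their mean and SE; pain-state
#' multipliers are Beta with their explicit shape pairs; healthcare visit
#' counts are resampled as Binomial(n, mean/n) counts (expectation equal to
#' the reported mean). Draws are reproducible: the same seed yields the same
#' parameter set.
#'
#' @param params A `zoster_parameters` object.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return A `zoster_parameters` object with sampled values.
#' @export
draw_parameters <- function(params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- params
  for (i in seq_len(nrow(out$phn))) {
    if (out$phn$dist[i] == "beta_mean_se") {
      sh <- beta_from_mean_se(params$phn$mean[i], params$phn$se[i])
      out$phn$mean[i] <- stats::rbeta(1L, sh[["alpha"]], sh[["beta"]])
    }
  }
  for (i in seq_len(nrow(out$utility_baseline))) {
    if (out$utility_baseline$dist[i] == "beta_mean_se") {
      sh <- beta_from_mean_se(params$utility_baseline$mean[i],
                              params$utility_baseline$se[i])
      out$utility_baseline$mean[i] <- stats::rbeta(1L, sh[["alpha"]], sh[["beta"]])
    }
  }
  for (i in seq_len(nrow(out$utility_multipliers))) {
    if (out$utility_multipliers$dist[i] == "beta_shape") {
      out$utility_multipliers$value[i] <- stats::rbeta(
        1L, params$utility_multipliers$alpha[i], params$utility_multipliers$beta[i])
    }
  }
  for (i in seq_len(nrow(out$visits))) {
    if (out$visits$dist[i] == "binomial") {
      n <- params$visits$n[i]
      out$visits$primary[i] <- stats::rbinom(1L, n, params$visits$primary[i] / n)
      out$visits$outpatient[i] <- stats::rbinom(1L, n, params$visits$outpatient[i] / n)
      out$visits$inpatient[i] <- stats::rbinom(1L, n, params$visits$inpatient[i] / n)
    }
  }
  out
}

#' Probabilistic sensitivity analysis
#'
#' Repeats the full cohort comparison under parameter sets drawn from their
#' uncertainty distributions and summarises the incremental outcomes with
#' means and empirical 2.5th/97.5th percentiles (a 95% credible interval).
#' One master seed deterministically derives an independent substream seed
#' per draw, so results are reproducible and individual draws can be
#' re-created in isolation.
#'
#' @param params A `zoster_parameters` object.
#' @param n_draws Number of Monte Carlo draws (default 1000).
#' @param seed Master seed.
#' @param start_age Cohort band lower age.
#' @param scenario Efficacy scenario id.
#' @return An object of class `psa_result`: per-draw data frame (`draws`),
#'   summary table (`summary` with mean and CrI for incremental QALYs, cost
#'   offset, net cost and ICER), `seed`, `n_draws`, cohort metadata.
#' @export
run_psa <- function(params, n_draws = 1000, seed = 1, start_age = 65,
                    scenario = "rct") {
  if (n_draws < 2) stop("n_draws must be >= 2")
  set.seed(seed)
  draw_seeds <- sample.int(.Machine$integer.max - 1L, n_draws)
  rows <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    p_i <- draw_parameters(params, seed = draw_seeds[i])
    r <- run_comparison(start_age, p_i, scenario, keep_traces = FALSE)
    rows[[i]] <- data.frame(draw = i, d_qalys = r$d_qalys,
                            cost_offset = r$cost_offset, net_cost = r$net_cost,
                            icer = r$icer)
  }
  draws <- do.call(rbind, rows)
  summarise <- function(x) {
    q <- stats::quantile(x, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
    c(mean = mean(x, na.rm = TRUE), lo = q[1], hi = q[2])
  }
  summary <- rbind(
    d_qalys = summarise(draws$d_qalys),
    cost_offset = summarise(draws$cost_offset),
    net_cost = summarise(draws$net_cost),
    icer = summarise(draws$icer)
  )
  structure(list(draws = draws, summary = as.data.frame(summary),
                 ratio_of_means_icer = mean(draws$net_cost) / mean(draws$d_qalys),
                 seed = seed, n_draws = n_draws,
                 start_age = start_age, scenario = scenario),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat("<psa_result> cohort ", x$start_age, "+, scenario ", x$scenario,
      ", ", x$n_draws, " draws (seed ", x$seed, ")\n", sep = "")
  s <- x$summary
  fmt <- function(r) paste0(format(round(s[r, "mean"], 1), big.mark = ","),
                            " (", format(round(s[r, "lo"], 1), big.mark = ","),
                            " - ", format(round(s[r, "hi"], 1), big.mark = ","), ")")
  cat("  incremental QALYs: ", fmt("d_qalys"), "\n", sep = "")
  cat("  cost offset: ", fmt("cost_offset"), "\n", sep = "")
  cat("  net cost: ", fmt("net_cost"), "\n", sep = "")
  cat("  per-draw ICER mean: ", format(round(s["icer", "mean"]), big.mark = ","),
      "; ratio-of-means ICER: ", format(round(x$ratio_of_means_icer), big.mark = ","),
      "\n", sep = "")
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws with
#' positive net monetary benefit (`wtp * dQALY - net cost > 0`).
#'
#' @param psa A [run_psa()] result.
#' @param wtp_grid Numeric vector of willingness-to-pay values (EUR/QALY).
#' @return Data frame with columns `wtp` and `p_cost_effective`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 500000, by = 10000)) {
  if (length(wtp_grid) < 1L) stop("wtp_grid must be non-empty")
  p <- vapply(wtp_grid, function(w) {
    mean(w * psa$draws$d_qalys - psa$draws$net_cost > 0)
  }, numeric(1L))
  data.frame(wtp = wtp_grid, p_cost_effective = p)
}

#' Define a one-way sensitivity scenario
#'
#' A named bundle of deterministic changes to the base-case parameter set:
#' scalar overrides by field path, a unit-cost scale factor (applied to all
#' healthcare unit costs but not the vaccine price), the
#' no-protection-after-year-10 switch, a PHN-proportion shift in SE units,
#' replacement pain-multiplier values, and the stroke add-on toggle.
#'
#' @param name Scenario label.
#' @param overrides Named list mapping dot-separated paths (see
#'   [modify_parameters()]) to replacement values.
#' @param cost_scale Multiplier on healthcare unit costs (default 1).
#' @param post10_zero Set both scenarios' protection to zero after year 10.
#' @param phn_shift_se Shift every PHN proportion by this many of its SEs
#'   (e.g. -1.96 / +1.96 for normal-approximation 95% bounds).
#' @param multipliers Optional numeric vector `c(mild, moderate, severe)`
#'   replacing the pain-state utility multipliers (alternative decrement
#'   sets from other evaluations; values must be user-supplied).
#' @param stroke Enable the stroke add-on (requires stroke tables in the
#'   parameter set).
#' @param group Optional grouping label for paired low/high scenarios in
#'   tornado displays.
#' @return A list of class `one_way_scenario`.
#' @export
one_way_scenario <- function(name, overrides = list(), cost_scale = 1,
                             post10_zero = FALSE, phn_shift_se = 0,
                             multipliers = NULL, stroke = FALSE,
                             group = name) {
  structure(list(name = name, overrides = overrides, cost_scale = cost_scale,
                 post10_zero = post10_zero, phn_shift_se = phn_shift_se,
                 multipliers = multipliers, stroke = stroke, group = group),
            class = "one_way_scenario")
}

apply_one_way <- function(params, sc) {
  p <- params
  for (path in names(sc$overrides)) {
    p <- modify_parameters(p, path, sc$overrides[[path]])
  }
  if (sc$cost_scale != 1) {
    for (f in c("administration_per_dose", "primary_care_visit",
                "inpatient_episode", "antiviral_course", "analgesic_per_month")) {
      p$costs[[f]] <- p$costs[[f]] * sc$cost_scale
    }
    p$costs$outpatient <- p$costs$outpatient * sc$cost_scale
  }
  if (isTRUE(sc$post10_zero)) {
    for (sid in names(p$scenarios)) p$scenarios[[sid]]$post10 <- "zero"
  }
  if (sc$phn_shift_se != 0) {
    p$phn$mean <- pmin(pmax(p$phn$mean + sc$phn_shift_se * p$phn$se, 1e-6), 1 - 1e-6)
  }
  if (!is.null(sc$multipliers)) {
    p$utility_multipliers$value <- sc$multipliers
  }
  if (isTRUE(sc$stroke)) {
    if (is.null(p$stroke$incidence)) {
      stop("scenario '", sc$name, "' enables the stroke add-on but the ",
           "parameter set has no stroke tables")
    }
    p$stroke$enabled <- TRUE
  }
  validate_parameters(p)
  p
}

#' Standard one-way sensitivity scenario set
#'
#' The deterministic scenario battery varied one at a time around the base
#' case: discount rate 0% and 5%; first-dose coverage 50% and 70%;
#' second-dose compliance 50% and 100%; no protection after year 10; PHN
#' proportion at its lower and upper 95% bounds (normal approximation from
#' the reported SEs); all healthcare unit costs 40% lower and higher.
#' Scenarios requiring values not shipped with the base case (stroke add-on,
#' age-specific efficacy vectors, alternative pain-decrement sets) are
#' constructible with [one_way_scenario()] once the user supplies them.
#'
#' @return Named list of [one_way_scenario()] objects.
#' @export
standard_one_way_scenarios <- function() {
  list(
    discount_0 = one_way_scenario("0% discount",
      overrides = list(economics.discount_rate = 0), group = "discount"),
    discount_5 = one_way_scenario("5% discount",
      overrides = list(economics.discount_rate = 0.05), group = "discount"),
    uptake1_50 = one_way_scenario("dose-1 coverage 50%",
      overrides = list(program.coverage = 0.50), group = "uptake dose 1"),
    uptake1_70 = one_way_scenario("dose-1 coverage 70%",
      overrides = list(program.coverage = 0.70), group = "uptake dose 1"),
    uptake2_50 = one_way_scenario("dose-2 compliance 50%",
      overrides = list(program.compliance = 0.50), group = "uptake dose 2"),
    uptake2_100 = one_way_scenario("dose-2 compliance 100%",
      overrides = list(program.compliance = 1.0), group = "uptake dose 2"),
    no_protection_10y = one_way_scenario("no protection after 10 years",
      post10_zero = TRUE),
    phn_lower = one_way_scenario("PHN proportion, lower 95% bound",
      phn_shift_se = -1.96, group = "PHN proportion"),
    phn_upper = one_way_scenario("PHN proportion, upper 95% bound",
      phn_shift_se = 1.96, group = "PHN proportion"),
    costs_m40 = one_way_scenario("unit costs -40%", cost_scale = 0.6,
      group = "unit costs"),
    costs_p40 = one_way_scenario("unit costs +40%", cost_scale = 1.4,
      group = "unit costs")
  )
}

#' Run one-way sensitivity analyses
#'
#' One deterministic model evaluation per scenario and efficacy scenario,
#' with the base case included as the first row.
#'
#' @param params Base-case `zoster_parameters`.
#' @param scenarios List of [one_way_scenario()] objects (default the
#'   standard battery).
#' @param start_age Cohort band lower age.
#' @param efficacy Character vector of efficacy scenario ids to evaluate.
#' @return Data frame with one row per scenario x efficacy scenario:
#'   `scenario`, `group`, `efficacy`, `icer`, `d_qalys`, `net_cost`.
#' @export
run_one_way <- function(params, scenarios = standard_one_way_scenarios(),
                        start_age = 65,
                        efficacy = c("rct", "observational")) {
  base_sc <- one_way_scenario("base case")
  all_sc <- c(list(base_sc), scenarios)
  rows <- list()
  for (i in seq_along(all_sc)) {
    sc <- all_sc[[i]]
    p <- apply_one_way(params, sc)
    for (ef in efficacy) {
      r <- run_comparison(start_age, p, ef, keep_traces = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc$name, group = sc$group, efficacy = ef,
        icer = r$icer, d_qalys = r$d_qalys, net_cost = r$net_cost,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tornado summary of one-way results
#'
#' Orders scenarios by the absolute departure of their ICER from the base
#' case, grouping paired low/high variants, for tornado-diagram tables.
#'
#' @param one_way A [run_one_way()] result (single efficacy scenario).
#' @return Data frame sorted by descending group impact, with columns
#'   `group`, `scenario`, `icer`, `delta`.
#' @export
tornado <- function(one_way) {
  ef <- unique(one_way$efficacy)
  if (length(ef) > 1L) {
    stop("tornado expects results for a single efficacy scenario; filter first")
  }
  base <- one_way$icer[one_way$scenario == "base case"]
  if (length(base) != 1L) stop("one-way table must contain the base case row")
  rest <- one_way[one_way$scenario != "base case", , drop = FALSE]
  rest$delta <- rest$icer - base
  impact <- tapply(abs(rest$delta), rest$group, max)
  rest <- rest[order(-impact[rest$group], rest$group, rest$delta), ,
               drop = FALSE]
  out <- rest[, c("group", "scenario", "icer", "delta")]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base
  out
}
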