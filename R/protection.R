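#' Two-dose vaccine efficacy at a given model year
#'
#' Evaluates the protection curve of an efficacy scenario. Under the
#' parametric rule the year-1 value declines linearly by the annual waning
#' rate in absolute percentage points and is floored at zero; under the
#' `post10 = "zero"` sensitivity switch protection stops entirely after year
#' 10. An explicit year-by-year trajectory (`ve_vector`) overrides the
#' parametric rule for the years it covers, with the parametric rule
#' continuing beyond it.
#'
#' @param scenario One scenario entry of a `zoster_parameters` object, or its
#'   name together with `params`.
#' @param year Model year, integer >= 1 (vectorized).
#' @param params Optional `zoster_parameters` from which to look `scenario`
#'   up by name.
#' @return Vaccine efficacy in \[0, 1\], same length as `year`.
#' @examples
#' p <- basecase_fixture()
#' ve_two_dose("rct", 1, p)            # 0.977
#' ve_two_dose("observational", 2, p)  # 0.761
#' @export
ve_two_dose <- function(scenario, year, params = NULL) {
  if (is.character(scenario)) {
    if (is.null(params)) stop("supply 'params' when naming a scenario")
    if (is.null(params$scenarios[[scenario]])) stop("unknown scenario: ", scenario)
    scenario <- params$scenarios[[scenario]]
  }
  if (any(year < 1)) stop("model year must be >= 1")
  ve <- pmax(scenario$ve_year1 - (year - 1) * scenario$waning, 0)
  if (!is.null(scenario$ve_vector)) {
    k <- length(scenario$ve_vector)
    use <- year <= k
    ve[use] <- scenario$ve_vector[year[use]]
    if (any(!use)) {
      # continue waning from the last explicit value
      tail_ve <- scenario$ve_vector[k]
      ve[!use] <- pmax(tail_ve - (year[!use] - k) * scenario$waning, 0)
    }
  }
  if (identical(scenario$post10, "zero")) ve[year > 10] <- 0
  ve
}

#' One-dose vaccine efficacy at a given model year
#'
#' The single-dose effect is applied only in the first model year (its
#' waning beyond that is too uncertain to extrapolate); zero afterwards.
#'
#' @inheritParams ve_two_dose
#' @return Vaccine efficacy in \[0, 1\], same length as `year`.
#' @export
ve_one_dose <- function(scenario, year, params = NULL) {
  if (is.character(scenario)) {
    if (is.null(params)) stop("supply 'params' when naming a scenario")
    if (is.null(params$scenarios[[scenario]])) stop("unknown scenario: ", scenario)
    scenario <- params$scenarios[[scenario]]
  }
  if (any(year < 1)) stop("model year must be >= 1")
  ifelse(year == 1, scenario$one_dose_ve_year1, 0)
}

#' Population-average incidence multiplier for the vaccinated arm
#'
#' Combines program coverage c and second-dose compliance q with the one- and
#' two-dose protection curves into the per-year multiplier applied to HZ
#' incidence in the vaccinated arm:
#' \deqn{m(t) = 1 - c \, [\, q \, VE_2(t) + (1-q) \, VE_1(t) \,]}
#' The unvaccinated fraction contributes multiplier 1. The same multiplier
#' applies to first and recurrent episodes.
#'
#' @param scenario Scenario entry or name (see [ve_two_dose()]).
#' @param program The `program` element of a `zoster_parameters` object
#'   (coverage, compliance), or the full parameter set.
#' @param horizon Number of model years, >= 1.
#' @param params Optional parameter set for scenario lookup by name.
#' @return An object of class `protection_profile`: numeric vector of
#'   per-year multipliers in \[0, 1\], with the scenario id as attribute.
#' @export
build_protection_profile <- function(scenario, program, horizon, params = NULL) {
  if (horizon < 1) stop("horizon must be >= 1")
  if (inherits(program, "zoster_parameters")) program <- program$program
  if (is.character(scenario)) {
    if (is.null(params)) stop("supply 'params' when naming a scenario")
    scenario <- params$scenarios[[scenario]]
    if (is.null(scenario)) stop("unknown scenario")
  }
  years <- seq_len(horizon)
  ve2 <- ve_two_dose(scenario, years)
  ve1 <- ve_one_dose(scenario, years)
  m <- 1 - program$coverage * (program$compliance * ve2 +
                               (1 - program$compliance) * ve1)
  structure(m, class = "protection_profile", scenario = scenario$id)
}

#' @export
print.protection_profile <- function(x, ...) {
  cat("<protection_profile> scenario:", attr(x, "scenario"),
      "| horizon:", length(x), "years\n")
  cat("  incidence multiplier year 1:", format(x[1], digits = 4),
      "-> year", length(x), ":", format(x[length(x)], digits = 4), "\n")
  invisible(x)
}
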