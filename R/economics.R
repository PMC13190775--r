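#' Run both arms of one age cohort (both sexes) and difference them
#'
#' Convenience driver: builds the female and male traces for the vaccinated
#' and unvaccinated arms of one 5-year age cohort under one efficacy
#' scenario and returns the incremental comparison.
#'
#' @param start_age Lower age of the cohort band (65, 70, ..., 100).
#' @param params A `zoster_parameters` object.
#' @param scenario Efficacy scenario id, e.g. `"rct"` or `"observational"`.
#' @param keep_traces Attach the four traces to the result (default `TRUE`).
#' @return A [ce_result] object.
#' @export
run_comparison <- function(start_age, params, scenario = "rct",
                           keep_traces = TRUE) {
  horizon <- params$economics$max_age - start_age + 1L
  prof <- build_protection_profile(params$scenarios[[scenario]],
                                   params$program, horizon)
  arms <- lapply(c(no_vaccination = "no_vaccination", rzv = "rzv"), function(arm) {
    lapply(c("female", "male"), function(sx) {
      run_cohort(cohort_spec(start_age, sx, arm = arm, scenario = scenario,
                             params = params),
                 params,
                 protection = if (arm == "rzv") prof else NULL)
    })
  })
  res <- incremental_result(arms$rzv, arms$no_vaccination)
  res$start_age <- start_age
  res$scenario <- scenario
  if (keep_traces) res$traces <- arms
  res
}

#' Incremental cost-effectiveness comparison of two arms
#'
#' Differences the discounted totals of the vaccinated and unvaccinated
#' traces of the same cohort: incremental QALYs, vaccination cost, the HZ
#' direct-cost offset (costs avoided by vaccination, reported positive), the
#' net cost (vaccination cost minus offset), and the ICER (net cost per QALY
#' gained). A zero or negative QALY gain leaves the ICER flagged undefined
#' (`NA`) rather than dividing.
#'
#' @param vax,novax A `cohort_trace` or list of traces (one per sex) for the
#'   vaccinated and unvaccinated arm, covering the same cohort.
#' @return An object of class `ce_result` with elements `d_qalys`,
#'   `d_episodes`, `d_phn`, `vaccination_cost`, `cost_offset`, `net_cost`,
#'   `icer`, `icer_defined`, plus undiscounted totals per arm.
#' @export
incremental_result <- function(vax, novax) {
  spec_of <- function(x) {
    if (inherits(x, "cohort_trace")) x <- list(x)
    lapply(x, function(tr) {
      sp <- attr(tr, "spec")
      list(start_age = sp$start_age, sex = sp$sex, size = sp$size)
    })
  }
  sv <- spec_of(vax); sn <- spec_of(novax)
  if (!identical(sv, sn)) {
    stop("vaccinated and unvaccinated traces describe different cohorts")
  }
  tv <- trace_totals(vax)
  tn <- trace_totals(novax)
  d_qalys <- tv[["qalys_disc"]] - tn[["qalys_disc"]]
  vaccination_cost <- tv[["cost_vaccination_disc"]] - tn[["cost_vaccination_disc"]]
  cost_offset <- tn[["cost_hz_disc"]] - tv[["cost_hz_disc"]]
  net_cost <- vaccination_cost - cost_offset
  defined <- is.finite(d_qalys) && d_qalys > 0
  structure(list(
    d_qalys = d_qalys,
    d_episodes = tv[["episodes"]] - tn[["episodes"]],
    d_phn = tv[["phn_cases"]] - tn[["phn_cases"]],
    vaccination_cost = vaccination_cost,
    cost_offset = cost_offset,
    net_cost = net_cost,
    icer = if (defined) net_cost / d_qalys else NA_real_,
    icer_defined = defined,
    totals_vax = tv,
    totals_novax = tn
  ), class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat("<ce_result>", if (!is.null(x$start_age)) paste0("cohort ", x$start_age, "+"),
      if (!is.null(x$scenario)) paste0("scenario ", x$scenario), "\n")
  cat("  HZ episodes averted: ", format(round(-x$d_episodes), big.mark = ","),
      "; PHN averted: ", format(round(-x$d_phn), big.mark = ","), "\n", sep = "")
  cat("  incremental QALYs: ", format(round(x$d_qalys, 1), big.mark = ","), "\n", sep = "")
  cat("  vaccination cost: ", format(round(x$vaccination_cost), big.mark = ","),
      "; HZ cost offset: ", format(round(x$cost_offset), big.mark = ","), "\n", sep = "")
  cat("  net cost: ", format(round(x$net_cost), big.mark = ","), "\n", sep = "")
  if (x$icer_defined) {
    cat("  ICER: ", format(round(x$icer), big.mark = ","), " EUR/QALY\n", sep = "")
  } else {
    cat("  ICER: undefined (QALY gain <= 0)\n")
  }
  invisible(x)
}

#' Vaccine price at which the ICER equals the willingness-to-pay
#'
#' Net cost is linear in the price per dose (`net(p) = doses * p + constant`
#' with QALY gain unaffected), so the threshold solves in closed form:
#' `p* = (wtp * dQALY - constant) / doses`. The solution is verified by
#' re-running the model at `p*`; if an enabled add-on breaks linearity the
#' function falls back to bisection. When even a free vaccine is not
#' cost-effective (or the QALY gain is not positive) the result is flagged
#' instead of returning a negative price.
#'
#' @param params A `zoster_parameters` object.
#' @param start_age Cohort band lower age.
#' @param scenario Efficacy scenario id.
#' @param wtp Willingness-to-pay per QALY (defaults to the parameter set's).
#' @return List of class `threshold_price_result`: `wtp`, `price`,
#'   `doses`, `net_cost_intercept`, `icer_at_price`, `achievable`.
#' @export
threshold_price <- function(params, start_age = 65, scenario = "rct",
                            wtp = params$economics$wtp) {
  run_at <- function(p) {
    run_comparison(start_age,
                   modify_parameters(params, "costs.vaccine_price_per_dose", p),
                   scenario, keep_traces = FALSE)
  }
  r0 <- run_at(0)
  r1 <- run_at(100)
  if (!r0$icer_defined) {
    return(structure(list(wtp = wtp, price = NA_real_, achievable = FALSE,
                          reason = "QALY gain not positive"),
                     class = "threshold_price_result"))
  }
  doses <- (r1$net_cost - r0$net_cost) / 100
  if (doses <= 0) stop("net cost is not increasing in price; no threshold exists")
  price <- (wtp * r0$d_qalys - r0$net_cost) / doses
  if (price < 0) {
    return(structure(list(wtp = wtp, price = NA_real_, doses = doses,
                          net_cost_intercept = r0$net_cost, achievable = FALSE,
                          reason = "not cost-effective at any non-negative price"),
                     class = "threshold_price_result"))
  }
  check <- run_at(price)
  if (abs(check$icer - wtp) / wtp > 1e-6) {
    # nonlinearity guard: bisection on ICER(p) - wtp over a wide bracket
    lo <- 0; hi <- max(price * 4, 1000)
    f <- function(p) run_at(p)$icer - wtp
    flo <- f(lo); fhi <- f(hi)
    if (flo > 0 || fhi < 0) stop("no threshold price within [0, ", hi, "]")
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
      if ((hi - lo) / max(1, hi) < 1e-12) break
    }
    price <- (lo + hi) / 2
    check <- run_at(price)
  }
  structure(list(wtp = wtp, price = price, doses = doses,
                 net_cost_intercept = r0$net_cost,
                 icer_at_price = check$icer, achievable = TRUE),
            class = "threshold_price_result")
}

#' @export
print.threshold_price_result <- function(x, ...) {
  cat("<threshold_price_result> WTP ", format(x$wtp, big.mark = ","), " EUR/QALY\n", sep = "")
  if (isTRUE(x$achievable)) {
    cat("  threshold price per dose: ", format(round(x$price, 2), big.mark = ","),
        " EUR (doses delivered: ", format(round(x$doses), big.mark = ","), ")\n", sep = "")
  } else {
    cat("  no threshold price: ", x$reason, "\n", sep = "")
  }
  invisible(x)
}

#' Population-weighted combined-cohort ICER
#'
#' The combined estimate for a multi-cohort (catch-up) program is the
#' population-size-weighted mean of the per-cohort ICERs. Note this is a
#' mean of ratios, not the ratio of pooled sums; [pooled_icer()] gives the
#' latter. Any cohort with an undefined ICER aborts with an error naming it.
#'
#' @param results List of [ce_result] objects.
#' @param weights Positive cohort sizes, same length as `results`; defaults
#'   to each result's cohort population when traces were kept.
#' @return Combined ICER in EUR per QALY.
#' @export
combined_cohort_icer <- function(results, weights = NULL) {
  if (length(results) < 1L) stop("need at least one cohort result")
  bad <- vapply(results, function(r) !isTRUE(r$icer_defined), logical(1L))
  if (any(bad)) {
    labs <- vapply(results[bad], function(r) {
      if (is.null(r$start_age)) "<unnamed>" else paste0(r$start_age, "+")
    }, character(1L))
    stop("undefined ICER in cohorts: ", paste(labs, collapse = ", "))
  }
  if (is.null(weights)) {
    weights <- vapply(results, function(r) {
      if (is.null(r$traces)) stop("supply 'weights' when traces were not kept")
      sum(vapply(r$traces$no_vaccination, function(tr) attr(tr, "spec")$size,
                 numeric(1L)))
    }, numeric(1L))
  }
  if (length(weights) != length(results) || any(weights <= 0)) {
    stop("weights must be positive and match the number of results")
  }
  icers <- vapply(results, `[[`, numeric(1L), "icer")
  sum(weights * icers) / sum(weights)
}

#' Pooled-sums ICER across cohorts
#'
#' Ratio of summed incremental net costs to summed incremental QALYs — the
#' alternative aggregate to the weighted mean of per-cohort ratios.
#'
#' @inheritParams combined_cohort_icer
#' @return Pooled ICER in EUR per QALY.
#' @export
pooled_icer <- function(results) {
  dq <- sum(vapply(results, `[[`, numeric(1L), "d_qalys"))
  nc <- sum(vapply(results, `[[`, numeric(1L), "net_cost"))
  if (dq <= 0) stop("pooled QALY gain is not positive; ICER undefined")
  nc / dq
}

#' ICER as a function of vaccine price
#'
#' Evaluates the comparison over a grid of prices per dose, for
#' price-sweep tables and threshold-price illustrations.
#'
#' @param params A `zoster_parameters` object.
#' @param start_age Cohort band lower age (vectorized over cohorts).
#' @param scenario Efficacy scenario id.
#' @param prices Numeric vector of prices per dose.
#' @return Data frame with columns `start_age`, `scenario`, `price`,
#'   `net_cost`, `d_qalys`, `icer`.
#' @export
price_sweep <- function(params, start_age = 65, scenario = "rct",
                        prices = seq(0, 200, by = 10)) {
  rows <- lapply(start_age, function(a) {
    per_price <- lapply(prices, function(p) {
      r <- run_comparison(a, modify_parameters(params, "costs.vaccine_price_per_dose", p),
                          scenario, keep_traces = FALSE)
      data.frame(start_age = a, scenario = scenario, price = p,
                 net_cost = r$net_cost, d_qalys = r$d_qalys, icer = r$icer)
    })
    do.call(rbind, per_price)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
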