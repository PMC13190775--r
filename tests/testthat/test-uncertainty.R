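make_fixed <- function(p) {
  p$phn$dist <- "fixed"
  p$utility_baseline$dist <- "fixed"
  p$utility_multipliers$dist <- "fixed"
  p$visits$dist <- "fixed"
  p
}

test_that("one-way runner reproduces the base case and applies overrides", {
  p <- toy_params(85)
  ow <- run_one_way(p, scenarios = list(
    none = one_way_scenario("no change"),
    disc0 = one_way_scenario("0% discount",
                             overrides = list(economics.discount_rate = 0))
  ), start_age = 65, efficacy = "rct")
  base <- run_comparison(65, p, "rct", keep_traces = FALSE)
  expect_equal(ow$icer[ow$scenario == "base case"], base$icer)
  expect_equal(ow$icer[ow$scenario == "no change"], base$icer)
  # undiscounted QALY gains are larger, so the ICER falls
  expect_lt(ow$icer[ow$scenario == "0% discount"], base$icer)

  expect_error(
    run_one_way(p, scenarios = list(one_way_scenario("bad",
      overrides = list(no.such.path = 1))), start_age = 65, efficacy = "rct"),
    "no.such.path")
})

test_that("every standard sensitivity scenario is constructible from the fixture", {
  p <- basecase_fixture()
  for (sc in standard_one_way_scenarios()) {
    expect_s3_class(validate_parameters(zostercea:::apply_one_way(p, sc)),
                    "zoster_parameters")
  }
  # the stroke scenario needs user-supplied tables and says so
  expect_error(
    zostercea:::apply_one_way(p, one_way_scenario("stroke", stroke = TRUE)),
    "stroke tables")
})

test_that("tornado orders scenarios by departure from the base case", {
  ow <- data.frame(
    scenario = c("base case", "a low", "a high", "b"),
    group = c("base", "a", "a", "b"),
    efficacy = "rct",
    icer = c(100, 90, 160, 100),
    d_qalys = 1, net_cost = 1)
  tn <- tornado(ow)
  expect_equal(tn$group, c("a", "a", "b"))
  expect_equal(tn$delta, c(-10, 60, 0))
  expect_equal(attr(tn, "base_icer"), 100)
  # zero-impact scenario sorts last
  expect_equal(tn$scenario[nrow(tn)], "b")
})

test_that("PSA is seed-reproducible and degenerates with fixed parameters", {
  p <- toy_params(80)
  a <- run_psa(p, n_draws = 8, seed = 21, start_age = 65, scenario = "rct")
  b <- run_psa(p, n_draws = 8, seed = 21, start_age = 65, scenario = "rct")
  expect_identical(a$draws, b$draws)
  expect_identical(a$summary, b$summary)

  fixed <- make_fixed(p)
  f <- run_psa(fixed, n_draws = 6, seed = 3, start_age = 65, scenario = "rct")
  det <- run_comparison(65, fixed, "rct", keep_traces = FALSE)
  expect_equal(f$summary["d_qalys", "lo"], f$summary["d_qalys", "hi"])
  expect_equal(f$summary["net_cost", "lo"], f$summary["net_cost", "hi"])
  expect_equal(f$summary["d_qalys", "mean"], det$d_qalys)
  expect_equal(f$summary["icer", "mean"], det$icer)
  expect_error(run_psa(p, n_draws = 1), ">= 2")
})

test_that("PSA means converge to the deterministic run for linear outputs", {
  # visit counts enter costs linearly and their binomial draws are unbiased,
  # so with only visits stochastic the PSA mean approaches the point estimate
  p <- toy_params(75)
  p$phn$dist <- "fixed"
  p$utility_baseline$dist <- "fixed"
  p$utility_multipliers$dist <- "fixed"
  det <- run_comparison(65, p, "rct", keep_traces = FALSE)
  psa <- run_psa(p, n_draws = 400, seed = 9, start_age = 65, scenario = "rct")
  se <- sd(psa$draws$cost_offset) / sqrt(400)
  expect_lt(abs(psa$summary["cost_offset", "mean"] - det$cost_offset), 3 * se)
  expect_equal(psa$summary["d_qalys", "mean"], det$d_qalys)
})

test_that("the acceptability curve has the right limits and monotonicity", {
  p <- toy_params(80)
  psa <- run_psa(p, n_draws = 40, seed = 5, start_age = 65, scenario = "rct")
  cv <- ceac(psa, wtp_grid = c(0, 5e4, 1e5, 2e5, 5e5, 1e7))
  # all draws have positive net cost at wtp 0 and positive QALY gains at the top
  expect_equal(cv$p_cost_effective[1], 0)
  expect_equal(cv$p_cost_effective[nrow(cv)], 1)
  expect_true(all(diff(cv$p_cost_effective) >= 0))

  # synthetic symmetric draw set: probability 0.5 at the median ICER
  fake <- list(draws = data.frame(d_qalys = rep(1, 4),
                                  net_cost = c(1, 2, 8, 9)))
  out <- ceac(fake, wtp_grid = 5)
  expect_equal(out$p_cost_effective, 0.5)
  expect_error(ceac(fake, wtp_grid = numeric(0)), "non-empty")
})
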