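test_that("episode QALY loss matches the exhaustive enumeration oracle", {
  p <- basecase_fixture()
  for (age in c(65, 68, 72, 79, 83, 91, 104)) {
    for (sex in c("female", "male")) {
      expect_equal(episode_qaly_loss(age, sex, p),
                   oracle_episode_qaly_loss(age, sex, p),
                   tolerance = 1e-12)
    }
  }
})

test_that("episode QALY loss degenerates correctly", {
  p <- basecase_fixture()
  # multipliers all 1: no decrement anywhere
  p1 <- p
  p1$utility_multipliers$value <- c(1, 1, 1)
  expect_equal(episode_qaly_loss(70, "female", p1), 0)
  # PHN branch off: only the acute month remains
  p2 <- modify_parameters(modify_parameters(p, "phn.se", rep(1e-4, 5)),
                          "phn.mean", rep(1e-6, 5))
  u <- 0.66  # female 70-79 baseline
  sv <- p$hz_severity[p$hz_severity$age_group == ">=70", ]
  mm <- c(no_pain = 1, mild = 0.91, moderate = 0.71, severe = 0.32)
  acute <- sum(sv$prob * (1 - mm[sv$severity])) * u / 12
  expect_equal(episode_qaly_loss(72, "female", p2), acute, tolerance = 1e-3)
})

test_that("episode cost matches the hand sum and the enumeration oracle", {
  p <- basecase_fixture()
  # uncomplicated-only mix without PHN: arithmetic on the printed rows
  p29 <- modify_parameters(p, "complication_mix.prob", c(1, 0, 0, 0, 0))
  p29 <- modify_parameters(modify_parameters(p29, "phn.se", rep(1e-4, 5)),
                           "phn.mean", rep(1e-6, 5))
  hand <- 1.17 * 182 + 0.14 * 369 + 0.05 * 5180 + 0.62 * 18.7 + 0.20 * 16.6 * 1
  expect_equal(episode_cost(67, "female", p29), hand, tolerance = 1e-3)

  for (age in c(66, 74, 88)) {
    expect_equal(episode_cost(age, "female", p), oracle_episode_cost(age, p),
                 tolerance = 1e-12)
  }

  # all visits and uptakes zero: costless episode
  p0 <- p
  p0$visits$primary <- p0$visits$outpatient <- p0$visits$inpatient <- rep(0, 5)
  p0$uptake <- lapply(p0$uptake, function(x) 0)
  expect_equal(episode_cost(70, "female", p0), 0)

  # complicated episodes cost strictly more (higher analgesic uptake), all else equal
  pu <- modify_parameters(p, "complication_mix.prob", c(1, 0, 0, 0, 0))
  pc <- modify_parameters(p, "complication_mix.prob", c(0, 1, 0, 0, 0))
  pc$visits[2, c("primary", "outpatient", "inpatient")] <-
    pu$visits[1, c("primary", "outpatient", "inpatient")]
  pc$costs$outpatient[["B02.2"]] <- pu$costs$outpatient[["B02.9"]]
  expect_gt(episode_cost(70, "female", pc), episode_cost(70, "female", pu))
})

test_that("the cohort trace conserves occupancy and responds to degenerate inputs", {
  p <- toy_params(80)
  tr <- run_cohort(cohort_spec(65, "female", arm = "no_vaccination", params = p), p)
  # conservation: alive(t) = alive(1) - cumulative deaths
  expect_equal(tr$alive, tr$alive[1] - c(0, cumsum(tr$deaths))[seq_len(nrow(tr))])
  expect_true(all(tr$at_risk >= 0))
  expect_true(all(tr$episodes <= tr$alive))

  # certain death in cycle 1 empties the cohort
  pd <- p
  pd$demography$p_death <- rep(1, 16)
  trd <- run_cohort(cohort_spec(65, "female", size = 1,
                                arm = "no_vaccination", params = pd), pd)
  expect_equal(trd$alive[-1], rep(0, nrow(trd) - 1))
  expect_equal(trd$episodes, rep(0, nrow(trd)))

  # zero incidence: QALYs are the discounted survival-weighted baseline utility
  pz <- modify_parameters(p, "incidence.p_hz", rep(0, 16))
  trz <- run_cohort(cohort_spec(65, "female", arm = "no_vaccination", params = pz), pz)
  expect_equal(sum(trz$cost_visits + trz$cost_medication), 0)
  expected_q <- sum(trz$at_risk * zostercea:::baseline_utility(trz$age, "female", pz) *
                    trz$discount)
  expect_equal(sum(trz$qalys_disc), expected_q, tolerance = 1e-12)
})

test_that("zero discounting equates discounted and undiscounted totals", {
  p0 <- modify_parameters(toy_params(90), "economics.discount_rate", 0)
  tr <- run_cohort(cohort_spec(65, "male", arm = "rzv", params = p0), p0)
  tot <- trace_totals(tr)
  expect_equal(tot[["qalys_disc"]], tot[["qalys"]], tolerance = 1e-9)
  expect_equal(tot[["cost_hz_disc"]], tot[["cost_hz"]], tolerance = 1e-9)
})

test_that("outcomes are linear in cohort size and the ICER is invariant", {
  p <- basecase_fixture()
  s1 <- cohort_spec(70, "female", size = 1000, arm = "no_vaccination", params = p)
  s2 <- cohort_spec(70, "female", size = 2000, arm = "no_vaccination", params = p)
  t1 <- trace_totals(run_cohort(s1, p))
  t2 <- trace_totals(run_cohort(s2, p))
  expect_equal(t2, 2 * t1, tolerance = 1e-12)

  r1 <- run_comparison(70, p, "rct")
  ph <- p
  ph$demography$size <- ph$demography$size * 2
  r2 <- run_comparison(70, ph, "rct")
  expect_equal(r2$d_qalys, 2 * r1$d_qalys, tolerance = 1e-9)
  expect_equal(r2$icer, r1$icer, tolerance = 1e-9)
})

test_that("vaccination never increases episode counts when VE is non-negative", {
  p <- basecase_fixture()
  for (sc in c("rct", "observational")) {
    r <- run_comparison(65, p, sc)
    for (i in 1:2) {
      expect_true(all(r$traces$rzv[[i]]$episodes <=
                      r$traces$no_vaccination[[i]]$episodes + 1e-12))
    }
  }
})

test_that("the expectation engine agrees with a per-person microsimulation", {
  p <- toy_params(67)  # 3 cycles
  n <- 2e5
  for (arm in c("no_vaccination", "rzv")) {
    sim <- oracle_microsim(p, 65, "female", arm = arm, scenario = "rct",
                           n_persons = n, seed = 101)
    eng <- engine_per_person(p, 65, "female", arm = arm, scenario = "rct")
    for (q in c("qalys", "costs", "episodes")) {
      se <- sd(sim[[q]]) / sqrt(n)
      expect_lt(abs(mean(sim[[q]]) - eng[[q]]), 3 * se)
    }
  }
})

test_that("a too-short protection profile is rejected", {
  p <- basecase_fixture()
  prof <- build_protection_profile("rct", p$program, 5, p)
  expect_error(run_cohort(cohort_spec(65, "female", arm = "rzv", params = p),
                          p, protection = prof),
               "protection horizon")
})

test_that("the stroke add-on charges excess strokes to the onset cycle", {
  p <- toy_params(75)
  cfg <- write_parameters(p)
  cfg$stroke <- list(enabled = TRUE,
                     p_stroke_female = rep(0.01, 8), p_stroke_male = rep(0.01, 8),
                     relative_risk = 1.8, cost_per_stroke = 50000,
                     utility_multiplier = 0.6)
  ps <- load_parameters(cfg)
  tr0 <- run_cohort(cohort_spec(65, "female", arm = "no_vaccination", params = p), p)
  trs <- run_cohort(cohort_spec(65, "female", arm = "no_vaccination", params = ps), ps)
  excess <- trs$episodes * (1.8 - 1) * 0.01
  expect_equal(trs$cost_stroke, excess * 50000)
  expect_true(all(trs$qalys <= tr0$qalys))
})
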