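test_that("method-of-moments Beta conversion solves the moment equations", {
  sh <- beta_from_mean_se(0.5, 0.1)
  expect_equal(unname(sh), c(12, 12))

  # round trip: shapes -> moments -> inputs, to 1e-12
  for (case in list(c(0.12, 0.022), c(0.75, 0.01), c(0.32, 0.07), c(0.9, 0.02))) {
    sh <- beta_from_mean_se(case[1], case[2])
    a <- sh[["alpha"]]; b <- sh[["beta"]]
    expect_equal(a / (a + b), case[1], tolerance = 1e-12)
    expect_equal(sqrt(a * b / ((a + b)^2 * (a + b + 1))), case[2], tolerance = 1e-12)
  }

  # Beta symmetry: mirroring the mean swaps the shape pair
  s1 <- beta_from_mean_se(0.3, 0.05)
  s2 <- beta_from_mean_se(0.7, 0.05)
  expect_equal(s1[["alpha"]], s2[["beta"]], tolerance = 1e-12)
  expect_equal(s1[["beta"]], s2[["alpha"]], tolerance = 1e-12)

  expect_error(beta_from_mean_se(0.5, 0.6), "no Beta distribution")
  expect_error(beta_from_mean_se(1.2, 0.1), "strictly in")
})

test_that("sampled Beta reproduces the requested mean (Monte Carlo oracle)", {
  m <- 0.3; se <- 0.08
  sh <- beta_from_mean_se(m, se)
  set.seed(42)
  x <- rbeta(1e6, sh[["alpha"]], sh[["beta"]])
  expect_lt(abs(mean(x) - m), 3 * se / 1e3)
  expect_lt(abs(sd(x) - se), 3 * se / 1e3)
})

test_that("distribution_spec validates kind-dependent parameters", {
  expect_s3_class(distribution_spec("beta_mean_se", mean = 0.12, se = 0.022),
                  "distribution_spec")
  expect_error(distribution_spec("beta_mean_se", mean = 0.5, se = 0.6),
               "undefined")
  expect_error(distribution_spec("beta_shape", alpha = -1, beta = 2), "> 0")
  expect_error(distribution_spec("binomial", n = 10.5, mean = 2), "positive integer")
  expect_equal(zostercea:::draw_from_spec(distribution_spec("fixed", mean = 3)), 3)
})

test_that("the base-case fixture reproduces the printed input values", {
  p <- basecase_fixture()
  inc <- p$incidence
  expect_equal(inc$p_hz[inc$age_band == "65-69" & inc$sex == "female"], 0.0071)
  expect_equal(inc$p_hz[inc$age_band == "80-84" & inc$sex == "female"], 0.0119)
  expect_equal(p$costs$vaccine_price_per_dose, 176.4)
  expect_equal(p$costs$inpatient_episode, 5180)
})

test_that("fixture matches every published table value exactly", {
  p <- basecase_fixture()
  dem <- function(sex, col) p$demography[p$demography$sex == sex, col]
  expect_equal(dem("female", "size"),
               c(272568, 275284, 251189, 159458, 100350, 52199, 15643, 2226))
  expect_equal(dem("male", "size"),
               c(267652, 260832, 231607, 131553, 66971, 25549, 5239, 436))
  expect_equal(dem("female", "p_death"),
               c(0.010, 0.016, 0.027, 0.049, 0.093, 0.167, 0.251, 0.353))
  expect_equal(dem("male", "p_death"),
               c(0.008, 0.013, 0.022, 0.042, 0.080, 0.153, 0.315, 0.434))
  inc <- function(sex) p$incidence$p_hz[p$incidence$sex == sex]
  expect_equal(inc("female"),
               c(0.0071, 0.009, 0.0119, 0.0119, 0.0117, 0.0131, 0.011, 0.0083))
  expect_equal(inc("male")[1:7],
               c(0.0051, 0.0068, 0.0079, 0.0092, 0.0088, 0.0089, 0.0042))
  expect_equal(p$phn$mean, c(0.12, 0.15, 0.15, 0.15, 0.16))
  expect_equal(p$phn$se, c(0.022, 0.016, 0.016, 0.015, 0.015))
  # severity rows renormalized to sum to one; printed under-70 row sums to 1.01
  u70 <- p$hz_severity$prob[p$hz_severity$age_group == "<70"]
  expect_equal(u70, c(0.65, 0.24, 0.04, 0.08) / 1.01)
  expect_equal(p$hz_severity$prob[p$hz_severity$age_group == ">=70"],
               c(0.45, 0.41, 0.05, 0.09))
  expect_equal(p$phn_severity$prob, c(0, 0.89, 0.11))
  expect_equal(unname(p$durations$phn_months), c(7, 10, 13))
  ub <- function(sex, col) p$utility_baseline[p$utility_baseline$sex == sex, col]
  expect_equal(ub("female", "mean"), c(0.75, 0.66, 0.57))
  expect_equal(ub("male", "mean"), c(0.78, 0.76, 0.68))
  expect_equal(ub("female", "se"), c(0.010, 0.014, 0.021))
  expect_equal(ub("male", "se"), c(0.012, 0.013, 0.027))
  expect_equal(p$utility_multipliers$value, c(0.91, 0.71, 0.32))
  expect_equal(p$utility_multipliers$alpha, c(81.27, 153, 13.76))
  expect_equal(p$utility_multipliers$beta, c(8.08, 62.55, 29.38))
  expect_equal(p$visits$primary, c(1.17, 1.38, 0.87, 1.00, 1.25))
  expect_equal(p$visits$outpatient, c(0.14, 0.27, 1.82, 0.22, 0.21))
  expect_equal(p$visits$inpatient, c(0.05, 0.14, 0.17, 0.15, 0.11))
  expect_equal(unlist(p$uptake, use.names = FALSE), c(0.62, 0.62, 0.20, 0.50))
  expect_equal(unname(p$costs$outpatient), c(369, 613, 193, 393, 384))
  expect_equal(p$costs$administration_per_dose, 7.2)
  expect_equal(p$costs$primary_care_visit, 182)
  expect_equal(p$costs$antiviral_course, 18.7)
  expect_equal(p$costs$analgesic_per_month, 16.6)
  expect_equal(p$program$coverage, 0.63)
  expect_equal(p$program$compliance, 0.749)
  expect_equal(p$economics$discount_rate, 0.03)
  expect_equal(p$economics$wtp, 80000)
  expect_equal(p$scenarios$rct$ve_year1, 0.977)
  expect_equal(p$scenarios$observational$ve_year1, 0.792)
  expect_equal(p$scenarios$rct$waning, 0.031)
})

test_that("validation rejects out-of-range inputs and names the field", {
  p <- basecase_fixture()
  expect_error(modify_parameters(p, "program.coverage", 1.2), "program.coverage")
  expect_error(modify_parameters(p, "economics.wtp", -1), "economics.wtp")
  expect_error(modify_parameters(p, "not.a.field", 1), "not.a.field")
  bad <- p
  bad$hz_severity$prob[1] <- 0.9  # sum now far from 1
  expect_error(zostercea:::renormalize_severity(bad), "tolerance")
  bad2 <- p
  bad2$utility_multipliers$value <- c(0.3, 0.7, 0.9)
  expect_error(validate_parameters(bad2), "mild > moderate > severe")
})

test_that("parameter sets round-trip through the config representation", {
  p <- basecase_fixture()
  expect_equal(load_parameters(write_parameters(p)), p)
  path <- tempfile(fileext = ".yaml")
  write_parameters(p, path)
  expect_equal(load_parameters(path), p)
})

test_that("draw_parameters respects distributions, means and the seed", {
  p <- basecase_fixture()
  # all-fixed set: drawing changes nothing
  fixed <- p
  fixed$phn$dist <- "fixed"
  fixed$utility_baseline$dist <- "fixed"
  fixed$utility_multipliers$dist <- "fixed"
  fixed$visits$dist <- "fixed"
  expect_equal(draw_parameters(fixed, seed = 7), fixed)

  # determinism: same seed, same draws
  expect_equal(draw_parameters(p, seed = 11), draw_parameters(p, seed = 11))

  # sampled PHN proportion concentrates on its reported mean
  set.seed(5)
  draws <- replicate(1e4, draw_parameters(p)$phn$mean[1])
  expect_lt(abs(mean(draws) - 0.12), 0.002)

  # fixed fields untouched, stochastic fields inside their support
  d <- draw_parameters(p, seed = 3)
  expect_equal(d$incidence, p$incidence)
  expect_equal(d$costs, p$costs)
  expect_true(all(d$phn$mean > 0 & d$phn$mean < 1))
  expect_true(all(d$utility_multipliers$value > 0 & d$utility_multipliers$value < 1))
  expect_true(all(d$visits$primary == round(d$visits$primary)))
})
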