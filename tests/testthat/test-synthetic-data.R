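test_that("generation is deterministic given the seed", {
  c1 <- generate_cohort(sim_config(n_patients = 4, seed = 42), the_catalog)
  c2 <- generate_cohort(sim_config(n_patients = 4, seed = 42), the_catalog)
  c3 <- generate_cohort(sim_config(n_patients = 4, seed = 43), the_catalog)
  expect_identical(c1, c2)
  expect_false(identical(c1, c3))
})

test_that("full compliance plants every required assessment", {
  coh <- generate_cohort(sim_config(n_patients = 6, compliance = 1,
                                    seed = 2), the_catalog)
  rep <- evaluate_catalog(coh, the_catalog, selection = "2a")
  ind <- rep[rep$level == "indicator", ]
  expect_equal(ind$fraction, 1)
  expect_gt(ind$denominator, 0)
})

test_that("generated events carry only registry codings", {
  coh <- generate_cohort(sim_config(n_patients = 5, compliance = 0.5,
                                    seed = 12), the_catalog)
  reg <- qi_registry(the_catalog)
  for (p in coh) {
    expect_true(all(paste(p$events$system, p$events$code) %in%
                      paste(reg$system, reg$code)))
  }
})

test_that("per-day compliance is recovered within binomial tolerance", {
  cfg <- sim_config(n_patients = 120, stay = list(dist = "fixed", days = 10),
                    compliance = 0.7, seed = 31)
  coh <- generate_cohort(cfg, the_catalog)
  rep <- evaluate_catalog(coh, the_catalog, selection = "9b")
  row <- rep[rep$plan_id == "9b-daily", ]
  se <- sqrt(0.7 * 0.3 / row$denominator)
  expect_lt(abs(row$fraction - 0.7), 3 * se)
})

test_that("rate cohorts realize the Poisson target", {
  cfg <- sim_config(n_patients = 200, stay = list(dist = "fixed", days = 50),
                    seed = 3)
  coh <- generate_rate_cohort(cfg, 80)
  plan <- get_indicator(the_catalog, "6b")$plans[[1]]
  r <- evaluate_plan(coh, plan, catalog = the_catalog)
  expect_equal(r$denominator, 10000)
  expect_lt(abs(r$rate - 80), 3 * sqrt(80 / 10))

  none <- generate_rate_cohort(sim_config(n_patients = 5, seed = 4), 0)
  expect_true(all(vapply(none, function(p)
    sum(p$events$code == "30088009") == 0, logical(1))))

  again <- generate_rate_cohort(cfg, 80)
  expect_identical(coh, again)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(compliance = 0.5, prevalence = list(wizards = 1)),
               "unknown prevalence")
  expect_error(generate_cohort(sim_config(compliance = c(`zz` = 0.5)),
                               the_catalog), "unknown sub_id")
  expect_error(generate_cohort(sim_config(compliance = 1.5), the_catalog),
               "lie in")
  expect_error(generate_rate_cohort(sim_config(), -5), ">= 0")
  expect_error(sim_config(stay = list(dist = "fixed", days = 10),
                          n_patients = -1), ">= 0")
})

test_that("geometric stays produce plausible variable lengths", {
  coh <- generate_cohort(sim_config(n_patients = 40,
                                    stay = list(dist = "geometric", mean = 7),
                                    compliance = 0.5, seed = 8), the_catalog)
  lens <- vapply(coh, function(p) length(stay_days(p)), integer(1))
  expect_true(all(lens >= 1))
  expect_gt(length(unique(lens)), 3)
})
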