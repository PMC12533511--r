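test_that("atom matching follows day overlap, comparators and exact units", {
  p <- mk_patient(specs = list(
    list("invasive_ventilation", "2026-01-02 08:00", end = "2026-01-05 12:00"),
    list("oxygenation_index", "2026-01-03 08:00", value = 85),
    list("plateau_pressure", "2026-01-03 09:00", value = 28, unit = "cm H2O")))
  vent <- qi_atom("invasive_ventilation")
  expect_true(atom_matches(p, vent, as.Date("2026-01-04"), the_catalog))
  expect_false(atom_matches(p, vent, as.Date("2026-01-06"), the_catalog))
  oi <- qi_atom("oxygenation_index", qi_comparator("LT", 100))
  expect_true(atom_matches(p, oi, as.Date("2026-01-03"), the_catalog))
  expect_false(atom_matches(p, oi, as.Date("2026-01-04"), the_catalog))
  # comparator with a different unit ignores the event entirely
  pp <- qi_atom("plateau_pressure", qi_comparator("LT", 100, unit = "mmHg"))
  expect_false(atom_matches(p, pp, as.Date("2026-01-03"), the_catalog))
})

test_that("population matching excludes on active orders and composes atoms", {
  pop9 <- get_indicator(the_catalog, "9b")$plans[[1]]$population
  resting <- mk_icu_patient(specs = list(
    list("immobilization_order", "2026-01-01 08:00", end = "2026-01-11 00:00")))
  mobile <- mk_icu_patient()
  expect_false(population_matches(resting, pop9, as.Date("2026-01-03"),
                                  the_catalog))
  expect_true(population_matches(mobile, pop9, as.Date("2026-01-03"),
                                 the_catalog))

  pop3 <- get_indicator(the_catalog, "3a")$plans[[1]]$population
  ards_pt <- mk_icu_patient(specs = list(
    list("ards", "2026-01-01 00:00", end = "2026-01-11 00:00"),
    list("invasive_ventilation", "2026-01-01 00:00", end = "2026-01-11 00:00"),
    list("oxygenation_index", "2026-01-03 08:00", value = 85)))
  expect_true(population_matches(ards_pt, pop3, as.Date("2026-01-03"),
                                 the_catalog))
  expect_false(population_matches(ards_pt, pop3, as.Date("2026-01-04"),
                                  the_catalog)) # no oxygenation index that day
})

test_that("population matching agrees with the truth-table oracle on random cases", {
  set.seed(77)
  keys <- c("mobilization", "invasive_ventilation", "blood_culture",
            "antibiotics", "invasive_device")
  for (rep in 1:25) {
    specs <- list()
    for (k in keys) {
      for (d in 1:3) {
        if (stats::runif(1) < 0.4)
          specs <- c(specs, list(list(k, sprintf("2026-01-%02d 10:00", d))))
      }
    }
    p <- mk_patient(discharge = "2026-01-04 00:00", specs = specs)
    e <- rand_expr(depth = 3, n_atoms = 4)
    # remap the abstract atom names onto concept keys
    remap <- function(x) {
      if (x$kind == "ATOM")
        return(qi_atom(keys[as.integer(sub("a", "", x$concept))]))
      if (x$kind == "NOT") return(qi_not(remap(x$child)))
      qi_combo(x$method, lapply(x$children, remap), n = x$n)
    }
    e <- remap(e)
    day <- as.Date("2026-01-02")
    truth <- vapply(expr_atoms(e), function(a)
      atom_matches(p, a, day, the_catalog), logical(1))
    names(truth) <- vapply(expr_atoms(e), atom_key, character(1))
    truth <- truth[!duplicated(names(truth))]
    expect_identical(population_matches(p, e, day, the_catalog),
                     oracle_eval(e, truth))
  }
})

test_that("per-shift fulfillment requires every shift window of the day", {
  plan <- get_indicator(the_catalog, "2a")$plans[[1]] # sedation assessments
  full <- mk_icu_patient(specs = list(
    list("sedation_assessment", "2026-01-02 07:00"),
    list("sedation_assessment", "2026-01-02 15:00"),
    list("sedation_assessment", "2026-01-02 23:00")))
  partial <- mk_icu_patient(specs = list(
    list("sedation_assessment", "2026-01-02 07:00"),
    list("sedation_assessment", "2026-01-02 15:00")))
  day2 <- c("2026-01-02", "2026-01-02")
  expect_equal(evaluate_plan(list(full), plan, day2, the_catalog)$fraction, 1)
  expect_equal(evaluate_plan(list(partial), plan, day2, the_catalog)$fraction,
               0)
})

test_that("night shift of day d extends past midnight into day d+1", {
  expect_equal(shift_of_time(qi_time("2026-01-03 02:00"),
                             as.Date("2026-01-02")), "night")
  expect_true(is.na(shift_of_time(qi_time("2026-01-03 02:00"),
                                  as.Date("2026-01-03"))))
  plan <- get_indicator(the_catalog, "2a")$plans[[1]]
  p <- mk_icu_patient(specs = list(
    list("sedation_assessment", "2026-01-02 07:00"),
    list("sedation_assessment", "2026-01-02 15:00"),
    list("sedation_assessment", "2026-01-03 02:00"),  # day 2's night shift
    list("sedation_assessment", "2026-01-03 07:00"),
    list("sedation_assessment", "2026-01-03 15:00")))
  expect_equal(evaluate_plan(list(p), plan, c("2026-01-02", "2026-01-02"),
                             the_catalog)$fraction, 1)
  # the 02:00 event does not count for any shift of day 3
  expect_equal(evaluate_plan(list(p), plan, c("2026-01-03", "2026-01-03"),
                             the_catalog)$fraction, 0)
})

test_that("goal days require a measurement and all values in range", {
  plan <- get_indicator(the_catalog, "2b")$plans[[1]] # RASS -1..+1
  good <- mk_icu_patient(discharge = "2026-01-02 00:00", specs = list(
    list("rass", "2026-01-01 08:00", value = 0),
    list("rass", "2026-01-01 14:00", value = 1)))
  bad <- mk_icu_patient(discharge = "2026-01-02 00:00", specs = list(
    list("rass", "2026-01-01 08:00", value = 0),
    list("rass", "2026-01-01 14:00", value = -3)))
  none <- mk_icu_patient(discharge = "2026-01-02 00:00")
  expect_equal(evaluate_plan(list(good), plan, catalog = the_catalog)$fraction, 1)
  expect_equal(evaluate_plan(list(bad), plan, catalog = the_catalog)$fraction, 0)
  expect_equal(evaluate_plan(list(none), plan, catalog = the_catalog)$fraction, 0)
})

test_that("blood-culture rates hit the published threshold exactly", {
  mk_cohort <- function(n_events) {
    lapply(1:10, function(i) {
      specs <- if (i == 1)
        lapply(seq_len(n_events), function(k)
          list("blood_culture", sprintf("2026-01-%02d 13:00", k)))
      else list()
      mk_icu_patient(id = paste0("P", i), specs = specs)
    })
  }
  plan <- get_indicator(the_catalog, "6b")$plans[[1]]
  r8 <- evaluate_plan(mk_cohort(8), plan, catalog = the_catalog)
  expect_equal(r8$denominator, 100)
  expect_equal(r8$rate, 80)
  expect_true(r8$pass)
  r7 <- evaluate_plan(mk_cohort(7), plan, catalog = the_catalog)
  expect_equal(r7$rate, 70)
  expect_false(r7$pass)
})

test_that("weekly and admission-window timings follow the stay clock", {
  plan8b <- get_indicator(the_catalog, "8b")$plans[[1]]
  base <- list(list("icu_stay", "2026-01-01 00:00", value = 240, unit = "h",
                    end = "2026-01-11 00:00"))
  one_block <- mk_icu_patient(specs = c(base, list(
    list("family_interview", "2026-01-02 10:00"))))
  both_blocks <- mk_icu_patient(specs = c(base, list(
    list("family_interview", "2026-01-02 10:00"),
    list("family_interview", "2026-01-09 10:00"))))
  expect_equal(evaluate_plan(list(one_block), plan8b,
                             catalog = the_catalog)$fraction, 0)
  expect_equal(evaluate_plan(list(both_blocks), plan8b,
                             catalog = the_catalog)$fraction, 1)

  plan9a <- get_indicator(the_catalog, "9a")$plans[[1]]
  at_limit <- mk_icu_patient(specs = list(
    list("mobilization", "2026-01-02 00:00")))   # exactly 24 h
  too_late <- mk_icu_patient(specs = list(
    list("mobilization", "2026-01-02 01:00")))   # 25 h
  expect_equal(evaluate_plan(list(at_limit), plan9a,
                             catalog = the_catalog)$fraction, 1)
  expect_equal(evaluate_plan(list(too_late), plan9a,
                             catalog = the_catalog)$fraction, 0)
})

test_that("negated stay actions forbid any matching event", {
  plan4b <- get_indicator(the_catalog, "4b")$plans[[1]]
  vent <- list(list("invasive_ventilation", "2026-01-01 00:00",
                    end = "2026-01-11 00:00"))
  clean <- mk_icu_patient(specs = vent)
  transferred <- mk_icu_patient(specs = c(vent, list(
    list("home_ventilation", "2026-01-10 23:00"))))
  expect_equal(evaluate_plan(list(clean), plan4b,
                             catalog = the_catalog)$fraction, 1)
  expect_equal(evaluate_plan(list(transferred), plan4b,
                             catalog = the_catalog)$fraction, 0)
})

test_that("reports are monotone under patient removal and order-invariant", {
  coh <- generate_cohort(sim_config(n_patients = 15, compliance = 0.6,
                                    seed = 5), the_catalog)
  full <- evaluate_catalog(coh, the_catalog)
  fewer <- evaluate_catalog(coh[-3], the_catalog)
  key <- function(r) paste(r$sub_id, r$plan_id, r$level)
  m <- match(key(fewer), key(full))
  expect_false(any(is.na(m)))
  ok <- !is.na(fewer$denominator)
  expect_true(all(fewer$denominator[ok] <= full$denominator[m][ok]))
  expect_true(all(fewer$numerator[ok] <= full$numerator[m][ok]))

  set.seed(9)
  shuffled <- lapply(sample(coh), function(p) {
    p$events <- p$events[sample(nrow(p$events)), ]
    p
  })
  again <- evaluate_catalog(shuffled, the_catalog)
  ord <- match(key(full), key(again))
  expect_equal(again$rate[ord], full$rate)
  expect_equal(again$fraction[ord], full$fraction)
})

test_that("empty cohorts report zero denominators and null fractions", {
  rep0 <- evaluate_catalog(list(), the_catalog)
  exec <- rep0[rep0$level == "plan", ]
  expect_true(all(exec$denominator == 0))
  expect_true(all(is.na(exec$fraction)))
  # structure indicators are skipped with a warning row
  repS <- evaluate_catalog(list(), the_catalog, selection = c("1a", "10a"))
  expect_match(repS$note[repS$sub_id == "10a"], "structure")
})

test_that("event streams round-trip through JSON Lines", {
  coh <- generate_cohort(sim_config(n_patients = 2, compliance = 0.5,
                                    seed = 21), the_catalog)
  tmp <- withr::local_tempfile(fileext = ".jsonl")
  write_events_jsonl(coh, tmp)
  back <- read_events_jsonl(tmp)
  expect_length(back, 2)
  for (i in 1:2) {
    expect_equal(back[[i]]$patient_id, coh[[i]]$patient_id)
    expect_equal(back[[i]]$admission, coh[[i]]$admission)
    a <- coh[[i]]$events[order(coh[[i]]$events$time, coh[[i]]$events$code), ]
    b <- back[[i]]$events[order(back[[i]]$events$time, back[[i]]$events$code), ]
    rownames(a) <- rownames(b) <- NULL
    expect_equal(b, a)
  }
  # evaluation on the re-read cohort is identical
  expect_equal(evaluate_catalog(back, the_catalog)$fraction,
               evaluate_catalog(coh, the_catalog)$fraction)
})
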