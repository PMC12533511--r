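test_that("the bundled catalog has the published structure", {
  expect_length(the_catalog$indicators, 31)
  expect_equal(counts_by_type(the_catalog),
               c(structure = 9L, process = 17L, outcome = 5L))
  expect_equal(sum(counts_by_type(the_catalog)), 31)
  expect_equal(counts_by_type(qi_catalog(list(), list())),
               c(structure = 0L, process = 0L, outcome = 0L))
})

test_that("the (qi_number, sub_id, type) triples match the indicator overview", {
  got <- do.call(rbind, lapply(the_catalog$indicators, function(q)
    data.frame(n = q$qi_number, id = q$sub_id, type = q$type,
               stringsAsFactors = FALSE)))
  rownames(got) <- NULL
  want <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
    n id type
    1 1a process
    1 1b process
    2 2a process
    2 2b outcome
    2 2c structure
    3 3a process
    3 3b process
    3 3c process
    3 3d process
    3 3e structure
    4 4a process
    4 4b outcome
    4 4c structure
    5 5a process
    5 5b process
    5 5c outcome
    5 5d outcome
    5 5e structure
    5 5f structure
    6 6a process
    6 6b outcome
    6 6c structure
    7 7a process
    7 7b process
    7 7c structure
    8 8a process
    8 8b process
    9 9a process
    9 9b process
    9 9c structure
    10 10a structure")
  expect_identical(got[order(got$id), ], want[order(want$id), ],
                   ignore_attr = TRUE)
})

test_that("severe-ARDS ventilation indicator carries the published thresholds", {
  qi <- get_indicator(the_catalog, "3a")
  plan <- qi$plans[[1]]
  keys <- vapply(expr_atoms(plan$population), `[[`, character(1), "concept")
  expect_setequal(keys, c("icu_patient", "ards", "oxygenation_index",
                          "invasive_ventilation"))
  oi <- Filter(function(a) a$concept == "oxygenation_index",
               expr_atoms(plan$population))[[1]]
  expect_equal(oi$comparator$op, "LT")
  expect_equal(oi$comparator$value, 100)
  goal <- plan$intervention$items[[1]]
  expect_s3_class(goal, "qi_goal")
  expect_equal(goal$concept, "tidal_volume_ibw")
  expect_equal(goal$comparator$op, "LE")
  expect_equal(goal$comparator$value, 6)
  expect_equal(goal$comparator$unit, "mL/kg")
})

test_that("sedation/pain/delirium outcome goals match the published ranges", {
  qi <- get_indicator(the_catalog, "2b")
  expect_length(qi$plans, 3)
  sed <- qi$plans[[1]]$intervention$items[[1]]
  expect_equal(sed$comparator$op, "RANGE")
  expect_equal(c(sed$comparator$value, sed$comparator$value_high), c(-1, 1))
  pain <- qi$plans[[2]]$intervention
  expect_equal(pain$method, "ANY")
  expect_true(all(vapply(pain$items, function(it)
    it$comparator$op == "LE" && it$comparator$value == 3, logical(1))))
  del <- qi$plans[[3]]$intervention
  expect_equal(del$method, "ALL")
  expect_true(all(vapply(del$items, function(it)
    it$comparator$op == "EQ" && it$comparator$value == 0, logical(1))))
})

test_that("get_indicator retrieves rate indicators and rejects unknown ids", {
  qi <- get_indicator(the_catalog, "6b")
  expect_equal(qi$type, "outcome")
  rate <- qi$plans[[1]]$intervention$items[[1]]
  expect_s3_class(rate, "qi_rate")
  expect_equal(rate$threshold$op, "GE")
  expect_equal(rate$threshold$value, 80)
  expect_equal(rate$per, 1000)

  s10 <- get_indicator(the_catalog, "10a")
  expect_equal(s10$type, "structure")
  expect_length(s10$plans, 0)

  err <- tryCatch(get_indicator(the_catalog, "99z"), error = identity)
  expect_s3_class(err, "icuqi_not_found")
  expect_match(conditionMessage(err), "3a")
})

test_that("every plan references only registry concepts", {
  reg_keys <- names(the_catalog$concepts)
  for (qi in the_catalog$indicators) {
    for (plan in qi$plans) {
      pkeys <- vapply(expr_atoms(plan$population), `[[`, character(1),
                      "concept")
      ikeys <- vapply(plan$intervention$items, `[[`, character(1), "concept")
      expect_true(all(c(pkeys, ikeys) %in% reg_keys))
    }
  }
})

test_that("the shipped catalog fixture equals the in-code transcription", {
  shipped <- catalog_read_json(system.file("extdata", "divi_catalog.json",
                                           package = "icuqi"))
  expect_identical(icuqi:::catalog_to_list(shipped),
                   icuqi:::catalog_to_list(the_catalog))
})
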