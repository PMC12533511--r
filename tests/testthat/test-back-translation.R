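statements <- backtranslate(the_catalog, the_catalog)

test_that("rendered statements parse back to the identical model", {
  expect_equal(nrow(statements), 26) # 20 single-plan + 3 each for 2a and 2b
  for (qi in Filter(function(q) q$type != "structure",
                    the_catalog$indicators)) {
    st <- backtranslate(qi, the_catalog)
    for (i in seq_len(nrow(st))) {
      plan <- qi$plans[[i]]
      parsed <- parse_statement(st$population_text[i],
                                st$intervention_text[i], the_catalog)
      expect_identical(icuqi:::expr_to_list(parsed$population),
                       icuqi:::expr_to_list(plan$population),
                       label = paste(st$plan_id[i], "population"))
      expect_identical(
        lapply(parsed$intervention$items, icuqi:::item_to_list),
        lapply(plan$intervention$items, icuqi:::item_to_list),
        label = paste(st$plan_id[i], "items"))
      expect_identical(parsed$intervention$method, plan$intervention$method,
                       label = paste(st$plan_id[i], "method"))
    }
  }
})

test_that("specific renderings match the published operationalizations", {
  st4a <- statements[statements$plan_id == "4a-weaning", ]
  expect_equal(st4a$population_text,
               "intensive care patient AND invasive ventilation AND NOT home ventilation")
  expect_equal(st4a$intervention_text,
               "1×/day: (weaning ability evaluated OR weaning attempt documented)")
  expect_equal(statements$intervention_text[statements$plan_id == "3b-pplat"],
               "plateau pressure ≤ 30 cm H2O (continuous)")
  # single-atom population renders without parentheses
  expect_equal(statements$population_text[statements$plan_id == "1b-goals"],
               "intensive care patient")
  expect_false(grepl("[()]",
                     statements$population_text[statements$plan_id ==
                                                "1b-goals"]))
})

test_that("output uses display names only, never code literals", {
  reg <- qi_registry(the_catalog)
  txt <- paste(statements$population_text, statements$intervention_text)
  # DIVI-QI-S mnemonics like CAM-ICU double as display names; the check is
  # about numeric SNOMED/LOINC code literals leaking into the rendering
  long_codes <- reg$code[nchar(reg$code) >= 5 & grepl("^[0-9]", reg$code)]
  for (code in long_codes)
    expect_false(any(grepl(code, txt, fixed = TRUE)), label = code)
})

test_that("the grammar rejects ambiguity and unknown names", {
  expect_error(
    parse_statement(
      "intensive care patient AND invasive ventilation OR severe ARDS",
      "1×/day: mobilization", the_catalog),
    "mixed AND/OR")
  err <- tryCatch(
    parse_statement("intensive care patient AND flux capacitor",
                    "1×/day: mobilization", the_catalog),
    error = identity)
  expect_s3_class(err, "icuqi_parse_error")
  expect_match(conditionMessage(err), "flux capacitor")
  expect_match(conditionMessage(err), "token")
  expect_error(
    parse_statement("intensive care patient",
                    "mobilization (continuous)", the_catalog),
    "comparator")
})

test_that("paired one-sided bounds normalize into a range", {
  p <- parse_statement(
    "intensive care patient",
    "RASS ≥ -1 (continuous) AND RASS ≤ 1 (continuous)",
    the_catalog)
  expect_length(p$intervention$items, 1)
  goal <- p$intervention$items[[1]]
  expect_equal(goal$comparator$op, "RANGE")
  expect_equal(c(goal$comparator$value, goal$comparator$value_high), c(-1, 1))
  # identical to the catalog's sedation-outcome goal
  want <- get_indicator(the_catalog, "2b")$plans[[1]]$intervention$items[[1]]
  expect_identical(icuqi:::item_to_list(goal), icuqi:::item_to_list(want))
})

test_that("qitxt files round-trip", {
  tmp <- withr::local_tempfile(fileext = ".qitxt")
  write_qitxt(statements, tmp)
  expect_identical(read_qitxt(tmp), statements)
})

test_that("back-translation works from an encoded bundle and rejects structure", {
  st <- backtranslate(encode_indicator("3b", the_catalog), the_catalog)
  expect_equal(st$intervention_text,
               statements$intervention_text[statements$plan_id == "3b-pplat"])
  expect_error(backtranslate("10a", the_catalog),
               class = "icuqi_unsupported_type")
})
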