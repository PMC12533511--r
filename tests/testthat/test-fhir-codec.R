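exec_ids <- names(Filter(function(q) q$type != "structure",
                         the_catalog$indicators))

qi_as_list <- function(qi) {
  icuqi:::catalog_to_list(qi_catalog(list(qi), the_catalog$concepts))$indicators
}

test_that("decode(encode(x)) is the identity on all executable indicators", {
  expect_length(exec_ids, 22)
  for (id in exec_ids) {
    qi <- get_indicator(the_catalog, id)
    back <- decode_bundle(encode_indicator(qi, the_catalog), the_catalog)
    expect_identical(qi_as_list(back), qi_as_list(qi), label = id)
  }
})

test_that("validate_bundle is clean on all encoder output", {
  for (id in exec_ids) {
    expect_length(validate_bundle(encode_indicator(id, the_catalog)), 0)
  }
})

test_that("per-shift assessments expand to three instances per action", {
  b <- encode_indicator("2a", the_catalog)
  types <- vapply(b, `[[`, character(1), "resourceType")
  expect_equal(sum(types == "ActivityDefinition"), 9)
  plans <- Filter(function(r)
    icuqi:::has_profile(r, icuqi:::fhir_profiles$plan), b)
  expect_length(plans, 3)
  whens <- unlist(lapply(b[types == "ActivityDefinition"], function(r)
    r$timingTiming$repeat_$when))
  expect_equal(sort(whens), sort(rep(c("MORN", "AFT", "NIGHT"), 3)))
})

test_that("continuous interventions become goals, not activities", {
  b <- encode_indicator("3a", the_catalog)
  types <- vapply(b, `[[`, character(1), "resourceType")
  expect_equal(sum(types == "ActivityDefinition"), 0)
  plan <- Filter(function(r)
    icuqi:::has_profile(r, icuqi:::fhir_profiles$plan), b)[[1]]
  expect_length(plan$goal, 1)
  expect_equal(plan$goal[[1]]$target[[1]]$detailQuantity$value, 6)
})

test_that("activity counts are a pure function of the model", {
  for (id in exec_ids) {
    qi <- get_indicator(the_catalog, id)
    want <- sum(vapply(qi$plans, function(p)
      sum(vapply(p$intervention$items, function(it)
        if (it$item == "ACTION" && it$timing$kind == "PER_SHIFT") 3L
        else if (it$item == "ACTION") 1L else 0L, integer(1))), integer(1)))
    b <- encode_indicator(qi, the_catalog)
    types <- vapply(b, `[[`, character(1), "resourceType")
    expect_equal(sum(types == "ActivityDefinition"), want, label = id)
  }
})

test_that("structure indicators are rejected and broken bundles are caught", {
  expect_error(encode_indicator("10a", the_catalog),
               class = "icuqi_unsupported_type")

  b <- encode_indicator("2a", the_catalog)
  types <- vapply(b, `[[`, character(1), "resourceType")
  drop <- which(types == "ActivityDefinition")[1]
  ref <- paste0("ActivityDefinition/", b[[drop]]$id)
  broken <- structure(b[-drop], class = "qi_bundle")
  v <- validate_bundle(broken)
  expect_true(any(grepl(ref, v, fixed = TRUE)))
  expect_error(decode_bundle(broken, the_catalog),
               class = "icuqi_integrity_error")

  expect_true(length(validate_bundle(structure(list(), class = "qi_bundle")))
              >= 1)
})

test_that("encoding is deterministic and canonical on disk", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_bundle(encode_indicator("2a", the_catalog), d1)
  write_bundle(encode_indicator("2a", the_catalog), d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  for (i in seq_along(f1))
    expect_identical(readLines(f1[i]), readLines(f2[i]))
  # array-file form round-trips through read_bundle
  arr <- withr::local_tempfile(fileext = ".json")
  write_bundle(encode_indicator("4a", the_catalog), arr)
  back <- decode_bundle(read_bundle(arr), the_catalog)
  expect_identical(qi_as_list(back),
                   qi_as_list(get_indicator(the_catalog, "4a")))
})

test_that("a hand-built disjunctive population decodes to an ANY combination", {
  sys_url <- function(key) {
    cd <- the_catalog$concepts[[key]]$codings
    lapply(cd, function(x) list(system = icuqi:::qi_system_urls[[x$system]],
                                code = x$code, display = x$display))
  }
  ev <- list(resourceType = "EvidenceVariable", id = "x-eligibility",
             meta = list(profile = list(icuqi:::fhir_profiles$eligibility)),
             status = "active",
             characteristic = list(list(
               exclude = FALSE,
               definitionByCombination = list(
                 code = "any-of",
                 characteristic = list(
                   list(exclude = FALSE, definitionCodeableConcept =
                          list(coding = sys_url("invasive_ventilation"))),
                   list(exclude = FALSE, definitionCodeableConcept =
                          list(coding = sys_url("invasive_device"))))))))
  pop <- icuqi:::decode_characteristic(ev$characteristic[[1]], the_catalog)
  expect_equal(pop$kind, "COMBO")
  expect_equal(pop$method, "ANY")
  expect_length(pop$children, 2)
  expect_equal(pop$children[[1]]$concept, "invasive_ventilation")
})
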