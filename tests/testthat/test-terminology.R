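registry <- qi_registry(the_catalog)

test_that("lookup resolves codes and rejects unknown ones", {
  expect_equal(lookup_code(registry, "SNOMED", "30088009")$display,
               "Blood culture")
  expect_equal(lookup_code(registry, "DIVI_QI_S", "BPS")$display,
               "Behavioral Pain Scale")
  expect_error(lookup_code(registry, "SNOMED", "000"),
               class = "icuqi_not_found")
  err <- tryCatch(lookup_code(registry, "SNOMED", "000"), error = identity)
  expect_match(conditionMessage(err), "SNOMED")
  expect_match(conditionMessage(err), "000")
})

test_that("concept statistics reproduce the published mapping counts", {
  s <- concept_stats(the_catalog)
  expect_equal(s$unique_concepts, 58)
  expect_equal(s$mapped_international, 52)
  expect_equal(s$custom_divi, 6)
  expect_equal(s$pct_mapped, 90)
  expect_equal(s$unique_concepts, s$mapped_international + s$custom_divi)

  empty <- qi_catalog(list(), list())
  s0 <- concept_stats(empty)
  expect_equal(unlist(s0), c(unique_concepts = 0, mapped_international = 0,
                             custom_divi = 0, pct_mapped = 0))
})

test_that("the supplementary code system holds exactly the six custom codes", {
  divi <- registry[registry$system == "DIVI_QI_S", ]
  expect_setequal(divi$code, c("FA-ZB-ITS", "TAGESZIEL", "BPS", "CAM-ICU",
                               "ICDSC", "tvpibw"))
  expect_true(all(nzchar(divi$display)))
})

test_that("statistics are invariant to ordering and cross-indicator reuse", {
  shuffled <- qi_catalog(rev(the_catalog$indicators),
                         sample(the_catalog$concepts))
  expect_identical(concept_stats(shuffled), concept_stats(the_catalog))
  # the shared "Indication of" code appears in two concepts but counts once
  n_raw <- sum(vapply(the_catalog$concepts, function(cp) length(cp$codings),
                      integer(1)))
  expect_equal(n_raw, 59)
  expect_equal(concept_stats(the_catalog)$unique_concepts, 58)
})

test_that("code-system export writes one valid JSON file per system", {
  dir <- withr::local_tempdir()
  paths <- write_code_systems(registry, dir)
  expect_length(paths, 3)
  divi <- jsonlite::fromJSON(file.path(dir, "codesystem-divi-qi-s.json"),
                             simplifyVector = FALSE)
  expect_equal(divi$resourceType, "CodeSystem")
  expect_length(divi$concept, 6)
  # shipped fixtures match a fresh export
  shipped <- system.file("extdata", "codesystem-divi-qi-s.json",
                         package = "icuqi")
  expect_equal(readLines(file.path(dir, "codesystem-divi-qi-s.json")),
               readLines(shipped))
})
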