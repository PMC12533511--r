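test_that("validate_catalog accepts the bundled catalog and reports violations", {
  expect_length(validate_catalog(the_catalog), 0)

  dup <- qi_catalog(c(the_catalog$indicators,
                      list(the_catalog$indicators[["3a"]])),
                    the_catalog$concepts)
  v <- validate_catalog(dup)
  expect_true(any(grepl("3a", v)))

  broken <- qi_catalog(
    list(qi_indicator(1, "1x", "no plans", "process")),
    the_catalog$concepts)
  expect_true(any(grepl("1x.*no plans", validate_catalog(broken))))

  # structure indicators must not carry plans
  bad_struct <- the_catalog$indicators[["10a"]]
  bad_struct$plans <- the_catalog$indicators[["1a"]]$plans
  v <- validate_catalog(qi_catalog(list(bad_struct), the_catalog$concepts))
  expect_true(any(grepl("structure indicator", v)))
})

test_that("type constructors enforce their invariants", {
  expect_error(qi_comparator("RANGE", 3, 1), "value <= value_high")
  expect_error(qi_comparator("LE", 3, value_high = 5), "RANGE")
  expect_error(qi_combo("AT_LEAST", list(qi_atom("a")), n = 2), "exceeds")
  expect_error(qi_combo("ALL", list()), "at least one child")
  expect_error(qi_timing("PER_DAY", hours = 4), "only allowed")
  expect_error(qi_timing("WITHIN_HOURS_OF_ADMISSION"), "requires positive")
  expect_error(qi_concept("x", "x", list()), "at least one coding")
  expect_error(qi_goal("rass", NULL), "requires a comparator")
  expect_error(qi_rate("blood_culture", qi_comparator("EQ", 1)),
               "GE, GT, LE, RANGE")
})

test_that("expr_eval implements the counting semantics", {
  t <- c(a = TRUE, b = FALSE, c = TRUE)
  expect_false(expr_eval(qi_all(qi_atom("a"), qi_atom("b")), t))
  expect_true(expr_eval(qi_any(qi_atom("a"), qi_atom("b")), t))
  expect_true(expr_eval(qi_at_least(2, qi_atom("a"), qi_atom("b"),
                                    qi_atom("c")), t))
  expect_false(expr_eval(qi_exactly(2, qi_atom("a"), qi_atom("a"),
                                    qi_atom("c")), c(a = TRUE, c = TRUE)))
  expect_error(expr_eval(qi_atom("missing"), t), "missing")
})

test_that("expr_eval agrees with the brute-force truth-table oracle", {
  set.seed(401)
  for (rep in 1:80) {
    e <- rand_expr(depth = 3, n_atoms = 4)
    grid <- all_assignments(e)
    for (i in seq_len(nrow(grid))) {
      truth <- unlist(grid[i, , drop = FALSE])
      expect_identical(expr_eval(e, truth), oracle_eval(e, truth))
    }
  }
})

test_that("logical equivalences hold on random assignments", {
  set.seed(402)
  for (rep in 1:40) {
    e <- rand_expr(depth = 2, n_atoms = 3)
    keys <- unique(vapply(expr_atoms(e), atom_key, character(1)))
    truth <- stats::setNames(stats::runif(length(keys)) < 0.5, keys)
    expect_identical(expr_eval(qi_not(qi_not(e)), truth), expr_eval(e, truth))
    expect_identical(expr_eval(qi_combo("ALL", list(e)), truth),
                     expr_eval(e, truth))
    ch <- lapply(1:3, function(i) rand_expr(1, 3))
    keys2 <- unique(unlist(lapply(ch, function(x)
      vapply(expr_atoms(x), atom_key, character(1)))))
    truth2 <- stats::setNames(stats::runif(length(keys2)) < 0.5, keys2)
    any_ <- expr_eval(qi_combo("ANY", ch), truth2)
    expect_identical(expr_eval(qi_combo("AT_LEAST", ch, n = 1), truth2), any_)
    expect_identical(expr_eval(qi_combo("ONE_OR_MORE", ch), truth2), any_)
  }
})

test_that("catalog JSON serialization round-trips losslessly", {
  tmp <- withr::local_tempfile(fileext = ".json")
  catalog_write_json(the_catalog, tmp)
  back <- catalog_read_json(tmp)
  expect_identical(icuqi:::catalog_to_list(back),
                   icuqi:::catalog_to_list(the_catalog))
  # validation is total on well-formed input
  expect_type(validate_catalog(back), "character")
})
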