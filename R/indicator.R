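QI_EVAL_UNITS <- c("PATIENT_DAY", "STAY", "COHORT_PERIOD")
QI_TYPES <- c("process", "outcome", "structure")

#' Create a recommendation plan (one population-intervention pair)
#'
#' @param id plan identifier, unique within its indicator.
#' @param population a `qi_expr` eligibility criterion.
#' @param intervention a [qi_intervention()].
#' @param evaluation_unit `PATIENT_DAY`, `STAY` or `COHORT_PERIOD` (rates).
#' @return a `qi_plan` object.
#' @export
qi_plan <- function(id, population, intervention,
                    evaluation_unit = "PATIENT_DAY") {
  evaluation_unit <- match.arg(evaluation_unit, QI_EVAL_UNITS)
  stopifnot(is_string(id), inherits(population, "qi_expr"),
            inherits(intervention, "qi_intervention"))
  structure(list(id = id, population = population,
                 intervention = intervention,
                 evaluation_unit = evaluation_unit), class = "qi_plan")
}

#' Create a quality indicator (one subindicator)
#'
#' @param qi_number main indicator number (1-10).
#' @param sub_id subindicator id, e.g. `"3a"`.
#' @param title short title.
#' @param type `process`, `outcome` or `structure`; structure indicators
#'   carry only a narrative, no executable plans.
#' @param plans list of [qi_plan()] (empty iff structure).
#' @param narrative the human-readable intermediate-representation text.
#' @param notes optional transcription notes (ambiguities in the source).
#' @return a `qi_indicator` object.
#' @export
qi_indicator <- function(qi_number, sub_id, title, type, plans = list(),
                         narrative = "", notes = NULL) {
  type <- match.arg(type, QI_TYPES)
  stopifnot(is_count(qi_number), qi_number <= 10, is_string(sub_id))
  structure(list(qi_number = as.integer(qi_number), sub_id = sub_id,
                 title = title, type = type, plans = plans,
                 narrative = narrative, notes = notes),
            class = "qi_indicator")
}

#' Create an indicator catalog
#'
#' @param indicators list of [qi_indicator()].
#' @param concepts list of [qi_concept()].
#' @return a `qi_catalog`.
#' @export
qi_catalog <- function(indicators, concepts) {
  names(indicators) <- vapply(indicators, `[[`, character(1), "sub_id")
  names(concepts) <- vapply(concepts, `[[`, character(1), "key")
  structure(list(indicators = indicators, concepts = concepts),
            class = "qi_catalog")
}

#' Validate a catalog
#'
#' Checks all structural invariants of the indicator model: unique ids,
#' structure indicators without plans and process/outcome indicators with
#' plans, resolvable concept references, comparators only on value-bearing
#' concepts, rate plans on cohort-period denominators, admission-window plans
#' on stay denominators. Violations are returned as data, never raised.
#'
#' @param catalog a `qi_catalog`.
#' @return character vector of violation descriptions; empty if valid.
#' @export
validate_catalog <- function(catalog) {
  v <- character(0)
  ids <- vapply(catalog$indicators, `[[`, character(1), "sub_id")
  if (anyDuplicated(ids))
    v <- c(v, paste0("duplicate sub_id: ",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  keys <- vapply(catalog$concepts, `[[`, character(1), "key")
  if (anyDuplicated(keys))
    v <- c(v, paste0("duplicate concept key: ",
                     paste(unique(keys[duplicated(keys)]), collapse = ", ")))
  for (qi in catalog$indicators) {
    pre <- paste0("indicator ", qi$sub_id, ": ")
    if (qi$type == "structure" && length(qi$plans))
      v <- c(v, paste0(pre, "structure indicator must not carry plans"))
    if (qi$type != "structure" && !length(qi$plans))
      v <- c(v, paste0(pre, qi$type, " indicator has no plans"))
    for (plan in qi$plans) {
      ppre <- paste0(pre, "plan ", plan$id, ": ")
      for (atom in expr_atoms(plan$population)) {
        cp <- catalog$concepts[[atom$concept]]
        if (is.null(cp)) {
          v <- c(v, paste0(ppre, "unknown concept '", atom$concept, "'"))
        } else if (!is.null(atom$comparator) && !cp$value_bearing) {
          v <- c(v, paste0(ppre, "comparator on non-value-bearing concept '",
                           atom$concept, "'"))
        }
      }
      has_rate <- FALSE
      has_within <- FALSE
      for (item in plan$intervention$items) {
        if (!item$concept %in% keys)
          v <- c(v, paste0(ppre, "unknown concept '", item$concept, "'"))
        if (item$item == "RATE") has_rate <- TRUE
        if (item$item == "ACTION" &&
            item$timing$kind == "WITHIN_HOURS_OF_ADMISSION") has_within <- TRUE
        if (item$item == "GOAL" && !is.null(item$comparator$reference) &&
            !item$comparator$reference %in% keys)
          v <- c(v, paste0(ppre, "unknown reference concept '",
                           item$comparator$reference, "'"))
      }
      if (has_rate && plan$evaluation_unit != "COHORT_PERIOD")
        v <- c(v, paste0(ppre, "rate plans must use COHORT_PERIOD"))
      if (has_within && plan$evaluation_unit != "STAY")
        v <- c(v, paste0(ppre, "admission-window plans must use STAY"))
    }
  }
  v
}

#' Count indicators by type
#'
#' @param catalog a `qi_catalog`.
#' @return named integer vector with entries `structure`, `process`,
#'   `outcome`.
#' @export
counts_by_type <- function(catalog) {
  types <- vapply(catalog$indicators, `[[`, character(1), "type")
  out <- c(structure = 0L, process = 0L, outcome = 0L)
  tb <- table(types)
  out[names(tb)] <- as.integer(tb)
  out
}

#' Retrieve an indicator by subindicator id
#'
#' @param catalog a `qi_catalog`.
#' @param sub_id subindicator id such as `"3a"`.
#' @return the matching `qi_indicator`.
#' @export
get_indicator <- function(catalog, sub_id) {
  qi <- catalog$indicators[[sub_id]]
  if (is.null(qi))
    qi_stop("unknown sub_id '", sub_id, "'; valid ids: ",
            paste(names(catalog$indicators), collapse = ", "),
            class = "icuqi_not_found")
  qi
}

# ---- catalog JSON (de)serialization -----------------------------------------

cmp_to_list <- function(cmp) {
  if (is.null(cmp)) return(NULL)
  out <- list(op = cmp$op, value = cmp$value, unit = cmp$unit)
  if (!is.null(cmp$value_high)) out$value_high <- cmp$value_high
  if (!is.null(cmp$reference)) out$reference <- cmp$reference
  out
}

cmp_from_list <- function(x) {
  if (is.null(x)) return(NULL)
  qi_comparator(x$op, x$value %||% NA_real_, x$value_high, x$unit %||% "",
                x$reference)
}

expr_to_list <- function(e) {
  switch(e$kind,
         ATOM = list(kind = "ATOM", concept = e$concept,
                     comparator = cmp_to_list(e$comparator)),
         NOT = list(kind = "NOT", child = expr_to_list(e$child)),
         COMBO = list(kind = "COMBO", method = e$method, n = e$n,
                      children = lapply(e$children, expr_to_list)))
}

expr_from_list <- function(x) {
  switch(x$kind,
         ATOM = qi_atom(x$concept, cmp_from_list(x$comparator)),
         NOT = qi_not(expr_from_list(x$child)),
         COMBO = qi_combo(x$method, lapply(x$children, expr_from_list),
                          n = x$n),
         qi_stop("unknown expression kind '", x$kind, "'"))
}

item_to_list <- function(it) {
  switch(it$item,
         ACTION = {
           t <- it$timing
           list(item = "ACTION", concept = it$concept, negated = it$negated,
                timing = list(kind = t$kind, n = t$n, hours = t$hours))
         },
         GOAL = list(item = "GOAL", concept = it$concept,
                     comparator = cmp_to_list(it$comparator)),
         RATE = list(item = "RATE", concept = it$concept,
                     threshold = cmp_to_list(it$threshold)))
}

item_from_list <- function(x) {
  switch(x$item,
         ACTION = qi_action(x$concept,
                            qi_timing(x$timing$kind, x$timing$n %||% 1L,
                                      hours = x$timing$hours),
                            negated = isTRUE(x$negated)),
         GOAL = qi_goal(x$concept, cmp_from_list(x$comparator)),
         RATE = qi_rate(x$concept, cmp_from_list(x$threshold)),
         qi_stop("unknown intervention item '", x$item, "'"))
}

catalog_to_list <- function(catalog) {
  list(
    concepts = lapply(unname(catalog$concepts), function(cp) {
      list(key = cp$key, display = cp$display,
           value_bearing = cp$value_bearing,
           codings = lapply(cp$codings, function(cd) {
             list(system = cd$system, code = cd$code, display = cd$display,
                  omop_id = cd$omop_id)
           }))
    }),
    indicators = lapply(unname(catalog$indicators), function(qi) {
      list(qi_number = qi$qi_number, sub_id = qi$sub_id, title = qi$title,
           type = qi$type, narrative = qi$narrative, notes = qi$notes,
           plans = lapply(qi$plans, function(p) {
             list(id = p$id, evaluation_unit = p$evaluation_unit,
                  population = expr_to_list(p$population),
                  intervention = list(method = p$intervention$method,
                                      n = p$intervention$n,
                                      items = lapply(p$intervention$items,
                                                     item_to_list)))
           }))
    })
  )
}

catalog_from_list <- function(x) {
  concepts <- lapply(x$concepts, function(cp) {
    qi_concept(cp$key, cp$display,
               codings = lapply(cp$codings, function(cd) {
                 qi_coding(cd$system, cd$code, cd$display, cd$omop_id)
               }),
               value_bearing = isTRUE(cp$value_bearing))
  })
  indicators <- lapply(x$indicators, function(qi) {
    plans <- lapply(qi$plans, function(p) {
      qi_plan(p$id, expr_from_list(p$population),
              qi_intervention(p$intervention$method,
                              lapply(p$intervention$items, item_from_list),
                              n = p$intervention$n),
              p$evaluation_unit)
    })
    qi_indicator(qi$qi_number, qi$sub_id, qi$title, qi$type, plans,
                 qi$narrative %||% "", qi$notes)
  })
  qi_catalog(indicators, concepts)
}

#' Read and write catalogs as JSON
#'
#' The JSON form round-trips losslessly through [catalog_from_json()].
#'
#' @param catalog a `qi_catalog`.
#' @param path file path.
#' @return `catalog_write_json` invisibly returns `path`;
#'   `catalog_read_json` returns a `qi_catalog`.
#' @export
catalog_write_json <- function(catalog, path) {
  writeLines(canonical_json(catalog_to_list(catalog)), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname catalog_write_json
#' @export
catalog_read_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  catalog_from_list(x)
}
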