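# Encoder/decoder between the indicator model and CPG-on-EBMonFHIR-shaped
# FHIR JSON. One indicator becomes one Recommendation PlanDefinition; each
# population-intervention pair becomes a RecommendationPlan PlanDefinition
# with a RecommendationEligibilityCriteria EvidenceVariable for the
# population, RecommendationAction ActivityDefinitions for frequency-based
# actions (per-shift actions expand to three instances: morning, afternoon,
# night) and goal elements for continuously applicable criteria and rates.
# The resources follow the element names of the implementation guide
# (characteristic, exclusion, definitionByCombination, Timing, goal); full
# profile conformance against the official validator is not asserted.

fhir_profile_base <-
  "https://www.netzwerk-universitaetsmedizin.de/fhir/cpg-on-ebm-on-fhir/StructureDefinition/"

fhir_profiles <- list(
  recommendation = paste0(fhir_profile_base, "recommendation|1.2.0"),
  plan = paste0(fhir_profile_base, "recommendation-plan|1.2.0"),
  eligibility = paste0(fhir_profile_base, "recommendation-eligibility-criteria|1.2.0"),
  action = paste0(fhir_profile_base, "recommendation-action|1.2.0")
)

fhir_ext <- function(what) paste0(fhir_profile_base, "ext-", what)

combo_fhir_codes <- c(ALL = "all-of", ANY = "any-of", AT_LEAST = "at-least",
                      EXACTLY = "exactly", ONE_OR_MORE = "one-or-more")

fhir_coding <- function(cd) {
  list(system = unname(qi_system_urls[[cd$system]]), code = cd$code,
       display = cd$display)
}

concept_codeable <- function(catalog, key) {
  cp <- catalog$concepts[[key]]
  if (is.null(cp)) qi_stop("unknown concept '", key, "'",
                           class = "icuqi_encode_error")
  list(coding = lapply(cp$codings, fhir_coding), text = cp$display)
}

cmp_fhir <- function(cmp) {
  out <- list(op = cmp$op, unit = cmp$unit)
  if (!is.null(cmp$reference)) out$referenceConcept <- cmp$reference
  else out$value <- cmp$value
  if (!is.null(cmp$value_high)) out$valueHigh <- cmp$value_high
  out
}

cmp_from_fhir <- function(x) {
  qi_comparator(x$op, x$value %||% NA_real_, x$valueHigh, x$unit %||% "",
                x$referenceConcept)
}

# ---- population (EvidenceVariable characteristics) --------------------------

encode_characteristic <- function(expr, catalog, exclude = FALSE) {
  switch(expr$kind,
    ATOM = {
      ch <- list(exclude = exclude,
                 definitionCodeableConcept = concept_codeable(catalog, expr$concept))
      if (!is.null(expr$comparator)) ch$valueFilter <- cmp_fhir(expr$comparator)
      ch
    },
    NOT = encode_characteristic(expr$child, catalog, exclude = !exclude),
    COMBO = {
      comb <- list(code = unname(combo_fhir_codes[[expr$method]]))
      if (!is.null(expr$n)) comb$threshold <- expr$n
      comb$characteristic <- lapply(expr$children, encode_characteristic,
                                    catalog = catalog)
      list(exclude = exclude, definitionByCombination = comb)
    })
}

decode_characteristic <- function(ch, catalog) {
  expr <- if (!is.null(ch$definitionByCombination)) {
    comb <- ch$definitionByCombination
    method <- names(combo_fhir_codes)[match(comb$code, combo_fhir_codes)]
    if (is.na(method))
      qi_stop("unknown combination method '", comb$code, "'",
              class = "icuqi_decode_error")
    qi_combo(method, lapply(comb$characteristic, decode_characteristic,
                            catalog = catalog),
             n = comb$threshold)
  } else if (!is.null(ch$definitionCodeableConcept)) {
    key <- concept_key_from_codings(ch$definitionCodeableConcept$coding, catalog)
    cmp <- if (!is.null(ch$valueFilter)) cmp_from_fhir(ch$valueFilter)
    qi_atom(key, cmp)
  } else {
    qi_stop("characteristic has neither combination nor concept definition",
            class = "icuqi_decode_error")
  }
  if (isTRUE(ch$exclude)) qi_not(expr) else expr
}

concept_key_from_codings <- function(codings, catalog) {
  sig <- function(cds) paste(sort(vapply(cds, function(cd)
    paste0(cd$system, "|", cd$code), character(1))), collapse = ";")
  want <- sig(codings)
  for (cp in catalog$concepts) {
    have <- sig(lapply(cp$codings, fhir_coding))
    if (identical(have, want)) return(cp$key)
  }
  qi_stop("no catalog concept matches codings: ", want,
          class = "icuqi_decode_error")
}

# ---- intervention items -----------------------------------------------------

encode_timing <- function(timing, shift = NULL) {
  rep_ <- switch(timing$kind,
    PER_DAY = list(frequency = timing$n, period = 1, periodUnit = "d"),
    PER_WEEK = list(frequency = timing$n, period = 1, periodUnit = "wk"),
    PER_SHIFT = {
      sh <- timing$shifts[timing$shifts$label == shift, ]
      list(frequency = timing$n, period = 1, periodUnit = "d",
           when = list(unname(c(morning = "MORN", afternoon = "AFT",
                                night = "NIGHT")[shift])),
           timeOfDay = list(sprintf("%02d:00:00", sh$start_hour %% 24)))
    },
    WITHIN_HOURS_OF_ADMISSION = list(
      count = timing$n,
      boundsDuration = list(value = timing$hours, unit = "h",
                            system = "http://unitsofmeasure.org", code = "h")),
    ONCE_PER_STAY = list(count = timing$n))
  list(repeat_ = rep_)
}

decode_timing <- function(tm) {
  r <- tm$repeat_
  if (!is.null(r$when)) {
    shift <- c(MORN = "morning", AFT = "afternoon",
               NIGHT = "night")[[r$when[[1]]]]
    list(timing = qi_timing("PER_SHIFT", r$frequency %||% 1L), shift = shift)
  } else if (!is.null(r$boundsDuration)) {
    list(timing = qi_timing("WITHIN_HOURS_OF_ADMISSION", r$count %||% 1L,
                            hours = r$boundsDuration$value), shift = NULL)
  } else if (identical(r$periodUnit, "d")) {
    list(timing = qi_timing("PER_DAY", r$frequency %||% 1L), shift = NULL)
  } else if (identical(r$periodUnit, "wk")) {
    list(timing = qi_timing("PER_WEEK", r$frequency %||% 1L), shift = NULL)
  } else if (!is.null(r$count)) {
    list(timing = qi_timing("ONCE_PER_STAY", r$count), shift = NULL)
  } else {
    qi_stop("unrecognized timing", class = "icuqi_decode_error")
  }
}

encode_goal <- function(item, goal_id, catalog) {
  target <- list(measure = concept_codeable(catalog, item$concept))
  ext <- list()
  if (item$item == "GOAL") {
    cmp <- item$comparator
    if (cmp$op == "RANGE") {
      target$detailRange <- list(low = list(value = cmp$value, unit = cmp$unit),
                                 high = list(value = cmp$value_high,
                                             unit = cmp$unit))
    } else if (!is.null(cmp$reference)) {
      target$detailCodeableConcept <- concept_codeable(catalog, cmp$reference)
      ext <- c(ext, list(list(url = fhir_ext("goal-comparator"),
                              valueCode = cmp$op)))
      if (nzchar(cmp$unit))
        ext <- c(ext, list(list(url = fhir_ext("goal-unit"),
                                valueString = cmp$unit)))
    } else {
      target$detailQuantity <- list(value = cmp$value, unit = cmp$unit)
      ext <- c(ext, list(list(url = fhir_ext("goal-comparator"),
                              valueCode = cmp$op)))
    }
  } else { # RATE: goal with a fixed per-1000-patient-day denominator
    ext <- c(ext, list(list(url = fhir_ext("rate-denominator"),
                            valueQuantity = list(value = item$per,
                                                 unit = "patient-days"))))
    if (!is.null(item$threshold)) {
      if (item$threshold$op == "RANGE") {
        target$detailRange <- list(
          low = list(value = item$threshold$value, unit = item$threshold$unit),
          high = list(value = item$threshold$value_high,
                      unit = item$threshold$unit))
      } else {
        target$detailQuantity <- list(value = item$threshold$value,
                                      unit = item$threshold$unit)
        ext <- c(ext, list(list(url = fhir_ext("goal-comparator"),
                                valueCode = item$threshold$op)))
      }
    }
  }
  g <- list(id = goal_id,
            description = list(text = catalog$concepts[[item$concept]]$display),
            target = list(target))
  if (length(ext)) g$extension <- ext
  g
}

find_ext <- function(x, url) {
  for (e in x$extension %||% list()) if (identical(e$url, url)) return(e)
  NULL
}

decode_goal <- function(g, catalog) {
  target <- g$target[[1]]
  key <- concept_key_from_codings(target$measure$coding, catalog)
  rate_ext <- find_ext(g, fhir_ext("rate-denominator"))
  op_ext <- find_ext(g, fhir_ext("goal-comparator"))
  if (!is.null(rate_ext)) {
    thr <- NULL
    if (!is.null(target$detailRange)) {
      thr <- qi_comparator("RANGE", target$detailRange$low$value,
                           target$detailRange$high$value,
                           target$detailRange$low$unit %||% "")
    } else if (!is.null(target$detailQuantity)) {
      thr <- qi_comparator(op_ext$valueCode, target$detailQuantity$value,
                           unit = target$detailQuantity$unit %||% "")
    }
    return(qi_rate(key, thr))
  }
  cmp <- if (!is.null(target$detailRange)) {
    qi_comparator("RANGE", target$detailRange$low$value,
                  target$detailRange$high$value,
                  target$detailRange$low$unit %||% "")
  } else if (!is.null(target$detailCodeableConcept)) {
    unit_ext <- find_ext(g, fhir_ext("goal-unit"))
    qi_comparator(op_ext$valueCode, unit = unit_ext$valueString %||% "",
                  reference = concept_key_from_codings(
                    target$detailCodeableConcept$coding, catalog))
  } else {
    qi_comparator(op_ext$valueCode, target$detailQuantity$value,
                  unit = target$detailQuantity$unit %||% "")
  }
  qi_goal(key, cmp)
}

# ---- resources --------------------------------------------------------------

encode_action_resource <- function(item, id, catalog, shift = NULL) {
  res <- list(resourceType = "ActivityDefinition", id = id,
              meta = list(profile = list(fhir_profiles$action)),
              status = "active",
              code = concept_codeable(catalog, item$concept),
              timingTiming = encode_timing(item$timing, shift))
  if (item$negated) res$doNotPerform <- TRUE
  res
}

#' Encode an indicator as a FHIR resource bundle
#'
#' @param qi a process or outcome `qi_indicator` (structure indicators are
#'   not encoded and raise an error).
#' @param catalog the catalog providing concept definitions (default: the
#'   bundled catalog).
#' @return a `qi_bundle`: a list of FHIR resource objects.
#' @export
encode_indicator <- function(qi, catalog = load_default_catalog()) {
  if (is.character(qi)) qi <- get_indicator(catalog, qi)
  if (qi$type == "structure")
    qi_stop("structure indicator '", qi$sub_id,
            "' has no computable representation",
            class = "icuqi_unsupported_type")
  resources <- list()
  plan_refs <- list()
  for (plan in qi$plans) {
    ev_id <- paste0(plan$id, "-eligibility")
    ev <- list(resourceType = "EvidenceVariable", id = ev_id,
               meta = list(profile = list(fhir_profiles$eligibility)),
               status = "active",
               characteristic = list(
                 encode_characteristic(plan$population, catalog)))
    actions <- list()
    goals <- list()
    ads <- list()
    k <- 0L
    for (item in plan$intervention$items) {
      k <- k + 1L
      if (item$item == "ACTION") {
        if (item$timing$kind == "PER_SHIFT") {
          for (shift in item$timing$shifts$label) {
            ad_id <- paste0(plan$id, "-action-", k, "-", shift)
            ads <- c(ads, list(encode_action_resource(item, ad_id, catalog,
                                                      shift)))
            actions <- c(actions, list(list(
              definitionCanonical = paste0("ActivityDefinition/", ad_id))))
          }
        } else {
          ad_id <- paste0(plan$id, "-action-", k)
          ads <- c(ads, list(encode_action_resource(item, ad_id, catalog)))
          actions <- c(actions, list(list(
            definitionCanonical = paste0("ActivityDefinition/", ad_id))))
        }
      } else {
        goal_id <- paste0(plan$id, "-goal-", k)
        goals <- c(goals, list(encode_goal(item, goal_id, catalog)))
        actions <- c(actions, list(list(goalId = list(goal_id))))
      }
    }
    pd <- list(resourceType = "PlanDefinition", id = plan$id,
               meta = list(profile = list(fhir_profiles$plan)),
               status = "active",
               extension = list(
                 list(url = fhir_ext("eligibility"),
                      valueReference = list(
                        reference = paste0("EvidenceVariable/", ev_id))),
                 list(url = fhir_ext("evaluation-unit"),
                      valueCode = plan$evaluation_unit),
                 list(url = fhir_ext("combination-method"),
                      valueCode = plan$intervention$method)),
               action = actions)
    if (!is.null(plan$intervention$n))
      pd$extension <- c(pd$extension,
                        list(list(url = fhir_ext("combination-n"),
                                  valueInteger = plan$intervention$n)))
    if (length(goals)) pd$goal <- goals
    resources <- c(resources, list(pd), list(ev), ads)
    plan_refs <- c(plan_refs, list(list(
      definitionCanonical = paste0("PlanDefinition/", plan$id))))
  }
  rec <- list(resourceType = "PlanDefinition", id = qi$sub_id,
              meta = list(profile = list(fhir_profiles$recommendation)),
              status = "active", title = qi$title,
              identifier = list(list(system = "https://www.divi.de/qi",
                                     value = qi$sub_id)),
              description = qi$narrative,
              extension = list(
                list(url = fhir_ext("qi-number"), valueInteger = qi$qi_number),
                list(url = fhir_ext("indicator-type"), valueCode = qi$type)),
              action = plan_refs)
  if (!is.null(qi$notes))
    rec$extension <- c(rec$extension,
                       list(list(url = fhir_ext("transcription-note"),
                                 valueString = qi$notes)))
  structure(c(list(rec), resources), class = "qi_bundle")
}

bundle_index <- function(bundle) {
  ids <- vapply(bundle, function(r) paste0(r$resourceType, "/", r$id),
                character(1))
  stats::setNames(seq_along(bundle), ids)
}

bundle_get <- function(bundle, ref) {
  idx <- bundle_index(bundle)
  if (!ref %in% names(idx))
    qi_stop("dangling reference: ", ref, class = "icuqi_integrity_error")
  bundle[[idx[[ref]]]]
}

has_profile <- function(res, profile) {
  profile %in% unlist(res$meta$profile %||% list())
}

#' Decode a FHIR bundle back into the indicator model
#'
#' Inverse of [encode_indicator()]: unfolds `definitionByCombination` /
#' `exclusion` nesting into Boolean expressions, re-merges the three
#' per-shift ActivityDefinition instances into one per-shift action, and
#' turns goal elements back into goals and rates.
#'
#' @param bundle a `qi_bundle` (or structurally equivalent list of resources).
#' @param catalog catalog used to resolve codings to concepts.
#' @return a `qi_indicator`.
#' @export
decode_bundle <- function(bundle, catalog = load_default_catalog()) {
  recs <- Filter(function(r) has_profile(r, fhir_profiles$recommendation),
                 bundle)
  if (length(recs) != 1L)
    qi_stop("bundle must contain exactly one Recommendation PlanDefinition",
            class = "icuqi_decode_error")
  rec <- recs[[1]]
  plans <- lapply(rec$action, function(a) {
    pd <- bundle_get(bundle, a$definitionCanonical)
    elig_ref <- find_ext(pd, fhir_ext("eligibility"))$valueReference$reference
    ev <- bundle_get(bundle, elig_ref)
    population <- decode_characteristic(ev$characteristic[[1]], catalog)
    method <- find_ext(pd, fhir_ext("combination-method"))$valueCode
    n_ext <- find_ext(pd, fhir_ext("combination-n"))
    goals <- stats::setNames(pd$goal %||% list(),
                             vapply(pd$goal %||% list(), `[[`, character(1), "id"))
    items <- list()
    i <- 1L
    acts <- pd$action %||% list()
    while (i <= length(acts)) {
      act <- acts[[i]]
      if (!is.null(act$goalId)) {
        items <- c(items, list(decode_goal(goals[[act$goalId[[1]]]], catalog)))
        i <- i + 1L
      } else {
        ad <- bundle_get(bundle, act$definitionCanonical)
        dt <- decode_timing(ad$timingTiming)
        if (!is.null(dt$shift)) {
          # a per-shift action was expanded into three consecutive instances;
          # consume the triplet and re-merge
          ad2 <- bundle_get(bundle, acts[[i + 1L]]$definitionCanonical)
          ad3 <- bundle_get(bundle, acts[[i + 2L]]$definitionCanonical)
          labs <- c(dt$shift, decode_timing(ad2$timingTiming)$shift,
                    decode_timing(ad3$timingTiming)$shift)
          if (!setequal(labs, qi_shifts_default()$label))
            qi_stop("incomplete per-shift action triplet",
                    class = "icuqi_decode_error")
          i <- i + 3L
        } else {
          i <- i + 1L
        }
        items <- c(items, list(qi_action(
          concept_key_from_codings(ad$code$coding, catalog),
          dt$timing, negated = isTRUE(ad$doNotPerform))))
      }
    }
    qi_plan(pd$id, population,
            qi_intervention(method, items,
                            n = if (!is.null(n_ext)) n_ext$valueInteger),
            find_ext(pd, fhir_ext("evaluation-unit"))$valueCode)
  })
  note_ext <- find_ext(rec, fhir_ext("transcription-note"))
  qi_indicator(find_ext(rec, fhir_ext("qi-number"))$valueInteger,
               rec$identifier[[1]]$value, rec$title,
               find_ext(rec, fhir_ext("indicator-type"))$valueCode,
               plans, rec$description %||% "",
               if (!is.null(note_ext)) note_ext$valueString)
}

#' Validate a FHIR bundle
#'
#' Structural checks used by this codec: allowed resource types, exactly one
#' Recommendation, resolvable internal references, eligibility criteria
#' present for each plan, goal ids resolvable. Violations are returned as
#' data.
#'
#' @param bundle a `qi_bundle`.
#' @return character vector of violations; empty if clean.
#' @export
validate_bundle <- function(bundle) {
  v <- character(0)
  allowed <- c("PlanDefinition", "EvidenceVariable", "ActivityDefinition")
  for (r in bundle) {
    if (is.null(r$resourceType) || !r$resourceType %in% allowed)
      v <- c(v, paste0("unsupported resourceType: ",
                       r$resourceType %||% "<missing>"))
    if (is.null(r$id)) v <- c(v, "resource without id")
    if (is.null(r$meta$profile)) v <- c(v, paste0("resource ", r$id %||% "?",
                                                  " without meta.profile"))
  }
  idx <- bundle_index(bundle)
  recs <- Filter(function(r) has_profile(r, fhir_profiles$recommendation),
                 bundle)
  if (length(recs) != 1L) {
    v <- c(v, paste0("bundle must contain exactly one Recommendation (found ",
                     length(recs), ")"))
    return(v)
  }
  check_ref <- function(ref, ctx) {
    if (!ref %in% names(idx))
      v <<- c(v, paste0(ctx, ": unresolved reference ", ref))
  }
  for (a in recs[[1]]$action) check_ref(a$definitionCanonical, "Recommendation")
  plans <- Filter(function(r) has_profile(r, fhir_profiles$plan), bundle)
  for (pd in plans) {
    elig <- find_ext(pd, fhir_ext("eligibility"))
    if (is.null(elig)) {
      v <- c(v, paste0("plan ", pd$id, ": missing eligibility criteria"))
    } else {
      check_ref(elig$valueReference$reference, paste0("plan ", pd$id))
    }
    goal_ids <- vapply(pd$goal %||% list(), `[[`, character(1), "id")
    for (a in pd$action %||% list()) {
      if (!is.null(a$goalId)) {
        if (!a$goalId[[1]] %in% goal_ids)
          v <- c(v, paste0("plan ", pd$id, ": unknown goalId ", a$goalId[[1]]))
      } else if (!is.null(a$definitionCanonical)) {
        check_ref(a$definitionCanonical, paste0("plan ", pd$id))
      }
    }
  }
  v
}

#' Read and write FHIR bundles
#'
#' `write_bundle` writes either one canonical-JSON file per resource into a
#' directory (`one_file = FALSE`) or a single JSON array. `read_bundle`
#' accepts a directory of resource files or a single array file.
#'
#' @param bundle a `qi_bundle`.
#' @param path target file or directory.
#' @param one_file write a single JSON array instead of per-resource files.
#' @return written paths / a `qi_bundle`.
#' @export
write_bundle <- function(bundle, path, one_file = grepl("\\.json$", path)) {
  resources <- lapply(unclass(bundle), unrename_repeat)
  if (one_file) {
    writeLines(as.character(jsonlite::toJSON(lapply(resources, sort_keys),
                                             auto_unbox = TRUE, pretty = 2,
                                             digits = NA, null = "null",
                                             na = "null")),
               path, useBytes = TRUE)
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(resources, function(r) {
    p <- file.path(path, paste0(r$resourceType, "-", r$id, ".json"))
    writeLines(canonical_json(r), p, useBytes = TRUE)
    p
  }, character(1))
  invisible(paths)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) {
  resources <- if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.json$", full.names = TRUE))
    lapply(files, jsonlite::fromJSON, simplifyVector = FALSE)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  resources <- lapply(resources, rename_repeat)
  structure(resources, class = "qi_bundle")
}

# `repeat` is a reserved word in R; resources keep the FHIR element name in
# JSON but use `repeat_` in memory.
rename_repeat <- function(x) {
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm)) names(x)[nm == "repeat"] <- "repeat_"
    lapply(x, rename_repeat)
  } else x
}

unrename_repeat <- function(x) {
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm)) names(x)[nm == "repeat_"] <- "repeat"
    lapply(x, unrename_repeat)
  } else x
}
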