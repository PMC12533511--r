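# Fulfillment engine: matches plan populations against patient event streams
# and evaluates interventions per patient-day, per stay, or as cohort-level
# rates per 1000 patient-days.
#
# Conventions (documented in the methods vignette):
# * a patient-day is a calendar day overlapping the stay; admission and
#   discharge days count in full;
# * concept matching is exact code equality; no terminology hierarchy;
# * comparators require an exact unit match; value-less or unit-mismatched
#   events are ignored for comparator atoms and goals;
# * a goal with no measurement that day is not fulfilled;
# * per-shift requirements apply only to shift windows lying fully inside
#   the stay; days with no such window are excluded from the denominator;
# * stay-level populations are established on the admission day.

unit_norm <- function(u) ifelse(is.na(u), "", u)

concept_rows <- function(patient, concept) {
  sig <- vapply(concept$codings, function(cd) paste0(cd$system, "|", cd$code),
                character(1))
  paste0(patient$events$system, "|", patient$events$code) %in% sig
}

# day indices overlapped by each event (point events: their own day)
event_day_index <- function(events, days) {
  if (!nrow(events) || !length(days)) {
    return(data.frame(row = integer(), day = integer()))
  }
  s <- as.integer(qi_day(events$time))
  end <- events$end_time
  end[is.na(end)] <- events$time[is.na(end)]
  e <- as.integer(qi_day(end))
  di <- as.integer(days)
  lo <- pmax(s, min(di))
  hi <- pmin(e, max(di))
  n <- pmax(hi - lo + 1L, 0L)
  if (!sum(n)) return(data.frame(row = integer(), day = integer()))
  rows <- rep.int(seq_along(n), n)
  dayv <- sequence(n, from = lo)
  hit <- match(dayv, di)
  keep <- !is.na(hit)
  data.frame(row = rows[keep], day = hit[keep])
}

# events of `concept` satisfying `cmp` (value present, exact unit match)
filter_comparator <- function(events, cmp) {
  keep <- !is.na(events$value) & unit_norm(events$unit) == (cmp$unit %||% "")
  events <- events[keep, , drop = FALSE]
  if (!nrow(events) || is.null(cmp)) return(events)
  events[comparator_eval(cmp, events$value), , drop = FALSE]
}

atom_days <- function(patient, atom, days, catalog) {
  cp <- catalog$concepts[[atom$concept]]
  if (is.null(cp)) qi_stop("unknown concept '", atom$concept, "'")
  ev <- patient$events[concept_rows(patient, cp), , drop = FALSE]
  if (!is.null(atom$comparator)) {
    if (!is.null(atom$comparator$reference))
      qi_stop("reference comparators are not supported in populations")
    ev <- filter_comparator(ev, atom$comparator)
  }
  idx <- event_day_index(ev, days)
  out <- rep(FALSE, length(days))
  out[unique(idx$day)] <- TRUE
  out
}

#' Does a patient match a criterion atom on a given day?
#'
#' True iff an event whose coding equals any coding of the atom's concept
#' overlaps the day and, when a comparator is present, the event value
#' satisfies it with an exact unit match (events without a value or with a
#' different unit are ignored).
#'
#' @param patient a `qi_patient`.
#' @param atom a `qi_atom`.
#' @param day a `Date`.
#' @param catalog concept definitions.
#' @return logical.
#' @export
atom_matches <- function(patient, atom, day, catalog = load_default_catalog()) {
  atom_days(patient, atom, as.Date(day), catalog)[1]
}

#' Does a patient match a population expression on a given day?
#'
#' Boolean evaluation of the population over per-day atom matches; negated
#' atoms are true when no matching event exists on the day.
#'
#' @param patient a `qi_patient`.
#' @param population a `qi_expr`.
#' @param day a `Date`.
#' @param catalog concept definitions.
#' @return logical.
#' @export
population_matches <- function(patient, population, day,
                               catalog = load_default_catalog()) {
  population_days(patient, population, as.Date(day), catalog)[1]
}

population_days <- function(patient, population, days, catalog) {
  expr_eval(population, function(atom)
    atom_days(patient, atom, days, catalog))
}

# per-day event counts for an action concept
action_day_counts <- function(patient, concept, days) {
  ev <- patient$events[concept_rows(patient, concept), , drop = FALSE]
  idx <- event_day_index(ev, days)
  counts <- integer(length(days))
  if (nrow(idx)) {
    tb <- table(idx$day)
    counts[as.integer(names(tb))] <- as.integer(tb)
  }
  counts
}

# per-day fulfillment of one intervention item; NA marks a day excluded from
# the denominator (only PER_SHIFT days without any fully contained window)
item_days <- function(patient, item, days, catalog) {
  cp <- catalog$concepts[[item$concept]]
  if (item$item == "ACTION") {
    timing <- item$timing
    if (timing$kind == "PER_DAY") {
      return(action_day_counts(patient, cp, days) >= timing$n)
    }
    if (timing$kind == "PER_SHIFT") {
      ev <- patient$events[concept_rows(patient, cp), , drop = FALSE]
      vapply(seq_along(days), function(i) {
        req <- shifts_within_stay(days[i], patient$admission,
                                  patient$discharge, timing$shifts)
        if (!length(req)) return(NA)
        day0 <- as.POSIXct(paste(days[i], "00:00:00"), tz = "UTC")
        all(vapply(req, function(lab) {
          sh <- timing$shifts[timing$shifts$label == lab, ]
          win_s <- day0 + sh$start_hour * 3600
          win_e <- day0 + sh$end_hour * 3600
          sum(ev$time >= win_s & ev$time < win_e) >= timing$n
        }, logical(1)))
      }, logical(1))
    } else {
      qi_stop("timing ", timing$kind, " requires a stay-level plan")
    }
  } else if (item$item == "GOAL") {
    goal_days(patient, item, days, catalog)
  } else {
    qi_stop("rate items require a cohort-period plan")
  }
}

# goal: >=1 value-bearing matching event on the day AND all such values
# satisfy the comparator; reference thresholds use the day's latest value of
# the referenced concept
goal_days <- function(patient, item, days, catalog) {
  cp <- catalog$concepts[[item$concept]]
  cmp <- item$comparator
  ev <- patient$events[concept_rows(patient, cp), , drop = FALSE]
  ev <- ev[!is.na(ev$value) & unit_norm(ev$unit) == (cmp$unit %||% ""), ,
           drop = FALSE]
  idx <- event_day_index(ev, days)
  ref_value <- NULL
  if (!is.null(cmp$reference)) {
    ref_cp <- catalog$concepts[[cmp$reference]]
    rev <- patient$events[concept_rows(patient, ref_cp), , drop = FALSE]
    rev <- rev[!is.na(rev$value), , drop = FALSE]
    ridx <- event_day_index(rev, days)
    ref_value <- rep(NA_real_, length(days))
    if (nrow(ridx)) {
      for (d in unique(ridx$day)) {
        rows <- ridx$row[ridx$day == d]
        ref_value[d] <- rev$value[rows[which.max(as.numeric(rev$time[rows]))]]
      }
    }
  }
  vapply(seq_along(days), function(i) {
    rows <- idx$row[idx$day == i]
    if (!length(rows)) return(FALSE)
    vals <- ev$value[rows]
    if (!is.null(ref_value)) {
      if (is.na(ref_value[i])) return(FALSE)
      return(all(comparator_eval(cmp, vals, threshold = ref_value[i])))
    }
    all(comparator_eval(cmp, vals))
  }, logical(1))
}

# stay-level fulfillment of one item
item_stay <- function(patient, item, catalog) {
  cp <- catalog$concepts[[item$concept]]
  if (item$item == "GOAL")
    return(goal_days(patient, item, qi_day(patient$admission), catalog)[1])
  if (item$item == "RATE")
    qi_stop("rate items require a cohort-period plan")
  timing <- item$timing
  ev <- patient$events[concept_rows(patient, cp), , drop = FALSE]
  if (item$negated) {
    # the intervention must not occur anywhere in the stay
    end <- ev$end_time
    end[is.na(end)] <- ev$time[is.na(end)]
    in_stay <- ev$time <= patient$discharge & end >= patient$admission
    return(sum(in_stay) == 0L)
  }
  switch(timing$kind,
    WITHIN_HOURS_OF_ADMISSION = {
      limit <- patient$admission + timing$hours * 3600
      sum(ev$time >= patient$admission & ev$time <= limit) >= timing$n
    },
    ONCE_PER_STAY = {
      in_stay <- ev$time >= patient$admission & ev$time <= patient$discharge
      sum(in_stay) >= timing$n
    },
    PER_WEEK = {
      # every started 7-day block since admission needs >= n events
      total <- as.numeric(difftime(patient$discharge, patient$admission,
                                   units = "days"))
      n_blocks <- max(1L, ceiling(total / 7))
      all(vapply(seq_len(n_blocks) - 1L, function(k) {
        b0 <- patient$admission + k * 7 * 86400
        b1 <- min(b0 + 7 * 86400, patient$discharge)
        sum(ev$time >= b0 & ev$time < b1) >= timing$n
      }, logical(1)))
    },
    PER_DAY = {
      days <- stay_days(patient)
      all(action_day_counts(patient, cp, days) >= timing$n)
    },
    qi_stop("timing ", timing$kind, " not supported per stay"))
}

combine_items <- function(truths, method, n) {
  counts <- Reduce(`+`, truths)
  switch(method,
         ALL = counts == length(truths),
         ANY = counts >= 1L,
         ONE_OR_MORE = counts >= 1L,
         AT_LEAST = counts >= n,
         EXACTLY = counts == n)
}

restrict_days <- function(days, period) {
  if (is.null(period)) return(days)
  days[days >= as.Date(period[[1]]) & days <= as.Date(period[[2]])]
}

# detail of one plan on one patient
eval_plan_patient <- function(patient, plan, catalog, period = NULL) {
  unit <- plan$evaluation_unit
  if (unit == "STAY") {
    adm_day <- qi_day(patient$admission)
    if (!is.null(period) &&
        (adm_day < as.Date(period[[1]]) || adm_day > as.Date(period[[2]])))
      return(NULL)
    if (!population_days(patient, plan$population, adm_day, catalog)[1])
      return(NULL)
    truths <- lapply(plan$intervention$items, item_stay, patient = patient,
                     catalog = catalog)
    fulfilled <- combine_items(truths, plan$intervention$method,
                               plan$intervention$n)
    return(data.frame(patient_id = patient$patient_id, fulfilled = fulfilled,
                      stringsAsFactors = FALSE))
  }
  days <- restrict_days(stay_days(patient), period)
  if (!length(days)) return(NULL)
  pop <- population_days(patient, plan$population, days, catalog)
  days <- days[pop]
  if (!length(days)) return(NULL)
  if (unit == "COHORT_PERIOD") {
    item <- plan$intervention$items[[1]]
    cp <- catalog$concepts[[item$concept]]
    ev <- patient$events[concept_rows(patient, cp), , drop = FALSE]
    idx <- event_day_index(ev, days)
    weights <- ifelse(is.na(ev$value[idx$row]), 1, ev$value[idx$row])
    return(data.frame(patient_id = patient$patient_id,
                      patient_days = length(days),
                      numerator = sum(weights), stringsAsFactors = FALSE))
  }
  truths <- lapply(plan$intervention$items, item_days, patient = patient,
                   days = days, catalog = catalog)
  excluded <- Reduce(`|`, lapply(truths, is.na))
  fulfilled <- combine_items(lapply(truths, function(x) x & !is.na(x)),
                             plan$intervention$method, plan$intervention$n)
  keep <- !excluded
  if (!any(keep)) return(NULL)
  data.frame(patient_id = patient$patient_id, day = days[keep],
             fulfilled = fulfilled[keep], stringsAsFactors = FALSE)
}

#' Evaluate one plan over a cohort
#'
#' @param patients list of `qi_patient`.
#' @param plan a `qi_plan`.
#' @param period optional evaluation period `c(from, to)` (dates); default is
#'   the full cohort span.
#' @param catalog concept definitions.
#' @param detail also return the per-unit detail table.
#' @return a one-row report data.frame (and optionally the detail).
#' @export
evaluate_plan <- function(patients, plan, period = NULL,
                          catalog = load_default_catalog(), detail = FALSE) {
  parts <- lapply(patients, eval_plan_patient, plan = plan, catalog = catalog,
                  period = period)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  det <- if (length(parts)) do.call(rbind, parts) else NULL
  unit <- plan$evaluation_unit
  if (unit == "COHORT_PERIOD") {
    pd <- if (is.null(det)) 0 else sum(det$patient_days)
    num <- if (is.null(det)) 0 else sum(det$numerator)
    rate <- if (pd > 0) 1000 * num / pd else NA_real_
    thr <- plan$intervention$items[[1]]$threshold
    row <- data.frame(plan_id = plan$id, unit = unit, denominator = pd,
                      numerator = num, fraction = NA_real_, rate = rate,
                      threshold = if (is.null(thr)) NA_character_ else
                        format(thr),
                      pass = if (is.null(thr) || is.na(rate)) NA else
                        comparator_eval(thr, rate),
                      stringsAsFactors = FALSE)
  } else {
    den <- if (is.null(det)) 0L else nrow(det)
    num <- if (is.null(det)) 0L else sum(det$fulfilled)
    row <- data.frame(plan_id = plan$id, unit = unit, denominator = den,
                      numerator = num,
                      fraction = if (den > 0) num / den else NA_real_,
                      rate = NA_real_, threshold = NA_character_, pass = NA,
                      stringsAsFactors = FALSE)
  }
  if (detail) list(row = row, detail = det) else row
}

#' Evaluate indicators over a cohort
#'
#' Produces one report row per plan; indicators with several plans
#' additionally get an indicator-level row on which a day (or stay) counts
#' as fulfilled only if all the indicator's plans are fulfilled on it
#' (denominator: units present in every plan's denominator). Structure
#' indicators in the selection are skipped with a warning row.
#'
#' @param patients list of `qi_patient`.
#' @param catalog a `qi_catalog`.
#' @param period optional `c(from, to)` dates.
#' @param selection sub_ids to evaluate (default: all process/outcome).
#' @return a `qi_report` data.frame with columns `sub_id`, `plan_id`,
#'   `level`, `unit`, `denominator`, `numerator`, `fraction`, `rate`,
#'   `threshold`, `pass`, `note`.
#' @export
evaluate_catalog <- function(patients, catalog = load_default_catalog(),
                             period = NULL, selection = NULL) {
  ids <- selection %||% names(Filter(function(q) q$type != "structure",
                                     catalog$indicators))
  rows <- list()
  for (sub_id in ids) {
    qi <- get_indicator(catalog, sub_id)
    if (qi$type == "structure") {
      rows <- c(rows, list(data.frame(
        sub_id = sub_id, plan_id = NA_character_, level = "indicator",
        unit = NA_character_, denominator = NA_integer_,
        numerator = NA_integer_, fraction = NA_real_, rate = NA_real_,
        threshold = NA_character_, pass = NA,
        note = "structure indicator skipped (not computable)",
        stringsAsFactors = FALSE)))
      next
    }
    evals <- lapply(qi$plans, evaluate_plan, patients = patients,
                    period = period, catalog = catalog, detail = TRUE)
    for (e in evals) {
      r <- e$row
      rows <- c(rows, list(cbind(data.frame(sub_id = sub_id,
                                            stringsAsFactors = FALSE),
                                 r[, c("plan_id", "unit")],
                                 data.frame(level = "plan",
                                            stringsAsFactors = FALSE),
                                 r[, c("denominator", "numerator", "fraction",
                                       "rate", "threshold", "pass")],
                                 data.frame(note = NA_character_,
                                            stringsAsFactors = FALSE))))
    }
    if (length(evals) > 1L &&
        all(vapply(evals, function(e) e$row$unit, character(1)) %in%
            c("PATIENT_DAY", "STAY")) &&
        length(unique(vapply(evals, function(e) e$row$unit,
                             character(1)))) == 1L) {
      unit <- evals[[1]]$row$unit
      key_cols <- if (unit == "PATIENT_DAY") c("patient_id", "day") else
        "patient_id"
      dets <- lapply(evals, `[[`, "detail")
      if (all(!vapply(dets, is.null, logical(1)))) {
        merged <- Reduce(function(a, b) {
          m <- merge(a, b, by = key_cols)
          m$fulfilled <- m$fulfilled.x & m$fulfilled.y
          m[, c(key_cols, "fulfilled")]
        }, dets)
        den <- nrow(merged)
        num <- sum(merged$fulfilled)
      } else {
        den <- 0L
        num <- 0L
      }
      rows <- c(rows, list(data.frame(
        sub_id = sub_id, plan_id = NA_character_, level = "indicator",
        unit = unit, denominator = den, numerator = num,
        fraction = if (den > 0) num / den else NA_real_, rate = NA_real_,
        threshold = NA_character_, pass = NA, note = NA_character_,
        stringsAsFactors = FALSE)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("qi_report", "data.frame")
  out
}

#' Write a fulfillment report
#'
#' @param report a `qi_report`.
#' @param path output path.
#' @param format `"json"` or `"csv"`.
#' @return invisibly, `path`.
#' @export
report_write <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(report, path, row.names = FALSE, na = "")
  } else {
    writeLines(as.character(jsonlite::toJSON(report, dataframe = "rows",
                                             pretty = 2, digits = NA,
                                             na = "null")),
               path, useBytes = TRUE)
  }
  invisible(path)
}
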