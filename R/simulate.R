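# Seeded synthetic ICU cohort generator. The generator plants
# population-defining events (stays, ventilation episodes, severe ARDS with
# oxygenation indices, devices, antibiotic courses, orders) according to
# configurable prevalences, and then, for every selected subindicator and
# every evaluation unit (day / shift / stay), plants the required
# intervention events with the configured compliance probability. Compliance
# is drawn independently per evaluation unit; non-compliant goal values are
# placed one resolution step outside the boundary to exercise comparator
# edges. Subindicators that share concepts coordinate their plantings (see
# the methods vignette); exact compliance recovery is guaranteed when the
# compliance map is uniform across subindicators.

#' Simulation configuration
#'
#' @param n_patients number of patients.
#' @param stay stay-length spec: `list(dist = "fixed", days = 10)` or
#'   `list(dist = "geometric", mean = 7)` (mean stay length in days, >= 1).
#' @param compliance single probability or named vector keyed by sub_id;
#'   applies to every executable subindicator not explicitly named.
#' @param prevalence named list overriding population prevalences
#'   (`ventilated`, `severe_ards`, `home_ventilation`, `invasive_device`,
#'   `antibiotics`, `inadequate_nutrition`, `enteral_contraindication`,
#'   `obesity`, `immobilization_order`).
#' @param start cohort admission date (all patients are admitted at 00:00 of
#'   this date; evaluation is per calendar day, so a common admission date
#'   loses no generality).
#' @param seed RNG seed.
#' @return a `qi_simconfig` list.
#' @export
sim_config <- function(n_patients = 100, stay = list(dist = "fixed", days = 10),
                       compliance = 0.8, prevalence = list(),
                       start = "2026-01-01", seed = 1L) {
  if (n_patients < 0) qi_stop("n_patients must be >= 0")
  defaults <- list(ventilated = 0.5, severe_ards = 0.5,
                   home_ventilation = 0.05, invasive_device = 0.7,
                   antibiotics = 0.5, inadequate_nutrition = 0.4,
                   enteral_contraindication = 0.15, obesity = 0.3,
                   immobilization_order = 0.15)
  bad <- setdiff(names(prevalence), names(defaults))
  if (length(bad)) qi_stop("unknown prevalence keys: ",
                           paste(bad, collapse = ", "))
  prev <- utils::modifyList(defaults, prevalence)
  if (any(unlist(prev) < 0 | unlist(prev) > 1))
    qi_stop("prevalences must lie in [0, 1]")
  structure(list(n_patients = as.integer(n_patients), stay = stay,
                 compliance = compliance, prevalence = prev,
                 start = as.Date(start), seed = as.integer(seed)),
            class = "qi_simconfig")
}

resolve_compliance <- function(compliance, catalog) {
  exec_ids <- names(Filter(function(q) q$type != "structure",
                           catalog$indicators))
  if (is.null(names(compliance))) {
    if (length(compliance) != 1L)
      qi_stop("unnamed compliance must be a single probability")
    comp <- stats::setNames(rep(as.numeric(compliance), length(exec_ids)),
                            exec_ids)
  } else {
    bad <- setdiff(names(compliance), exec_ids)
    if (length(bad))
      qi_stop("unknown sub_id in compliance map: ",
              paste(bad, collapse = ", "))
    comp <- stats::setNames(rep(NA_real_, length(exec_ids)), exec_ids)
    comp[names(compliance)] <- as.numeric(compliance)
    comp[is.na(comp)] <- 0.8
  }
  if (any(comp < 0 | comp > 1)) qi_stop("compliance must lie in [0, 1]")
  comp
}

sample_stay_length <- function(stay) {
  if (identical(stay$dist, "fixed")) return(as.integer(stay$days))
  if (identical(stay$dist, "geometric")) {
    if (stay$mean < 1) qi_stop("geometric stay mean must be >= 1")
    return(1L + stats::rgeom(1L, 1 / stay$mean))
  }
  qi_stop("unknown stay distribution '", stay$dist, "'")
}

#' Generate a synthetic ICU cohort
#'
#' Fully deterministic given the config seed. See the methods vignette for
#' the exact planting rules and the coordination between subindicators that
#' share concepts.
#'
#' @param config a [sim_config()].
#' @param catalog the indicator catalog (concepts and compliance keys).
#' @return list of `qi_patient`.
#' @export
generate_cohort <- function(config, catalog = load_default_catalog()) {
  set.seed(config$seed)
  comp <- resolve_compliance(config$compliance, catalog)
  prev <- config$prevalence
  adm0 <- as.POSIXct(paste(config$start, "00:00:00"), tz = "UTC")

  # "Indication of" (SNOMED 230165009) is shared by the device-indication and
  # antibiotic-indication concepts; the generator emits each concept's
  # discriminating coding so plantings do not cross-match
  coding_pick <- c(device_indication = 2L, antibiotic_indication = 2L)
  ev <- function(concept_key, time, value = NA_real_, unit = NA_character_,
                 end_time = NA) {
    k <- unname(coding_pick[concept_key])
    if (is.na(k)) k <- 1L
    cd <- catalog$concepts[[concept_key]]$codings[[k]]
    list(time = as.numeric(time), system = cd$system, code = cd$code,
         value = as.numeric(value),
         unit = as.character(unit),
         end_time = if (length(end_time) == 1 && is.na(end_time)[1])
           NA_real_ else as.numeric(end_time))
  }
  draw <- function(p) stats::runif(1L) < p

  patients <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    L <- sample_stay_length(config$stay)
    adm <- adm0
    disch <- adm + L * 86400
    days <- seq(qi_day(adm), by = "day", length.out = L)
    day0 <- function(d) as.POSIXct(paste(d, "00:00:00"), tz = "UTC")

    ventilated <- draw(prev$ventilated)
    ards <- ventilated && draw(prev$severe_ards)
    home_vent <- draw(prev$home_ventilation)
    device <- draw(prev$invasive_device)
    abx <- draw(prev$antibiotics)
    inad_nutrition <- draw(prev$inadequate_nutrition)
    contra <- draw(prev$enteral_contraindication)
    obese <- draw(prev$obesity)
    immobile <- draw(prev$immobilization_order)
    nourished <- inad_nutrition && !contra

    evs <- list(
      ev("icu_patient", adm, end_time = disch),
      ev("icu_stay", adm, value = L * 24, unit = "h", end_time = disch),
      ev("bmi", adm, value = if (obese) 35 else 24, unit = "kg/m2",
         end_time = disch))
    if (ventilated) evs <- c(evs, list(ev("invasive_ventilation", adm,
                                          end_time = disch)))
    if (ards) {
      evs <- c(evs, list(ev("ards", adm, end_time = disch)))
      for (di in seq_along(days))
        evs <- c(evs, list(ev("oxygenation_index",
                              day0(days[di]) + 8 * 3600, value = 85)))
    }
    # chronic dependence on home ventilation persists through the stay
    if (home_vent) evs <- c(evs, list(ev("home_ventilation",
                                         adm - 30 * 86400,
                                         end_time = disch)))
    if (device) evs <- c(evs, list(ev("invasive_device", adm,
                                      end_time = disch)))
    if (abx) evs <- c(evs, list(ev("antibiotics", adm, end_time = disch)))
    if (immobile) evs <- c(evs, list(ev("immobilization_order", adm,
                                        end_time = disch)))
    if (inad_nutrition) evs <- c(evs, list(ev("inadequate_nutrition",
                                              adm + 1800)))
    if (contra) evs <- c(evs, list(ev("enteral_contraindication",
                                      adm + 1800)))

    # ---- per-day indicators ------------------------------------------------
    for (di in seq_along(days)) {
      d <- days[di]
      t0 <- day0(d)
      # 1a: visit + specialist, drop the specialist on non-compliant days
      evs <- c(evs, list(ev("multiprofessional_visit", t0 + 10 * 3600)))
      if (draw(comp[["1a"]]))
        evs <- c(evs, list(ev("intensivist", t0 + 10 * 3600)))
      if (draw(comp[["1b"]]))
        evs <- c(evs, list(ev("daily_goals", t0 + 10.5 * 3600)))

      # 2a: one draw per day; non-compliant days miss one assessment-shift
      req <- shifts_within_stay(d, adm, disch)
      if (length(req)) {
        cells <- expand.grid(concept = c("sedation_assessment",
                                         "pain_assessment",
                                         "delirium_assessment"),
                             shift = req, stringsAsFactors = FALSE)
        drop_cell <- if (draw(comp[["2a"]])) 0L else
          sample.int(nrow(cells), 1L)
        sh <- qi_shifts_default()
        for (j in seq_len(nrow(cells))) {
          if (j == drop_cell) next
          start_h <- sh$start_hour[sh$label == cells$shift[j]]
          evs <- c(evs, list(ev(cells$concept[j], t0 + (start_h + 1) * 3600)))
        }
      }

      # 2b: non-compliant days push one score outside its acceptable range
      bad_plan <- if (draw(comp[["2b"]])) 0L else sample.int(3L, 1L)
      evs <- c(evs, list(
        ev("rass", t0 + 8 * 3600, value = if (bad_plan == 1L) 2 else 0),
        ev("nrs", t0 + 8 * 3600, value = if (bad_plan == 2L) 4 else 2),
        ev("cam_icu", t0 + 8 * 3600, value = if (bad_plan == 3L) 1 else 0),
        ev("icdsc", t0 + 8 * 3600, value = 0)))

      # QI3 (severe ARDS under invasive ventilation only)
      if (ards) {
        evs <- c(evs, list(
          ev("tidal_volume_ibw", t0 + 9 * 3600, unit = "mL/kg",
             value = if (draw(comp[["3a"]])) 6 else 7),
          ev("plateau_pressure", t0 + 9 * 3600, unit = "cm H2O",
             value = if (draw(comp[["3b"]])) 30 else 31),
          ev("driving_pressure", t0 + 9 * 3600, unit = "cm H2O",
             value = if (draw(comp[["3c"]])) 15 else 16)))
        if (draw(comp[["3d"]]))
          evs <- c(evs, list(ev("peep", t0 + 9 * 3600, value = 8,
                                unit = "cm H2O")))
      }

      # 4a: daily weaning evaluation for ventilated, not home-ventilated
      if (ventilated && !home_vent && draw(comp[["4a"]]))
        evs <- c(evs, list(ev("weaning_evaluation", t0 + 9 * 3600)))

      # 5a: daily device-indication documentation
      if (device && draw(comp[["5a"]]))
        evs <- c(evs, list(ev("device_indication", t0 + 11 * 3600)))

      # 5b/5c/5d/6b: event rates; compliance is the per-day event probability
      if (draw(comp[["5b"]]))
        evs <- c(evs, list(ev("hand_disinfectant", t0 + 12 * 3600,
                              value = 1, unit = "L")))
      if (device && draw(comp[["5c"]]))
        evs <- c(evs, list(ev("device_infection", t0 + 12 * 3600)))
      if (ventilated && draw(comp[["5d"]]))
        evs <- c(evs, list(ev("vap", t0 + 12 * 3600)))
      if (draw(comp[["6b"]]))
        evs <- c(evs, list(ev("blood_culture", t0 + 13 * 3600)))

      # 6a: antibiotic documentation triple, drop one when non-compliant
      if (abx) {
        docs <- c("antibiotic_indication", "antibiotic_focus",
                  "therapy_duration")
        drop_doc <- if (draw(comp[["6a"]])) 0L else sample.int(3L, 1L)
        for (j in seq_along(docs)) {
          if (j == drop_doc) next
          evs <- c(evs, list(ev(docs[j], t0 + 14 * 3600)))
        }
      }

      # 7b: daily calorie goal + intake for clinically nourished, non-obese
      if (nourished) {
        goal <- 2000
        evs <- c(evs, list(
          ev("calorie_goal", t0 + 9 * 3600, value = goal),
          ev("calorie_intake", t0 + 20 * 3600,
             value = if (draw(comp[["7b"]])) goal else goal - 1)))
      }

      # 9b: daily mobilization from day 2 on (day 1 is governed by 9a)
      if (!immobile && di > 1L && draw(comp[["9b"]]))
        evs <- c(evs, list(ev("mobilization", t0 + 10 * 3600)))
    }

    # ---- per-stay indicators -----------------------------------------------
    # 4b: non-compliant stays end in a transfer with home ventilation
    if (ventilated && !home_vent && !draw(comp[["4b"]]))
      evs <- c(evs, list(ev("home_ventilation", disch - 3600)))

    # 7a: enteral nutrition starts inside (or one hour outside) the window
    if (nourished) {
      start_t <- if (draw(comp[["7a"]])) adm + 12 * 3600 else adm + 25 * 3600
      evs <- c(evs, list(ev("clinical_nutrition", start_t, end_time = disch)))
    }

    # 8a/8b share the family-interview concept: one draw per stay drives both
    if (L * 24 > 72 && draw(comp[["8a"]])) {
      evs <- c(evs, list(ev("family_interview", adm + 24 * 3600)))
      total_d <- L
      n_blocks <- max(1L, ceiling(total_d / 7))
      for (k in seq_len(n_blocks - 1L)) {
        b0 <- adm + k * 7 * 86400
        b1 <- min(b0 + 7 * 86400, disch)
        evs <- c(evs, list(ev("family_interview",
                              b0 + as.numeric(b1 - b0, units = "secs") / 2)))
      }
    }

    # 9a: first mobilization within (or one hour outside) 24 h
    if (!immobile && draw(comp[["9a"]]))
      evs <- c(evs, list(ev("mobilization", adm + 12 * 3600)))

    patients[[i]] <- qi_patient(sprintf("P%04d", i), adm, disch,
                                events_from_rows(evs))
  }
  patients
}

events_from_rows <- function(rows) {
  if (!length(rows)) return(empty_events())
  num <- function(f) vapply(rows, function(r) r[[f]], numeric(1))
  chr <- function(f) vapply(rows, function(r) r[[f]], character(1))
  data.frame(time = as.POSIXct(num("time"), tz = "UTC",
                               origin = "1970-01-01"),
             end_time = as.POSIXct(num("end_time"), tz = "UTC",
                                   origin = "1970-01-01"),
             system = chr("system"), code = chr("code"), value = num("value"),
             unit = chr("unit"), stringsAsFactors = FALSE)
}

#' Generate a cohort with a Poisson-process event rate
#'
#' Plants numerator events (blood cultures by default) as a homogeneous
#' Poisson process with intensity `target_rate_per_1000 / 1000` per
#' patient-day, on top of plain ICU stays.
#'
#' @param config a [sim_config()] (stay/patient counts and seed are used).
#' @param target_rate_per_1000 expected events per 1000 patient-days (>= 0).
#' @param concept_key numerator concept (default `"blood_culture"`).
#' @param catalog the indicator catalog.
#' @return list of `qi_patient`.
#' @export
generate_rate_cohort <- function(config, target_rate_per_1000,
                                 concept_key = "blood_culture",
                                 catalog = load_default_catalog()) {
  if (target_rate_per_1000 < 0) qi_stop("target rate must be >= 0")
  set.seed(config$seed)
  adm0 <- as.POSIXct(paste(config$start, "00:00:00"), tz = "UTC")
  lambda <- target_rate_per_1000 / 1000
  cd_icu <- catalog$concepts[["icu_patient"]]$codings[[1]]
  cd_num <- catalog$concepts[[concept_key]]$codings[[1]]
  patients <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    L <- sample_stay_length(config$stay)
    adm <- adm0
    disch <- adm + L * 86400
    evs <- list(list(time = as.numeric(adm), system = cd_icu$system,
                     code = cd_icu$code, value = NA_real_,
                     unit = NA_character_, end_time = as.numeric(disch)))
    for (d in seq_len(L) - 1L) {
      k <- stats::rpois(1L, lambda)
      if (k > 0) {
        times <- as.numeric(adm) + d * 86400 + sort(stats::runif(k, 0, 86400))
        for (t in seq_len(k))
          evs <- c(evs, list(list(time = times[t], system = cd_num$system,
                                  code = cd_num$code, value = NA_real_,
                                  unit = NA_character_,
                                  end_time = NA_real_)))
      }
    }
    patients[[i]] <- qi_patient(sprintf("R%04d", i), adm, disch,
                                events_from_rows(evs))
  }
  patients
}
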