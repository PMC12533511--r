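#' Patient event data
#'
#' The engine consumes ICU stays with timestamped coded events. Events are
#' stored per patient as a data.frame with columns `time`, `end_time`
#' (`NA` for point events), `system`, `code`, `value`, `unit`. Interval
#' events (e.g. ventilation episodes) overlap every calendar day their
#' interval intersects; history events before admission are allowed (for
#' pre-existing conditions such as home ventilation).
#'
#' @param time,end_time timestamps (strings or POSIXct); `end_time` optional.
#' @param system,code event coding.
#' @param value optional numeric value.
#' @param unit optional unit string.
#' @return a one-row events data.frame.
#' @export
qi_event <- function(time, system, code, value = NA_real_, unit = NA_character_,
                     end_time = NA) {
  time <- qi_time(time)
  end_time <- if (length(end_time) == 1 && is.na(end_time)[1])
    as.POSIXct(NA) else qi_time(end_time)
  if (!is.na(end_time) && end_time < time)
    qi_stop("event end_time precedes time")
  data.frame(time = time, end_time = end_time, system = system, code = code,
             value = as.numeric(value), unit = as.character(unit),
             stringsAsFactors = FALSE)
}

empty_events <- function() {
  data.frame(time = as.POSIXct(character(), tz = "UTC"),
             end_time = as.POSIXct(character(), tz = "UTC"),
             system = character(), code = character(), value = numeric(),
             unit = character(), stringsAsFactors = FALSE)
}

#' Create a patient record
#'
#' @param patient_id identifier.
#' @param admission,discharge stay boundaries (discharge >= admission).
#' @param events events data.frame (rows from [qi_event()], `rbind`-ed).
#' @return a `qi_patient`.
#' @export
qi_patient <- function(patient_id, admission, discharge,
                       events = empty_events()) {
  admission <- qi_time(admission)
  discharge <- qi_time(discharge)
  if (discharge < admission) qi_stop("discharge precedes admission")
  structure(list(patient_id = patient_id, admission = admission,
                 discharge = discharge, events = events),
            class = "qi_patient")
}

#' Calendar days of a stay
#'
#' Patient-days are calendar days overlapping the stay; admission and
#' discharge days count as full patient-days. A discharge at exactly
#' midnight does not open a new patient-day.
#'
#' @param patient a `qi_patient`.
#' @return vector of `Date`.
#' @export
stay_days <- function(patient) {
  last <- patient$discharge
  if (format(last, "%H%M%S") == "000000" && last > patient$admission)
    last <- last - 1
  seq(qi_day(patient$admission), qi_day(last), by = "day")
}

#' Read and write patient event streams as JSON Lines
#'
#' One JSON object per line. Stay lines carry
#' `{"type":"stay","patient_id":...,"admission":...,"discharge":...}`, event
#' lines `{"type":"event","patient_id":...,"time":...,"system":...,
#' "code":...}` with optional `value`, `unit`, `end_time`.
#'
#' @param patients list of `qi_patient`.
#' @param path file path.
#' @return `read_events_jsonl` returns a list of `qi_patient`.
#' @export
write_events_jsonl <- function(patients, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (p in patients) {
    writeLines(jsonlite::toJSON(list(type = "stay", patient_id = p$patient_id,
                                     admission = format_time(p$admission),
                                     discharge = format_time(p$discharge)),
                                auto_unbox = TRUE), con)
    ev <- p$events
    for (i in seq_len(nrow(ev))) {
      line <- list(type = "event", patient_id = p$patient_id,
                   time = format_time(ev$time[i]), system = ev$system[i],
                   code = ev$code[i])
      if (!is.na(ev$value[i])) line$value <- ev$value[i]
      if (!is.na(ev$unit[i])) line$unit <- ev$unit[i]
      if (!is.na(ev$end_time[i])) line$end_time <- format_time(ev$end_time[i])
      writeLines(jsonlite::toJSON(line, auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}

#' @rdname write_events_jsonl
#' @export
read_events_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  objs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  stays <- Filter(function(o) identical(o$type, "stay"), objs)
  events <- Filter(function(o) identical(o$type, "event"), objs)
  ev_by_patient <- split(events, vapply(events, `[[`, character(1),
                                        "patient_id"))
  lapply(stays, function(s) {
    evs <- ev_by_patient[[s$patient_id]] %||% list()
    df <- if (length(evs)) {
      do.call(rbind, lapply(evs, function(e) {
        qi_event(e$time, e$system, e$code, e$value %||% NA_real_,
                 e$unit %||% NA_character_, e$end_time %||% NA)
      }))
    } else empty_events()
    qi_patient(s$patient_id, s$admission, s$discharge, df)
  })
}
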