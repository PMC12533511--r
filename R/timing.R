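QI_TIMING_KINDS <- c("PER_DAY", "PER_SHIFT", "PER_WEEK",
                     "WITHIN_HOURS_OF_ADMISSION", "ONCE_PER_STAY")

#' Default clinical shift windows
#'
#' Morning 06:00-14:00, afternoon 14:00-22:00, night 22:00-06:00 of the next
#' day; "every 8 hours" requirements are interpreted as once per shift.
#'
#' @return data.frame with columns `label`, `start_hour`, `end_hour`
#'   (end 30 means 06:00 of the following day).
#' @export
qi_shifts_default <- function() {
  data.frame(label = c("morning", "afternoon", "night"),
             start_hour = c(6, 14, 22),
             end_hour = c(14, 22, 30),
             stringsAsFactors = FALSE)
}

#' Create a timing specification
#'
#' @param kind one of `PER_DAY`, `PER_SHIFT`, `PER_WEEK`,
#'   `WITHIN_HOURS_OF_ADMISSION`, `ONCE_PER_STAY`.
#' @param n required count per period (default 1).
#' @param hours window length, `WITHIN_HOURS_OF_ADMISSION` only.
#' @param shifts shift windows, `PER_SHIFT` only (defaults to
#'   [qi_shifts_default()]).
#' @return a `qi_timing` object.
#' @export
qi_timing <- function(kind, n = 1L, hours = NULL, shifts = NULL) {
  kind <- match.arg(kind, QI_TIMING_KINDS)
  if (!is_count(n)) qi_stop("timing n must be a positive integer")
  if (kind == "WITHIN_HOURS_OF_ADMISSION") {
    if (is.null(hours) || !is.numeric(hours) || hours <= 0)
      qi_stop("WITHIN_HOURS_OF_ADMISSION requires positive hours")
    hours <- as.numeric(hours)
  } else if (!is.null(hours)) {
    qi_stop("hours only allowed for WITHIN_HOURS_OF_ADMISSION")
  }
  if (kind == "PER_SHIFT") {
    shifts <- shifts %||% qi_shifts_default()
  } else if (!is.null(shifts)) {
    qi_stop("shifts only allowed for PER_SHIFT")
  }
  structure(list(kind = kind, n = as.integer(n), hours = hours,
                 shifts = shifts), class = "qi_timing")
}

#' Shift assignment of a timestamp relative to a calendar day
#'
#' The night shift of day `d` runs from `d` 22:00 to `d+1` 06:00: a timestamp
#' at `d+1` 02:00 belongs to the night shift of day `d` and to no shift of
#' day `d+1`. Timestamps between 00:00 and 06:00 therefore never match any
#' shift of their own calendar day.
#'
#' @param time POSIXct timestamp(s).
#' @param day the calendar `Date` whose shifts are asked about.
#' @param shifts shift window table (default [qi_shifts_default()]).
#' @return character vector: the shift label of `day` each timestamp falls
#'   into, or `NA` if none.
#' @export
shift_of_time <- function(time, day, shifts = qi_shifts_default()) {
  day0 <- as.POSIXct(paste(day, "00:00:00"), tz = "UTC")
  hrs <- as.numeric(difftime(time, day0, units = "hours"))
  out <- rep(NA_character_, length(hrs))
  for (i in seq_len(nrow(shifts))) {
    hit <- hrs >= shifts$start_hour[i] & hrs < shifts$end_hour[i]
    out[hit & is.na(out)] <- shifts$label[i]
  }
  out
}

# Shift windows of `day` that lie fully inside [admission, discharge].
shifts_within_stay <- function(day, admission, discharge,
                               shifts = qi_shifts_default()) {
  day0 <- as.POSIXct(paste(day, "00:00:00"), tz = "UTC")
  start <- day0 + shifts$start_hour * 3600
  end <- day0 + shifts$end_hour * 3600
  shifts$label[start >= admission & end <= discharge]
}

timing_label <- function(t) {
  switch(t$kind,
         PER_DAY = paste0(t$n, "×/day"),
         PER_SHIFT = paste0(t$n, "×/shift"),
         PER_WEEK = paste0(t$n, "×/week"),
         WITHIN_HOURS_OF_ADMISSION =
           paste0("within ", format_qi_number(t$hours), " h of admission"),
         ONCE_PER_STAY = "once per stay")
}
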