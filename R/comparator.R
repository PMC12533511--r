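QI_COMPARATOR_OPS <- c("EQ", "NE", "LT", "LE", "GT", "GE", "RANGE")

#' Create a value comparator
#'
#' Comparators constrain the numeric value of an event (e.g. `RASS` in
#' `[-1, +1]`, `plateau pressure <= 30 cm H2O`). Units are opaque strings and
#' must match the event's unit exactly during evaluation; no unit conversion
#' is performed (the indicators fix their units).
#'
#' @param op one of `EQ, NE, LT, LE, GT, GE, RANGE`.
#' @param value threshold (lower bound for `RANGE`).
#' @param value_high upper bound, `RANGE` only.
#' @param unit unit string, may be `""` for unitless scores.
#' @param reference optional concept key; when set, the threshold is not a
#'   constant but the same-day value of the referenced concept (used for
#'   "calorie intake >= individual calorie requirement").
#' @return an object of class `qi_comparator`.
#' @export
qi_comparator <- function(op, value = NA_real_, value_high = NULL, unit = "",
                          reference = NULL) {
  op <- match.arg(op, QI_COMPARATOR_OPS)
  if (op == "RANGE") {
    if (is.null(value_high)) qi_stop("RANGE comparator requires value_high")
    if (value > value_high) qi_stop("RANGE requires value <= value_high")
  } else if (!is.null(value_high)) {
    qi_stop("value_high is only allowed for RANGE")
  }
  if (!is.null(reference) && op == "RANGE")
    qi_stop("reference thresholds cannot be ranges")
  structure(list(op = op, value = as.numeric(value),
                 value_high = if (!is.null(value_high)) as.numeric(value_high),
                 unit = unit, reference = reference),
            class = "qi_comparator")
}

#' Test a value against a comparator
#'
#' @param cmp a [qi_comparator()].
#' @param value numeric value(s) to test.
#' @param threshold overrides `cmp$value` (used for reference thresholds).
#' @return logical vector.
#' @export
comparator_eval <- function(cmp, value, threshold = NULL) {
  v <- cmp$value
  if (!is.null(threshold)) v <- threshold
  switch(cmp$op,
         EQ = value == v,
         NE = value != v,
         LT = value < v,
         LE = value <= v,
         GT = value > v,
         GE = value >= v,
         RANGE = value >= v & value <= cmp$value_high)
}

comparator_symbol <- c(EQ = "=", NE = "≠", LT = "<", LE = "≤",
                       GT = ">", GE = "≥")

format_qi_number <- function(x) {
  # drop trailing zeros but keep decimals ("6", "0.5", "-1")
  s <- formatC(x, format = "fg", digits = 15)
  trimws(s)
}

#' @export
format.qi_comparator <- function(x, ...) {
  if (x$op == "RANGE") {
    out <- paste(format_qi_number(x$value), "to", format_qi_number(x$value_high))
  } else if (!is.null(x$reference)) {
    out <- paste(comparator_symbol[[x$op]], "{", x$reference, "}")
  } else {
    out <- paste(comparator_symbol[[x$op]], format_qi_number(x$value))
  }
  if (nzchar(x$unit %||% "")) out <- paste(out, x$unit)
  out
}
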