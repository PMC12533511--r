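#' Intervention items
#'
#' Interventions distinguish actions that must occur (or not occur) at
#' defined frequencies, continuously applicable value goals, and
#' per-1000-patient-day rates.
#'
#' @param concept concept key.
#' @param timing a [qi_timing()].
#' @param negated `TRUE` when the action must NOT occur (evaluated per stay,
#'   e.g. "no transfer with ventilation at home").
#' @return a `qi_action` / `qi_goal` / `qi_rate` object.
#' @export
qi_action <- function(concept, timing, negated = FALSE) {
  stopifnot(is_string(concept), inherits(timing, "qi_timing"))
  structure(list(item = "ACTION", concept = concept, timing = timing,
                 negated = isTRUE(negated)),
            class = c("qi_action", "qi_item"))
}

#' @rdname qi_action
#' @param comparator a [qi_comparator()]; required for goals.
#' @export
qi_goal <- function(concept, comparator) {
  stopifnot(is_string(concept))
  if (!inherits(comparator, "qi_comparator"))
    qi_stop("a goal requires a comparator")
  structure(list(item = "GOAL", concept = concept, comparator = comparator),
            class = c("qi_goal", "qi_item"))
}

#' @rdname qi_action
#' @param threshold optional [qi_comparator()] with op in `GE, GT, LE, RANGE`
#'   applied to the observed rate per 1000 patient-days; omit for indicators
#'   the catalog reports without a pass/fail bound.
#' @export
qi_rate <- function(concept, threshold = NULL) {
  stopifnot(is_string(concept))
  if (!is.null(threshold)) {
    if (!inherits(threshold, "qi_comparator"))
      qi_stop("rate threshold must be a qi_comparator")
    if (!threshold$op %in% c("GE", "GT", "LE", "RANGE"))
      qi_stop("rate threshold op must be one of GE, GT, LE, RANGE")
  }
  structure(list(item = "RATE", concept = concept, threshold = threshold,
                 per = 1000), class = c("qi_rate", "qi_item"))
}

#' Combine intervention items
#'
#' @param method combination method (as for expressions).
#' @param items list of action/goal/rate items (at least one).
#' @param n count for `AT_LEAST` / `EXACTLY`.
#' @return a `qi_intervention` object.
#' @export
qi_intervention <- function(method, items, n = NULL) {
  method <- match.arg(method, QI_COMBO_METHODS)
  if (!length(items)) qi_stop("intervention requires at least one item")
  if (!all(vapply(items, inherits, logical(1), "qi_item")))
    qi_stop("intervention items must be qi_action/qi_goal/qi_rate objects")
  if (method %in% c("AT_LEAST", "EXACTLY")) {
    if (!is_count(n) || n > length(items))
      qi_stop(method, " requires 1 <= n <= number of items")
    n <- as.integer(n)
  } else n <- NULL
  structure(list(method = method, n = n, items = items),
            class = "qi_intervention")
}
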