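QI_COMBO_METHODS <- c("ALL", "ANY", "AT_LEAST", "EXACTLY", "ONE_OR_MORE")

#' Boolean criterion expressions
#'
#' Populations are nested Boolean expressions over criterion atoms. An atom
#' names a concept and may constrain its value with a comparator; combinators
#' are `ALL` (conjunction), `ANY` (disjunction), `AT_LEAST n`, `EXACTLY n`
#' and `ONE_OR_MORE` (an alias of `AT_LEAST 1`), plus `NOT`.
#'
#' @param concept concept key (string).
#' @param comparator optional [qi_comparator()].
#' @return a `qi_expr` object.
#' @export
qi_atom <- function(concept, comparator = NULL) {
  if (!is_string(concept)) qi_stop("atom concept must be a concept key string")
  if (!is.null(comparator) && !inherits(comparator, "qi_comparator"))
    qi_stop("comparator must be a qi_comparator")
  structure(list(kind = "ATOM", concept = concept, comparator = comparator),
            class = c("qi_atom", "qi_expr"))
}

#' @rdname qi_atom
#' @param x child expression.
#' @export
qi_not <- function(x) {
  stopifnot(inherits(x, "qi_expr"))
  structure(list(kind = "NOT", child = x), class = c("qi_not", "qi_expr"))
}

#' @rdname qi_atom
#' @param method combination method.
#' @param children list of child expressions (at least one).
#' @param n count for `AT_LEAST` / `EXACTLY`.
#' @export
qi_combo <- function(method, children, n = NULL) {
  method <- match.arg(method, QI_COMBO_METHODS)
  if (!length(children)) qi_stop("combination requires at least one child")
  if (!all(vapply(children, inherits, logical(1), "qi_expr")))
    qi_stop("combination children must be qi_expr objects")
  if (method %in% c("AT_LEAST", "EXACTLY")) {
    if (!is_count(n)) qi_stop(method, " requires a positive integer n")
    if (n > length(children))
      qi_stop(method, " n exceeds the number of children")
    n <- as.integer(n)
  } else {
    n <- NULL
  }
  structure(list(kind = "COMBO", method = method, n = n, children = children),
            class = c("qi_combo", "qi_expr"))
}

#' @rdname qi_atom
#' @param ... child expressions.
#' @export
qi_all <- function(...) qi_combo("ALL", list(...))

#' @rdname qi_atom
#' @export
qi_any <- function(...) qi_combo("ANY", list(...))

#' @rdname qi_atom
#' @export
qi_at_least <- function(n, ...) qi_combo("AT_LEAST", list(...), n = n)

#' @rdname qi_atom
#' @export
qi_exactly <- function(n, ...) qi_combo("EXACTLY", list(...), n = n)

#' Stable identity of an atom
#'
#' Concept key plus (if present) the comparator signature; used to key truth
#' assignments in [expr_eval()].
#'
#' @param atom a `qi_atom`.
#' @return a string.
#' @export
atom_key <- function(atom) {
  if (is.null(atom$comparator)) return(atom$concept)
  cmp <- atom$comparator
  paste0(atom$concept, "|", cmp$op, ":",
         if (is.null(cmp$reference)) format_qi_number(cmp$value) else cmp$reference,
         if (!is.null(cmp$value_high)) paste0("..", format_qi_number(cmp$value_high)),
         if (nzchar(cmp$unit %||% "")) paste0("|", cmp$unit))
}

#' All atoms of an expression
#'
#' @param expr a `qi_expr`.
#' @return list of `qi_atom` objects, in depth-first order.
#' @export
expr_atoms <- function(expr) {
  switch(expr$kind,
         ATOM = list(expr),
         NOT = expr_atoms(expr$child),
         COMBO = do.call(c, lapply(expr$children, expr_atoms)))
}

#' Evaluate a Boolean expression under a truth assignment
#'
#' `ALL` is conjunction, `ANY` disjunction; `AT_LEAST n` / `EXACTLY n` count
#' true children; `ONE_OR_MORE` is `AT_LEAST 1`. The assignment may be a
#' named logical vector/list keyed by [atom_key()], or a function taking an
#' atom and returning its truth value (vectorized truth values are supported,
#' enabling per-day evaluation in one pass).
#'
#' @param expr a `qi_expr`.
#' @param atom_truth named logical vector/list, or `function(atom)`.
#' @return logical scalar (or vector when the assignment is vectorized).
#' @export
expr_eval <- function(expr, atom_truth) {
  get_truth <- if (is.function(atom_truth)) {
    atom_truth
  } else {
    function(atom) {
      key <- atom_key(atom)
      if (!key %in% names(atom_truth))
        qi_stop("no truth assignment for atom '", key, "'")
      atom_truth[[key]]
    }
  }
  eval_node <- function(node) {
    switch(node$kind,
      ATOM = get_truth(node),
      NOT = !eval_node(node$child),
      COMBO = {
        vals <- lapply(node$children, eval_node)
        counts <- Reduce(`+`, vals)
        switch(node$method,
               ALL = counts == length(vals),
               ANY = counts >= 1L,
               ONE_OR_MORE = counts >= 1L,
               AT_LEAST = counts >= node$n,
               EXACTLY = counts == node$n)
      })
  }
  eval_node(expr)
}

expr_equal <- function(a, b) identical(unclass_expr(a), unclass_expr(b))

unclass_expr <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_expr) else x
}
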