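# Back-translation: rendering indicator plans into the human-readable
# intermediate representation (concept display names + AND/OR/NOT +
# numerical quantifiers) used for clinician review, and a strict parser
# turning such statements back into model objects. The grammar is
# deliberately unambiguous: mixed AND/OR requires parentheses, nested
# combinations are always parenthesized, and output is guaranteed to
# re-parse to the identical model.

# ---- rendering --------------------------------------------------------------

display_of <- function(catalog, key) {
  cp <- catalog$concepts[[key]]
  if (is.null(cp)) qi_stop("unknown concept '", key, "'",
                           class = "icuqi_render_error")
  cp$display
}

render_comparator <- function(cmp, catalog) {
  if (cmp$op == "RANGE") {
    out <- paste(format_qi_number(cmp$value), "to",
                 format_qi_number(cmp$value_high))
  } else if (!is.null(cmp$reference)) {
    return(paste(comparator_symbol[[cmp$op]],
                 display_of(catalog, cmp$reference)))
  } else {
    out <- paste(comparator_symbol[[cmp$op]], format_qi_number(cmp$value))
  }
  if (nzchar(cmp$unit %||% "")) out <- paste(out, cmp$unit)
  out
}

render_expr <- function(expr, catalog, nested = FALSE) {
  switch(expr$kind,
    ATOM = {
      out <- display_of(catalog, expr$concept)
      if (!is.null(expr$comparator))
        out <- paste(out, render_comparator(expr$comparator, catalog))
      out
    },
    NOT = {
      inner <- render_expr(expr$child, catalog, nested = TRUE)
      paste("NOT", inner)
    },
    COMBO = {
      parts <- vapply(expr$children, render_expr, character(1),
                      catalog = catalog, nested = TRUE)
      out <- switch(expr$method,
        ALL = paste(parts, collapse = " AND "),
        ANY = paste(parts, collapse = " OR "),
        ONE_OR_MORE = paste(parts, collapse = " OR "),
        AT_LEAST = paste0("AT LEAST ", expr$n, " OF (",
                          paste(parts, collapse = "; "), ")"),
        EXACTLY = paste0("EXACTLY ", expr$n, " OF (",
                         paste(parts, collapse = "; "), ")"))
      if (nested && expr$method %in% c("ALL", "ANY", "ONE_OR_MORE") &&
          length(parts) > 1L)
        out <- paste0("(", out, ")")
      out
    })
}

action_prefix <- function(item) {
  if (item$negated) "never during stay" else timing_label(item$timing)
}

render_item <- function(item, catalog) {
  switch(item$item,
    ACTION = paste0(action_prefix(item), ": ",
                    display_of(catalog, item$concept)),
    GOAL = paste0(display_of(catalog, item$concept), " ",
                  render_comparator(item$comparator, catalog),
                  " (continuous)"),
    RATE = paste0(display_of(catalog, item$concept), " ",
                  if (!is.null(item$threshold))
                    paste0(render_comparator(item$threshold, catalog), " "),
                  "per 1000 patient-days"))
}

render_intervention <- function(iv, catalog) {
  items <- iv$items
  # shared-frequency action groups render with one distributed prefix:
  # "1x/day: (A OR B)"
  all_actions <- all(vapply(items, function(it) it$item == "ACTION", logical(1)))
  if (all_actions && length(items) > 1L &&
      iv$method %in% c("ALL", "ANY", "ONE_OR_MORE")) {
    prefixes <- vapply(items, action_prefix, character(1))
    if (length(unique(prefixes)) == 1L) {
      conn <- if (iv$method == "ALL") " AND " else " OR "
      return(paste0(prefixes[1], ": (",
                    paste(vapply(items, function(it)
                      display_of(catalog, it$concept), character(1)),
                      collapse = conn), ")"))
    }
  }
  parts <- vapply(items, render_item, character(1), catalog = catalog)
  switch(iv$method,
    ALL = paste(parts, collapse = " AND "),
    ANY = paste(parts, collapse = " OR "),
    ONE_OR_MORE = paste(parts, collapse = " OR "),
    AT_LEAST = paste0("AT LEAST ", iv$n, " OF (",
                      paste(parts, collapse = "; "), ")"),
    EXACTLY = paste0("EXACTLY ", iv$n, " OF (",
                     paste(parts, collapse = "; "), ")"))
}

#' Back-translate indicators into the intermediate representation
#'
#' Renders each population-intervention pair as a human-readable statement
#' built only from concept display names, connectors (AND/OR/NOT),
#' quantifier symbols and counts/periods. Rendering is deterministic and
#' always re-parseable by [parse_statement()].
#'
#' @param x a `qi_indicator`, a sub_id string, a `qi_bundle`, or a
#'   `qi_catalog` (all executable indicators).
#' @param catalog concept source (default: bundled catalog).
#' @return data.frame with columns `sub_id`, `plan_id`, `population_text`,
#'   `intervention_text`.
#' @export
backtranslate <- function(x, catalog = load_default_catalog()) {
  if (inherits(x, "qi_bundle")) x <- decode_bundle(x, catalog)
  if (is.character(x)) x <- get_indicator(catalog, x)
  if (inherits(x, "qi_catalog")) {
    execs <- Filter(function(q) q$type != "structure", x$indicators)
    out <- do.call(rbind, lapply(execs, backtranslate, catalog = catalog))
    rownames(out) <- NULL
    return(out)
  }
  if (x$type == "structure")
    qi_stop("structure indicator '", x$sub_id, "' has no executable plans",
            class = "icuqi_unsupported_type")
  out <- do.call(rbind, lapply(x$plans, function(p) {
    data.frame(sub_id = x$sub_id, plan_id = p$id,
               population_text = render_expr(p$population, catalog),
               intervention_text = render_intervention(p$intervention, catalog),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# ---- tokenizer --------------------------------------------------------------

qi_tokenize <- function(text) {
  # comparator symbols may arrive as unicode or ASCII digraphs
  text <- gsub("<=", "≤", text, fixed = TRUE)
  text <- gsub(">=", "≥", text, fixed = TRUE)
  text <- gsub("!=", "≠", text, fixed = TRUE)
  pattern <- "≤|≥|≠|[()<>=:;]|[^\\s()<>=:;]+"
  m <- gregexpr(pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1) return(character(0))
  regmatches(text, list(m))[[1]]
}

is_num_token <- function(tok) grepl("^[+-]?[0-9]+([.][0-9]+)?$", tok)

CMP_TOKENS <- c("=" = "EQ", "≠" = "NE", "<" = "LT", "≤" = "LE",
                ">" = "GT", "≥" = "GE")

RESERVED <- c("AND", "OR", "NOT", "OF", "to", "(", ")", ";", ":",
              names(CMP_TOKENS))

# token cursor shared via environment
new_cursor <- function(tokens) {
  env <- new.env(parent = emptyenv())
  env$tokens <- tokens
  env$pos <- 1L
  env
}
peek <- function(cur, offset = 0L) {
  i <- cur$pos + offset
  if (i <= length(cur$tokens)) cur$tokens[[i]] else NULL
}
advance <- function(cur) { cur$pos <- cur$pos + 1L; cur$tokens[[cur$pos - 1L]] }
expect_tok <- function(cur, tok) {
  got <- peek(cur)
  if (!identical(got, tok))
    parse_fail(cur, "expected '", tok, "'")
  advance(cur)
}
at_end <- function(cur) cur$pos > length(cur$tokens)
parse_fail <- function(cur, ...) {
  qi_stop("parse error at token ", cur$pos, " ('",
          peek(cur) %||% "<end>", "'): ", ...,
          class = "icuqi_parse_error")
}

# longest run of non-reserved tokens that forms a known concept display name
parse_concept <- function(cur, catalog, displays) {
  words <- character(0)
  start <- cur$pos
  while (!at_end(cur) && !peek(cur) %in% RESERVED && !is_num_token(peek(cur))) {
    if (identical(peek(cur), "per") && identical(peek(cur, 1L), "1000")) break
    words <- c(words, advance(cur))
  }
  if (!length(words)) parse_fail(cur, "expected a concept name")
  name <- paste(words, collapse = " ")
  key <- displays[[name]]
  if (is.null(key)) {
    cur$pos <- start
    parse_fail(cur, "unknown concept name '", name, "'")
  }
  key
}

display_map <- function(catalog) {
  keys <- names(catalog$concepts)
  stats::setNames(as.list(keys),
                  vapply(catalog$concepts, `[[`, character(1), "display"))
}

parse_number <- function(cur) {
  tok <- peek(cur)
  if (is.null(tok) || !is_num_token(tok)) parse_fail(cur, "expected a number")
  as.numeric(advance(cur))
}

# unit = run of non-reserved word tokens not starting a rate marker or
# "(continuous)" suffix
parse_unit <- function(cur) {
  words <- character(0)
  repeat {
    tok <- peek(cur)
    if (is.null(tok) || tok %in% RESERVED || is_num_token(tok)) break
    if (identical(tok, "per") && identical(peek(cur, 1L), "1000")) break
    if (identical(tok, "continuous")) break
    words <- c(words, advance(cur))
  }
  paste(words, collapse = " ")
}

parse_comparator <- function(cur) {
  sym <- peek(cur)
  # a bare "a to b" range carries no comparator symbol
  if (!is.null(sym) && is_num_token(sym) && identical(peek(cur, 1L), "to")) {
    value <- parse_number(cur)
    advance(cur)
    high <- parse_number(cur)
    return(qi_comparator("RANGE", value, high, parse_unit(cur)))
  }
  if (is.null(sym) || !sym %in% names(CMP_TOKENS)) return(NULL)
  advance(cur)
  op <- CMP_TOKENS[[sym]]
  value <- parse_number(cur)
  if (identical(peek(cur), "to")) {
    advance(cur)
    high <- parse_number(cur)
    unit <- parse_unit(cur)
    if (op != "GE" && op != "LE" && op != "EQ" && op != "RANGE" && op != "GT" &&
        op != "LT") parse_fail(cur, "invalid range")
    return(qi_comparator("RANGE", value, high, unit))
  }
  unit <- parse_unit(cur)
  qi_comparator(op, value, unit = unit)
}

# ---- population grammar -----------------------------------------------------

parse_population_expr <- function(cur, catalog, displays) {
  first <- parse_population_unary(cur, catalog, displays)
  children <- list(first)
  conn <- NULL
  while (!at_end(cur) && peek(cur) %in% c("AND", "OR")) {
    tok <- advance(cur)
    if (is.null(conn)) conn <- tok
    else if (!identical(conn, tok))
      parse_fail(cur, "mixed AND/OR without parentheses")
    children <- c(children, list(parse_population_unary(cur, catalog, displays)))
  }
  if (is.null(conn)) return(normalize_range_atoms(first))
  method <- if (conn == "AND") "ALL" else "ANY"
  normalize_range_atoms(qi_combo(method, children))
}

parse_population_unary <- function(cur, catalog, displays) {
  tok <- peek(cur)
  if (identical(tok, "NOT")) {
    advance(cur)
    return(qi_not(parse_population_unary(cur, catalog, displays)))
  }
  if (identical(tok, "(")) {
    advance(cur)
    inner <- parse_population_expr(cur, catalog, displays)
    expect_tok(cur, ")")
    return(inner)
  }
  if (identical(tok, "AT") || identical(tok, "EXACTLY")) {
    method <- if (identical(tok, "AT")) { advance(cur); expect_tok(cur, "LEAST"); "AT_LEAST" }
              else { advance(cur); "EXACTLY" }
    n <- parse_number(cur)
    expect_tok(cur, "OF")
    expect_tok(cur, "(")
    children <- list(parse_population_expr(cur, catalog, displays))
    while (identical(peek(cur), ";")) {
      advance(cur)
      children <- c(children, list(parse_population_expr(cur, catalog, displays)))
    }
    expect_tok(cur, ")")
    return(qi_combo(method, children, n = n))
  }
  key <- parse_concept(cur, catalog, displays)
  cmp <- parse_comparator(cur)
  qi_atom(key, cmp)
}

# merge "X >= a AND X <= b" pairs on one concept into a RANGE atom
normalize_range_atoms <- function(expr) {
  if (expr$kind != "COMBO" || expr$method != "ALL") return(expr)
  ch <- expr$children
  merged <- list()
  used <- rep(FALSE, length(ch))
  for (i in seq_along(ch)) {
    if (used[i]) next
    a <- ch[[i]]
    paired <- FALSE
    if (a$kind == "ATOM" && !is.null(a$comparator) &&
        a$comparator$op %in% c("GE", "LE") && is.null(a$comparator$reference)) {
      for (j in seq_along(ch)) {
        if (j == i || used[j]) next
        b <- ch[[j]]
        if (b$kind == "ATOM" && identical(b$concept, a$concept) &&
            !is.null(b$comparator) &&
            b$comparator$op %in% c("GE", "LE") &&
            b$comparator$op != a$comparator$op &&
            identical(b$comparator$unit, a$comparator$unit)) {
          lo <- if (a$comparator$op == "GE") a$comparator else b$comparator
          hi <- if (a$comparator$op == "LE") a$comparator else b$comparator
          merged <- c(merged, list(qi_atom(a$concept,
            qi_comparator("RANGE", lo$value, hi$value, lo$unit))))
          used[c(i, j)] <- TRUE
          paired <- TRUE
          break
        }
      }
    }
    if (!paired && !used[i]) { merged <- c(merged, list(a)); used[i] <- TRUE }
  }
  if (length(merged) == 1L) merged[[1]] else qi_combo("ALL", merged)
}

# ---- intervention grammar ---------------------------------------------------

TIMING_PREFIX_RE <- "^([0-9]+)[×x]/(day|shift|week)$"

try_parse_timing_prefix <- function(cur) {
  tok <- peek(cur)
  if (is.null(tok)) return(NULL)
  if (grepl(TIMING_PREFIX_RE, tok)) {
    m <- regmatches(tok, regexec(TIMING_PREFIX_RE, tok))[[1]]
    if (!identical(peek(cur, 1L), ":")) return(NULL)
    advance(cur); advance(cur)
    kind <- c(day = "PER_DAY", shift = "PER_SHIFT", week = "PER_WEEK")[[m[3]]]
    return(list(timing = qi_timing(kind, as.integer(m[2])), negated = FALSE))
  }
  if (identical(tok, "within")) {
    hours <- as.numeric(peek(cur, 1L))
    if (identical(peek(cur, 2L), "h") && identical(peek(cur, 3L), "of") &&
        identical(peek(cur, 4L), "admission") && identical(peek(cur, 5L), ":")) {
      for (k in 1:6) advance(cur)
      return(list(timing = qi_timing("WITHIN_HOURS_OF_ADMISSION",
                                     hours = hours), negated = FALSE))
    }
  }
  if (identical(tok, "once") && identical(peek(cur, 1L), "per") &&
      identical(peek(cur, 2L), "stay") && identical(peek(cur, 3L), ":")) {
    for (k in 1:4) advance(cur)
    return(list(timing = qi_timing("ONCE_PER_STAY"), negated = FALSE))
  }
  if (identical(tok, "never") && identical(peek(cur, 1L), "during") &&
      identical(peek(cur, 2L), "stay") && identical(peek(cur, 3L), ":")) {
    for (k in 1:4) advance(cur)
    return(list(timing = qi_timing("ONCE_PER_STAY"), negated = TRUE))
  }
  NULL
}

parse_intervention_item <- function(cur, catalog, displays) {
  pre <- try_parse_timing_prefix(cur)
  if (!is.null(pre)) {
    if (identical(peek(cur), "(")) {
      # distributed prefix over a concept group: "1x/day: (A OR B)"
      advance(cur)
      keys <- list(parse_concept(cur, catalog, displays))
      conn <- NULL
      while (!at_end(cur) && peek(cur) %in% c("AND", "OR")) {
        tok <- advance(cur)
        if (is.null(conn)) conn <- tok
        else if (!identical(conn, tok))
          parse_fail(cur, "mixed AND/OR without parentheses")
        keys <- c(keys, list(parse_concept(cur, catalog, displays)))
      }
      expect_tok(cur, ")")
      items <- lapply(keys, function(k)
        qi_action(k, pre$timing, negated = pre$negated))
      return(list(items = items,
                  method = if (identical(conn, "OR")) "ANY" else "ALL"))
    }
    key <- parse_concept(cur, catalog, displays)
    return(list(items = list(qi_action(key, pre$timing,
                                       negated = pre$negated)),
                method = NULL))
  }
  # goal or rate: concept, comparator, then marker
  key <- parse_concept(cur, catalog, displays)
  sym <- peek(cur)
  cmp <- NULL
  if (!is.null(sym) && is_num_token(sym) && identical(peek(cur, 1L), "to")) {
    cmp <- parse_comparator(cur)
  } else if (!is.null(sym) && sym %in% names(CMP_TOKENS)) {
    op <- CMP_TOKENS[[advance(cur)]]
    if (!is.null(peek(cur)) && is_num_token(peek(cur))) {
      value <- parse_number(cur)
      if (identical(peek(cur), "to")) {
        advance(cur)
        high <- parse_number(cur)
        cmp <- qi_comparator("RANGE", value, high, parse_unit(cur))
      } else {
        cmp <- qi_comparator(op, value, unit = parse_unit(cur))
      }
    } else {
      ref <- parse_concept(cur, catalog, displays)
      cmp <- qi_comparator(op, reference = ref)
    }
  }
  if (identical(peek(cur), "per") && identical(peek(cur, 1L), "1000")) {
    advance(cur); advance(cur)
    if (!identical(advance(cur), "patient-days"))
      parse_fail(cur, "expected 'patient-days'")
    return(list(items = list(qi_rate(key, cmp)), method = NULL))
  }
  if (identical(peek(cur), "(") && identical(peek(cur, 1L), "continuous")) {
    advance(cur); advance(cur); expect_tok(cur, ")")
    if (is.null(cmp)) parse_fail(cur, "goal without comparator")
    return(list(items = list(qi_goal(key, cmp)), method = NULL))
  }
  parse_fail(cur, "expected '(continuous)' or 'per 1000 patient-days'")
}

parse_intervention_text <- function(cur, catalog, displays) {
  tok <- peek(cur)
  if (identical(tok, "AT") || identical(tok, "EXACTLY")) {
    method <- if (identical(tok, "AT")) { advance(cur); expect_tok(cur, "LEAST"); "AT_LEAST" }
              else { advance(cur); "EXACTLY" }
    n <- parse_number(cur)
    expect_tok(cur, "OF")
    expect_tok(cur, "(")
    items <- parse_intervention_item(cur, catalog, displays)$items
    while (identical(peek(cur), ";")) {
      advance(cur)
      items <- c(items, parse_intervention_item(cur, catalog, displays)$items)
    }
    expect_tok(cur, ")")
    return(qi_intervention(method, items, n = n))
  }
  first <- parse_intervention_item(cur, catalog, displays)
  items <- first$items
  conn <- NULL
  while (!at_end(cur) && peek(cur) %in% c("AND", "OR")) {
    t <- advance(cur)
    if (is.null(conn)) conn <- t
    else if (!identical(conn, t))
      parse_fail(cur, "mixed AND/OR without parentheses")
    items <- c(items, parse_intervention_item(cur, catalog, displays)$items)
  }
  method <- if (!is.null(first$method)) first$method
            else if (identical(conn, "OR")) "ANY"
            else "ALL"
  if (!is.null(first$method) && !is.null(conn))
    parse_fail(cur, "cannot combine a prefixed group with further items")
  normalize_goal_ranges(qi_intervention(method, items))
}

# merge "X >= a (continuous) AND X <= b (continuous)" into one RANGE goal
normalize_goal_ranges <- function(iv) {
  if (iv$method != "ALL") return(iv)
  items <- iv$items
  merged <- list()
  used <- rep(FALSE, length(items))
  for (i in seq_along(items)) {
    if (used[i]) next
    a <- items[[i]]
    paired <- FALSE
    if (a$item == "GOAL" && a$comparator$op %in% c("GE", "LE") &&
        is.null(a$comparator$reference)) {
      for (j in seq_along(items)) {
        if (j == i || used[j]) next
        b <- items[[j]]
        if (b$item == "GOAL" && identical(b$concept, a$concept) &&
            b$comparator$op %in% c("GE", "LE") &&
            b$comparator$op != a$comparator$op &&
            identical(b$comparator$unit, a$comparator$unit)) {
          lo <- if (a$comparator$op == "GE") a$comparator else b$comparator
          hi <- if (a$comparator$op == "LE") a$comparator else b$comparator
          merged <- c(merged, list(qi_goal(a$concept,
            qi_comparator("RANGE", lo$value, hi$value, lo$unit))))
          used[c(i, j)] <- TRUE
          paired <- TRUE
          break
        }
      }
    }
    if (!paired && !used[i]) { merged <- c(merged, list(a)); used[i] <- TRUE }
  }
  qi_intervention(iv$method, merged, n = iv$n)
}

#' Parse an intermediate-representation statement
#'
#' Inverse of [backtranslate()]: parses a population text and an intervention
#' text back into model objects. The grammar rejects ambiguity: mixed AND/OR
#' without parentheses is an error, unknown concept names are an error naming
#' the position. Paired one-sided bounds on the same concept (`X >= a AND
#' X <= b`) are normalized into a single range.
#'
#' @param population_text population sentence.
#' @param intervention_text intervention sentence.
#' @param catalog catalog supplying the display-name vocabulary.
#' @return list with elements `population` (a `qi_expr`) and `intervention`
#'   (a `qi_intervention`).
#' @export
parse_statement <- function(population_text, intervention_text,
                            catalog = load_default_catalog()) {
  displays <- display_map(catalog)
  cur <- new_cursor(qi_tokenize(population_text))
  population <- parse_population_expr(cur, catalog, displays)
  if (!at_end(cur)) parse_fail(cur, "trailing input in population")
  cur <- new_cursor(qi_tokenize(intervention_text))
  intervention <- parse_intervention_text(cur, catalog, displays)
  if (!at_end(cur)) parse_fail(cur, "trailing input in intervention")
  list(population = population, intervention = intervention)
}

#' Read and write intermediate-representation files
#'
#' The `.qitxt` format stores one statement per block: a `[plan-id]` header
#' followed by `population:` and `intervention:` lines, blocks separated by
#' blank lines.
#'
#' @param statements data.frame as returned by [backtranslate()].
#' @param path file path.
#' @return `read_qitxt` returns the statements data.frame.
#' @export
write_qitxt <- function(statements, path) {
  blocks <- vapply(seq_len(nrow(statements)), function(i) {
    paste0("[", statements$plan_id[i], "] ", statements$sub_id[i], "\n",
           "population: ", statements$population_text[i], "\n",
           "intervention: ", statements$intervention_text[i], "\n")
  }, character(1))
  writeLines(paste(blocks, collapse = "\n"), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_qitxt
#' @export
read_qitxt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  heads <- grep("^\\[", lines)
  out <- lapply(heads, function(i) {
    m <- regmatches(lines[i], regexec("^\\[([^]]+)\\]\\s*(\\S+)", lines[i]))[[1]]
    pop <- sub("^population:\\s*", "", lines[i + 1L])
    iv <- sub("^intervention:\\s*", "", lines[i + 2L])
    data.frame(sub_id = m[3], plan_id = m[2], population_text = pop,
               intervention_text = iv, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
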