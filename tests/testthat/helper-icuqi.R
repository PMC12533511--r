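# Shared fixtures: a cached catalog, compact patient builders, and an
# independent brute-force oracle for Boolean expressions.

the_catalog <- load_default_catalog()

# first coding of a concept, as (system, code)
cc <- function(key, k = 1L) {
  cd <- the_catalog$concepts[[key]]$codings[[k]]
  c(cd$system, cd$code)
}

# build a patient from compact event specs:
#   list("concept_key", "2026-01-02 08:00", value =, unit =, end =)
mk_patient <- function(id = "P1", admission = "2026-01-01 00:00",
                       discharge = "2026-01-11 00:00", specs = list()) {
  rows <- lapply(specs, function(s) {
    co <- cc(s[[1]], if (!is.null(s$coding)) s$coding else 1L)
    qi_event(s[[2]], co[1], co[2],
             value = if (!is.null(s$value)) s$value else NA_real_,
             unit = if (!is.null(s$unit)) s$unit else NA_character_,
             end_time = if (!is.null(s$end)) s$end else NA)
  })
  events <- if (length(rows)) do.call(rbind, rows) else NULL
  qi_patient(id, admission, discharge,
             if (is.null(events)) icuqi:::empty_events() else events)
}

# an ICU patient covered by the base population for the whole stay
mk_icu_patient <- function(id = "P1", admission = "2026-01-01 00:00",
                           discharge = "2026-01-11 00:00", specs = list()) {
  mk_patient(id, admission, discharge,
             c(list(list("icu_patient", admission, end = discharge)), specs))
}

# random expression over atom keys a1..ak (depth-bounded)
rand_expr <- function(depth, n_atoms) {
  atoms <- paste0("a", seq_len(n_atoms))
  build <- function(d) {
    if (d == 0 || stats::runif(1) < 0.3) {
      return(qi_atom(sample(atoms, 1)))
    }
    kind <- sample(c("NOT", "COMBO"), 1, prob = c(0.25, 0.75))
    if (kind == "NOT") return(qi_not(build(d - 1)))
    k <- sample(1:3, 1)
    children <- lapply(seq_len(k), function(i) build(d - 1))
    method <- sample(c("ALL", "ANY", "AT_LEAST", "EXACTLY", "ONE_OR_MORE"), 1)
    n <- if (method %in% c("AT_LEAST", "EXACTLY")) sample(seq_len(k), 1)
    qi_combo(method, children, n = n)
  }
  build(depth)
}

# independent oracle: translate the expression into base-R logical code and
# evaluate it with eval(parse(...))
oracle_eval <- function(expr, truth) {
  code <- function(e) {
    switch(e$kind,
      ATOM = atom_key(e),
      NOT = paste0("(!", code(e$child), ")"),
      COMBO = {
        parts <- vapply(e$children, code, character(1))
        s <- paste0("sum(", paste(parts, collapse = ", "), ")")
        switch(e$method,
               ALL = paste0("(", s, " == ", length(parts), ")"),
               ANY = paste0("(", s, " >= 1)"),
               ONE_OR_MORE = paste0("(", s, " >= 1)"),
               AT_LEAST = paste0("(", s, " >= ", e$n, ")"),
               EXACTLY = paste0("(", s, " == ", e$n, ")"))
      })
  }
  eval(parse(text = code(expr)), envir = as.list(truth))
}

# all 2^k truth assignments over the atoms of an expression
all_assignments <- function(expr) {
  keys <- unique(vapply(expr_atoms(expr), atom_key, character(1)))
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(keys)))
  names(grid) <- keys
  grid
}
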