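#' Code systems supported by the indicator model
#'
#' SNOMED CT and LOINC are the international vocabularies used for semantic
#' annotation; DIVI-QI-S is the supplementary code system defined for the
#' intensive-care concepts that neither vocabulary covers.
#'
#' @export
QI_SYSTEMS <- c(SNOMED = "SNOMED", LOINC = "LOINC", DIVI_QI_S = "DIVI_QI_S")

qi_system_urls <- c(
  SNOMED = "http://snomed.info/sct",
  LOINC = "http://loinc.org",
  DIVI_QI_S = "https://www.divi.de/fhir/CodeSystem/divi-qi-s"
)

#' Create a coding
#'
#' A coding is one vocabulary code attached to a medical concept.
#'
#' @param system one of `"SNOMED"`, `"LOINC"`, `"DIVI_QI_S"`.
#' @param code the code value (non-empty string).
#' @param display the display name printed for this code.
#' @param omop_id optional OMOP concept identifier.
#' @return an object of class `qi_coding`.
#' @export
qi_coding <- function(system, code, display, omop_id = NULL) {
  system <- match.arg(system, unname(QI_SYSTEMS))
  if (!is_string(code) || !nzchar(code)) qi_stop("coding code must be a non-empty string")
  if (!is_string(display)) qi_stop("coding display must be a string")
  structure(list(system = system, code = code, display = display,
                 omop_id = if (!is.null(omop_id)) as.integer(omop_id)),
            class = "qi_coding")
}

#' Create a concept
#'
#' A concept is a clinical notion (e.g. "invasive ventilation") referenced by
#' indicator criteria; it carries at least one vocabulary coding. An event in
#' the patient data matches a concept when its (system, code) pair equals any
#' of the concept's codings.
#'
#' @param key stable identifier, unique within a catalog.
#' @param display human-readable name used by the back-translation.
#' @param codings list of [qi_coding()] objects (at least one).
#' @param value_bearing whether events for this concept carry numeric values
#'   (scores, pressures, volumes); only value-bearing concepts may be
#'   constrained by comparators.
#' @return an object of class `qi_concept`.
#' @export
qi_concept <- function(key, display, codings, value_bearing = FALSE) {
  if (!is_string(key) || !nzchar(key)) qi_stop("concept key must be a non-empty string")
  if (!length(codings)) qi_stop("concept '", key, "' must have at least one coding")
  if (!all(vapply(codings, inherits, logical(1), "qi_coding")))
    qi_stop("codings must be qi_coding objects")
  sig <- vapply(codings, function(cd) paste(cd$system, cd$code), character(1))
  if (anyDuplicated(sig))
    qi_stop("concept '", key, "' has duplicate (system, code) pairs")
  structure(list(key = key, display = display, codings = codings,
                 value_bearing = isTRUE(value_bearing)), class = "qi_concept")
}

#' Build a code-system registry from a set of concepts
#'
#' Flattens concepts into one entry per (system, code) pair. Entries shared by
#' several concepts (the same code reused across indicators) are kept once.
#'
#' @param concepts list of [qi_concept()] objects, or a `qi_catalog`.
#' @return a `data.frame` of class `qi_registry` with columns `system`,
#'   `code`, `display`, `omop_id`, `concept_key`.
#' @export
qi_registry <- function(concepts) {
  if (inherits(concepts, "qi_catalog")) concepts <- concepts$concepts
  rows <- lapply(concepts, function(cp) {
    do.call(rbind, lapply(cp$codings, function(cd) {
      data.frame(system = cd$system, code = cd$code, display = cd$display,
                 omop_id = if (is.null(cd$omop_id)) NA_integer_ else as.integer(cd$omop_id),
                 concept_key = cp$key, stringsAsFactors = FALSE)
    }))
  })
  df <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(system = character(), code = character(),
               display = character(), omop_id = integer(),
               concept_key = character(), stringsAsFactors = FALSE)
  }
  # keep the first entry per (system, code); duplicates across concepts share
  # one display by construction of the source table
  df <- df[!duplicated(paste(df$system, df$code)), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("qi_registry", "data.frame")
  df
}

#' Look up a code in the registry
#'
#' @param registry a [qi_registry()].
#' @param system code system name.
#' @param code code value.
#' @return a one-row data.frame (system, code, display, omop_id, concept_key).
#' @export
lookup_code <- function(registry, system, code) {
  hit <- registry[registry$system == system & registry$code == code, , drop = FALSE]
  if (nrow(hit) == 0L)
    qi_stop("code not found in registry: ", system, " ", code,
            class = "icuqi_not_found")
  hit[1L, , drop = FALSE]
}

#' Concept mapping statistics
#'
#' Counts the unique (system, code) pairs used across all concepts of a
#' catalog, how many are mapped to international vocabularies (SNOMED CT or
#' LOINC) and how many required custom DIVI-QI-S codes. A code reused by
#' several indicators counts once.
#'
#' @param catalog a `qi_catalog` (or list of concepts).
#' @return a list with `unique_concepts`, `mapped_international`,
#'   `custom_divi` and `pct_mapped` (integer-rounded percentage).
#' @export
concept_stats <- function(catalog) {
  reg <- qi_registry(catalog)
  n <- nrow(reg)
  intl <- sum(reg$system %in% c("SNOMED", "LOINC"))
  divi <- sum(reg$system == "DIVI_QI_S")
  list(unique_concepts = n,
       mapped_international = intl,
       custom_divi = divi,
       pct_mapped = if (n == 0L) 0L else as.integer(round(100 * intl / n)))
}

#' Export the registry as code-system JSON files
#'
#' Writes one JSON code-system file per system (`system` url, version and a
#' `concept` array of code/display/omop entries).
#'
#' @param registry a [qi_registry()].
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_code_systems <- function(registry, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (sys in unique(registry$system)) {
    sub <- registry[registry$system == sys, , drop = FALSE]
    obj <- list(
      resourceType = "CodeSystem",
      id = tolower(gsub("_", "-", sys)),
      url = unname(qi_system_urls[[sys]]),
      version = "2023",
      content = "fragment",
      concept = lapply(seq_len(nrow(sub)), function(i) {
        entry <- list(code = sub$code[i], display = sub$display[i])
        if (!is.na(sub$omop_id[i])) {
          entry$property <- list(list(code = "omop-id",
                                      valueInteger = sub$omop_id[i]))
        }
        entry
      })
    )
    path <- file.path(dir, paste0("codesystem-", obj$id, ".json"))
    writeLines(canonical_json(obj), path, useBytes = TRUE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
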