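#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

qi_stop <- function(..., class = "icuqi_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == as.integer(x)
}

#' Canonical JSON serialization
#'
#' Serializes an R list structure to JSON with recursively sorted object keys,
#' two-space indentation and UTF-8 encoding, so that identical inputs always
#' yield byte-identical output. Used for all FHIR resource output.
#'
#' @param x a list (JSON object/array) structure.
#' @return a single JSON string.
#' @export
canonical_json <- function(x) {
  as.character(jsonlite::toJSON(sort_keys(x), auto_unbox = TRUE, pretty = 2,
                                digits = NA, null = "null", na = "null"))
}

sort_keys <- function(x) {
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) && all(nzchar(nm))) {
      x <- x[order(nm, method = "radix")]
    }
    lapply(x, sort_keys)
  } else {
    x
  }
}

# Timestamps are site-local and timezone-naive; parse everything as UTC so
# calendar-day arithmetic never crosses DST boundaries.
qi_time <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                   "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"))
  out
}

qi_day <- function(t) as.Date(t, tz = "UTC")

format_time <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
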