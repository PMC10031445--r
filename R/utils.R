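# Canonical JSON plumbing. All documents the engine writes are canonical:
# recursively sorted object keys, UTF-8, full numeric precision, decimal
# point, newline-terminated. This is what makes byte-level round-trip
# guarantees possible.

sort_keys_rec <- function(x) {
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) && any(nzchar(nm))) {
      x <- x[order(nm, method = "radix")]
    }
    x <- lapply(x, sort_keys_rec)
  }
  x
}

#' Serialize an R structure to canonical JSON
#'
#' Object keys are sorted recursively (radix/byte order), numbers keep full
#' precision, `NULL`/`NA` become JSON `null`, and the result ends with a
#' newline. Two structurally equal documents always serialize to identical
#' bytes, which the round-trip tests rely on.
#'
#' @param x nested list structure (unnamed lists become JSON arrays).
#' @param path optional file path; when given the JSON is written there and
#'   the path is returned invisibly, otherwise the JSON string is returned.
#' @return JSON string, or `path` invisibly.
#' @export
canonical_json <- function(x, path = NULL) {
  x <- sort_keys_rec(x)
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                           null = "null", na = "null", pretty = FALSE)
  txt <- paste0(as.character(json), "\n")
  if (is.null(path)) {
    return(txt)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(txt), con)
  invisible(path)
}

read_json_file <- function(path) {
  if (!file.exists(path)) {
    stop("file does not exist: ", path)
  }
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

# Schema envelope check shared by all readers; unknown versions are
# rejected, never silently coerced.
check_schema <- function(doc, schema_id, versions = "1.0", path = "<memory>") {
  if (!is.list(doc)) {
    stop("document is not a JSON object: ", path)
  }
  if (is.null(doc$schema_id) || !identical(doc$schema_id, schema_id)) {
    stop(sprintf("%s: expected schema_id '%s', found '%s'",
                 path, schema_id, if (is.null(doc$schema_id)) "<absent>" else doc$schema_id))
  }
  if (is.null(doc$schema_version) || !doc$schema_version %in% versions) {
    stop(sprintf("%s: unsupported schema_version '%s' for %s",
                 path, if (is.null(doc$schema_version)) "<absent>" else doc$schema_version,
                 schema_id))
  }
  invisible(doc)
}

# scalar helpers ------------------------------------------------------------

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x)
}

is_scalar_string <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x)
}

# A "missing" input slot: JSON null parses to NULL, R code may hand us NA.
is_absent <- function(x) {
  is.null(x) || (length(x) == 1L && is.na(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Format a value for display: integers without decimals, continuous values
# with one decimal (renderer convention).
format_value <- function(value, integer = FALSE) {
  if (is.character(value)) {
    return(value)
  }
  if (integer || isTRUE(all.equal(value, round(value), tolerance = 1e-9))) {
    formatC(round(value), format = "d")
  } else {
    formatC(value, format = "f", digits = 1)
  }
}
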