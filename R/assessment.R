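# Assessment records: one patient's raw clinical values plus questionnaire
# item responses at one timepoint, with explicit missingness.

ASSESSMENT_SCHEMA_ID <- "diag360/assessment"

#' Construct an assessment record
#'
#' @param patient_id opaque patient identifier.
#' @param timepoint ISO-8601 date string (`"YYYY-MM-DD"`).
#' @param clinical_values named list mapping body-domain element ids to
#'   numeric values (albuminuria stage as a category string). Absent
#'   elements are simply omitted (or set to `NA`).
#' @param item_responses named list mapping instrument ids to vectors (or
#'   lists) of raw item responses in the declared item order; `NA`/`NULL`
#'   marks an unanswered item, an omitted instrument is fully unanswered.
#' @return A `diag360_assessment` object (not yet validated against a
#'   config; see [validate_assessment()]).
#' @export
new_assessment <- function(patient_id, timepoint,
                           clinical_values = list(),
                           item_responses = list()) {
  if (!is_scalar_string(patient_id)) stop("patient_id must be a string")
  if (!is_scalar_string(timepoint) ||
      !grepl("^\\d{4}-\\d{2}-\\d{2}$", timepoint)) {
    stop("timepoint must be an ISO-8601 date string (YYYY-MM-DD)")
  }
  structure(list(patient_id = patient_id,
                 timepoint = timepoint,
                 clinical_values = clinical_values,
                 item_responses = item_responses),
            class = "diag360_assessment")
}

#' Validate an assessment against a rule configuration
#'
#' Collects *all* violations (unknown element ids, unknown instruments,
#' non-numeric or out-of-range values) and reports them in one error, so a
#' malformed record names every offending field at once. Absent values are
#' preserved as absent, never coerced.
#'
#' @param assessment a `diag360_assessment`.
#' @param config a `diag360_config`.
#' @return The assessment, invisibly, when valid.
#' @export
validate_assessment <- function(assessment, config) {
  stopifnot(inherits(assessment, "diag360_assessment"))
  problems <- character(0)

  unknown_el <- setdiff(names(assessment$clinical_values),
                        config$clinical_element_ids)
  if (length(unknown_el) > 0L) {
    problems <- c(problems, paste0("unknown clinical element id(s): ",
                                   paste(unknown_el, collapse = ", ")))
  }
  for (eid in intersect(names(assessment$clinical_values),
                        config$clinical_element_ids)) {
    v <- assessment$clinical_values[[eid]]
    if (is_absent(v)) next
    e <- config$elements[[eid]]
    if (identical(e$value_kind, "categorical")) {
      if (!is_scalar_string(v) || !v %in% unlist(e$categories)) {
        problems <- c(problems, sprintf(
          "clinical value '%s': '%s' is not one of the declared categories",
          eid, paste(v, collapse = ",")))
      }
    } else if (!is_scalar_number(v)) {
      problems <- c(problems, sprintf(
        "clinical value '%s': expected a number, got %s", eid, deparse(v)))
    } else if (v < e$range[[1L]] || v > e$range[[2L]]) {
      problems <- c(problems, sprintf(
        "clinical value '%s': %s outside valid range [%s, %s]",
        eid, v, e$range[[1L]], e$range[[2L]]))
    }
  }

  unknown_inst <- setdiff(names(assessment$item_responses),
                          config$instrument_order)
  if (length(unknown_inst) > 0L) {
    problems <- c(problems, paste0("unknown instrument id(s): ",
                                   paste(unknown_inst, collapse = ", ")))
  }
  for (iid in intersect(names(assessment$item_responses),
                        config$instrument_order)) {
    res <- tryCatch({
      normalize_items(assessment$item_responses[[iid]],
                      config$instruments[[iid]])
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) problems <- c(problems, res)
  }

  if (length(problems) > 0L) {
    stop("assessment invalid:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(assessment)
}

#' Read an assessment record from JSON
#'
#' @param path path to an assessment JSON document.
#' @param config a `diag360_config` to validate against.
#' @return A validated `diag360_assessment`.
#' @export
read_assessment <- function(path, config) {
  raw <- read_json_file(path)
  check_schema(raw, ASSESSMENT_SCHEMA_ID, path = path)
  if (is.null(raw$patient_id) || is.null(raw$timepoint)) {
    stop(path, ": assessment must carry patient_id and timepoint")
  }
  a <- new_assessment(raw$patient_id, raw$timepoint,
                      clinical_values = raw$clinical_values %||% list(),
                      item_responses = raw$item_responses %||% list())
  validate_assessment(a, config)
  a
}

#' Serialize an assessment to canonical JSON
#'
#' @param assessment a `diag360_assessment`.
#' @param path optional output path.
#' @return JSON string, or `path` invisibly.
#' @export
write_assessment <- function(assessment, path = NULL) {
  stopifnot(inherits(assessment, "diag360_assessment"))
  payload <- list(
    schema_id = ASSESSMENT_SCHEMA_ID,
    schema_version = "1.0",
    patient_id = assessment$patient_id,
    timepoint = assessment$timepoint,
    clinical_values = canonical_values(assessment$clinical_values),
    item_responses = lapply(assessment$item_responses, canonical_items)
  )
  canonical_json(payload, path)
}

# Drop absent clinical slots; keep item vectors as arrays with nulls.
canonical_values <- function(values) {
  keep <- !vapply(values, is_absent, TRUE)
  lapply(values[keep], function(v) v)
}

canonical_items <- function(items) {
  lapply(as.list(items), function(v) if (is_absent(v)) NULL else v)
}

#' @export
print.diag360_assessment <- function(x, ...) {
  cat(sprintf("<diag360 assessment: patient '%s' at %s>\n",
              x$patient_id, x$timepoint))
  cat(sprintf("  %d clinical value(s), %d instrument response set(s)\n",
              length(x$clinical_values), length(x$item_responses)))
  invisible(x)
}
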