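# Diagnosis profiles: per-element and per-parameter traffic-light
# statuses for all four domains, plus serialization and tabular export.

PROFILE_SCHEMA_ID <- "diag360/profile"

new_profile <- function(patient_id, timepoint, config_id,
                        element_status, parameter_status) {
  structure(list(patient_id = patient_id,
                 timepoint = timepoint,
                 config_id = config_id,
                 element_status = element_status,
                 parameter_status = parameter_status),
            class = "diag360_profile")
}

#' Read a diagnosis profile from JSON
#'
#' @param path path to a profile JSON document.
#' @return A `diag360_profile`.
#' @export
read_profile <- function(path) {
  raw <- read_json_file(path)
  check_schema(raw, PROFILE_SCHEMA_ID, path = path)
  ps <- lapply(raw$parameter_status, function(s) {
    assert_status(s)
    s
  })
  new_profile(raw$patient_id, raw$timepoint, raw$config_id,
              element_status = raw$element_status %||% list(),
              parameter_status = ps)
}

#' Serialize a diagnosis profile to canonical JSON
#'
#' @param profile a `diag360_profile`.
#' @param path optional output path.
#' @return JSON string, or `path` invisibly.
#' @export
write_profile <- function(profile, path = NULL) {
  stopifnot(inherits(profile, "diag360_profile"))
  payload <- list(
    schema_id = PROFILE_SCHEMA_ID,
    schema_version = "1.0",
    patient_id = profile$patient_id,
    timepoint = profile$timepoint,
    config_id = profile$config_id,
    element_status = profile$element_status,
    parameter_status = profile$parameter_status
  )
  canonical_json(payload, path)
}

#' Tabulate a profile as a data frame
#'
#' One row per parameter in config order: parameter id, domain, display
#' label and traffic-light status (21 rows for the reference config).
#'
#' @param profile a `diag360_profile`.
#' @param config the `diag360_config` the profile was built with.
#' @return A `data.frame` with columns `parameter_id`, `domain_id`,
#'   `label`, `status`.
#' @export
profile_table <- function(profile, config) {
  stopifnot(inherits(profile, "diag360_profile"))
  pids <- config$parameter_order
  data.frame(
    parameter_id = pids,
    domain_id = vapply(pids, function(p) config$parameters[[p]]$domain_id, ""),
    label = vapply(pids, function(p) cfg_label(config$parameters[[p]]), ""),
    status = vapply(pids, function(p) profile$parameter_status[[p]], ""),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Export a profile to CSV
#'
#' @param profile a `diag360_profile`.
#' @param config the matching `diag360_config`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_profile_csv <- function(profile, config, path) {
  utils::write.csv(profile_table(profile, config), path, row.names = FALSE)
  invisible(path)
}

#' List the parameters flagged for improvement
#'
#' @param profile a `diag360_profile`.
#' @param statuses which statuses count as flagged (default orange + red,
#'   the middle- and low-ranking scores).
#' @return Character vector of parameter ids, in profile order.
#' @export
flagged_parameters <- function(profile, statuses = c("orange", "red")) {
  stopifnot(inherits(profile, "diag360_profile"))
  ids <- names(profile$parameter_status)
  ids[vapply(ids, function(p) profile$parameter_status[[p]] %in% statuses, TRUE)]
}

#' @export
print.diag360_profile <- function(x, ...) {
  counts <- table(factor(unlist(x$parameter_status), levels = STATUS_LEVELS))
  cat(sprintf("<diag360 profile: patient '%s' at %s (config %s)>\n",
              x$patient_id, x$timepoint, x$config_id))
  cat(sprintf("  parameters: %d green, %d orange, %d red, %d gray\n",
              counts[["green"]], counts[["orange"]], counts[["red"]],
              counts[["gray"]]))
  invisible(x)
}
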