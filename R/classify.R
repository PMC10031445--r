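# Classification: cutoff bands map element values to traffic-light
# statuses; decision rules combine element statuses into parameter
# statuses, producing the diagnosis profile.

#' Classify a single element value against its cutoff bands
#'
#' Numeric elements use the configured ordered bands (half-open,
#' left-closed by default; inclusivity flags are explicit in the config so
#' rules like "score of 50 or below is red" are expressible). Categorical
#' elements match the category sets. An absent value is gray. A value
#' inside the declared valid range but outside all bands is a
#' configuration error (validation prevents this for loaded configs); a
#' value outside the declared valid range is a validation error.
#'
#' @param element_id element id declared in `config`.
#' @param value numeric value or category string; `NULL`/`NA` for absent.
#' @param config a `diag360_config`.
#' @return One of `"green"`, `"orange"`, `"red"`, `"gray"`.
#' @examples
#' cfg <- load_reference_config()
#' classify_element("systolic", 135, cfg) # "green"
#' classify_element("systolic", 140, cfg) # "orange" (left-closed band)
#' @export
classify_element <- function(element_id, value, config) {
  e <- cfg_element(config, element_id)
  if (is_absent(value)) {
    return("gray")
  }
  if (identical(e$value_kind, "categorical")) {
    if (!is_scalar_string(value)) {
      stop(sprintf("element '%s': expected a category string, got %s",
                   element_id, deparse(value)))
    }
    for (b in e$bands) {
      if (value %in% unlist(b$categories)) return(b$status)
    }
    stop(sprintf("element '%s': unknown category '%s'", element_id, value))
  }
  if (!is_scalar_number(value)) {
    stop(sprintf("element '%s': expected a numeric value, got %s",
                 element_id, deparse(value)))
  }
  lo <- e$range[[1L]]; hi <- e$range[[2L]]
  if (value < lo || value > hi) {
    stop(sprintf("element '%s': value %s outside valid range [%s, %s]",
                 element_id, value, lo, hi))
  }
  for (b in e$bands) {
    in_lo <- value > b$lower || (isTRUE(b$lower_incl) && value == b$lower)
    in_hi <- value < b$upper || (isTRUE(b$upper_incl) && value == b$upper)
    if (in_lo && in_hi) return(b$status)
  }
  stop(sprintf("configuration error: element '%s' has no band containing %s",
               element_id, value))
}

#' Combine element statuses into a parameter status
#'
#' The default `worst_of` rule returns the maximum severity among the
#' statuses; if any required element is gray (unmeasured) the parameter is
#' gray — no partial credit. An `explicit_table` rule looks the status
#' tuple up in a configured table covering every combination.
#'
#' @param statuses character vector of statuses (`green`/`orange`/`red`/
#'   `gray`), one per element, in the parameter's element order.
#' @param rule either the string `"worst_of"` or a decision-rule spec list
#'   with `rule_kind` and optionally `explicit_table`.
#' @return A single status string.
#' @examples
#' combine_statuses(c("orange", "red"))  # "red"
#' combine_statuses(c("gray", "green"))  # "gray"
#' @export
combine_statuses <- function(statuses, rule = "worst_of") {
  if (length(statuses) < 1L) stop("combine_statuses: empty status list")
  lapply(statuses, assert_status)
  if (is.character(rule)) rule <- list(rule_kind = rule)
  kind <- rule$rule_kind %||% "worst_of"
  if (any(statuses == "gray")) {
    return("gray")
  }
  if (kind == "worst_of") {
    return(RANKED_STATUSES[[max(status_rank(statuses)) + 1L]])
  }
  if (kind == "explicit_table") {
    key <- paste(statuses, collapse = "|")
    out <- rule$explicit_table[[key]]
    if (is.null(out)) {
      stop("explicit_table is missing status combination: ", key)
    }
    return(out)
  }
  stop("unknown rule_kind: ", kind)
}

#' Classify blood pressure from systolic and diastolic values
#'
#' Bands both elements and combines them with the configured decision rule
#' (worst-of in the reference config, which reproduces the printed
#' nine-row combined decision table exactly). One absent value makes the
#' parameter gray.
#'
#' @param systolic,diastolic pressures in mm Hg, or `NA`/`NULL` if absent.
#' @param config a `diag360_config`.
#' @return A status string.
#' @examples
#' cfg <- load_reference_config()
#' classify_blood_pressure(150, 95, cfg)  # "orange"
#' classify_blood_pressure(135, 102, cfg) # "red"
#' @export
classify_blood_pressure <- function(systolic, diastolic, config) {
  s <- classify_element("systolic", systolic, config)
  d <- classify_element("diastolic", diastolic, config)
  combine_statuses(c(s, d), config$rules[["blood_pressure"]])
}

#' Classify mental health from a WHO-5 well-being score
#'
#' Scores of 50 or below screen positive for depression and are red;
#' scores above 50 are green. There is no orange band for this parameter.
#'
#' @param who5_score score in 0..100 or `NA`/`NULL`.
#' @param config a `diag360_config` (defaults to the reference config).
#' @return `"red"`, `"green"`, or `"gray"` when absent.
#' @examples
#' cfg <- load_reference_config()
#' classify_mental_health(50, cfg) # "red"
#' classify_mental_health(51, cfg) # "green"
#' @export
classify_mental_health <- function(who5_score, config = load_reference_config()) {
  classify_element("who5_score", who5_score, config)
}

#' Build a diagnosis profile from an assessment
#'
#' Runs the full pipeline in order: questionnaire scoring, cutoff banding
#' of every element value, decision-rule combination per parameter. Every
#' parameter in the config receives a status (gray when undetermined);
#' element statuses are recorded only for elements whose inputs were
#' present. The profile records the rule-config identifier for provenance.
#'
#' @param assessment a `diag360_assessment` (see [new_assessment()],
#'   [read_assessment()]).
#' @param config a `diag360_config`.
#' @return A `diag360_profile` object.
#' @export
build_profile <- function(assessment, config) {
  stopifnot(inherits(assessment, "diag360_assessment"))
  validate_assessment(assessment, config)

  values <- list()
  # clinical values enter directly
  for (eid in names(assessment$clinical_values)) {
    v <- assessment$clinical_values[[eid]]
    if (!is_absent(v)) values[[eid]] <- v
  }
  # questionnaire responses are scored per instrument
  for (iid in config$instrument_order) {
    resp <- assessment$item_responses[[iid]]
    scores <- score_instrument(iid, resp, config)
    for (eid in names(scores)) {
      if (!is_absent(scores[[eid]])) values[[eid]] <- scores[[eid]]
    }
  }

  element_status <- list()
  for (eid in config$element_order) {
    v <- values[[eid]]
    if (!is.null(v)) {
      element_status[[eid]] <- list(value = v,
                                    status = classify_element(eid, v, config))
    }
  }

  parameter_status <- list()
  for (pid in config$parameter_order) {
    p <- config$parameters[[pid]]
    statuses <- vapply(unlist(p$element_ids), function(eid) {
      es <- element_status[[eid]]
      if (is.null(es)) "gray" else es$status
    }, "")
    parameter_status[[pid]] <- combine_statuses(statuses, config$rules[[pid]])
  }

  new_profile(patient_id = assessment$patient_id,
              timepoint = assessment$timepoint,
              config_id = config$config_id,
              element_status = element_status,
              parameter_status = parameter_status)
}
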