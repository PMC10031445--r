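# Rule configuration: the domain / parameter / element hierarchy, cutoff
# bands, decision rules and instrument definitions. The classification
# engine's behavior is fully determined by this document; cutoffs are
# config data, never code constants, so guideline updates need no code
# change.

CONFIG_SCHEMA_ID <- "diag360/rule-config"
DOMAIN_IDS <- c("body", "thinking_feeling", "behavior", "environment")

#' Load a rule configuration from JSON
#'
#' A rule configuration declares the four diagnostic domains, their
#' parameters (at most six per domain), the measurable elements of each
#' parameter with units, valid ranges and traffic-light cutoff bands, the
#' decision rule combining element statuses into a parameter status, and
#' the questionnaire instrument definitions. The file is validated
#' exhaustively at load; any violation raises an error naming the
#' offending key.
#'
#' @param path path to a JSON rule-config document.
#' @return A validated `diag360_config` object.
#' @seealso [load_reference_config()] for the packaged reference config.
#' @export
load_config <- function(path) {
  raw <- read_json_file(path)
  check_schema(raw, CONFIG_SCHEMA_ID, path = path)
  validate_config(raw)
}

#' Load the packaged reference configuration
#'
#' The reference config models the published tool: 4 domains (body;
#' thinking and feeling; behavior; environment) carrying 21 parameters
#' (5 + 5 + 6 + 5). Blood-pressure and WHO-5 cutoffs follow the printed
#' rules; all other cutoffs are documented Dutch-guideline defaults and
#' are flagged as such in the config itself.
#'
#' @return A validated `diag360_config` object.
#' @export
load_reference_config <- function() {
  load_config(system.file("extdata", "reference_config.json",
                          package = "diag360", mustWork = TRUE))
}

#' Serialize a configuration to canonical JSON
#'
#' @param config a `diag360_config` object.
#' @param path optional output path; when omitted the JSON string is
#'   returned.
#' @return JSON string or `path` invisibly.
#' @export
write_config <- function(config, path = NULL) {
  stopifnot(inherits(config, "diag360_config"))
  canonical_json(config$payload, path)
}

#' @export
print.diag360_config <- function(x, ...) {
  cat(sprintf("<diag360 rule config '%s' (schema %s)>\n",
              x$config_id, x$payload$schema_version))
  for (d in x$domain_order) {
    cat(sprintf("  %-17s %d parameters\n", d,
                length(x$domains[[d]]$parameter_ids)))
  }
  cat(sprintf("  %d parameters, %d elements, %d instruments\n",
              length(x$parameters), length(x$elements), length(x$instruments)))
  invisible(x)
}

# --- validation ------------------------------------------------------------

#' Validate a raw rule-config structure
#'
#' @param raw nested-list structure as parsed from JSON.
#' @return A `diag360_config` with indexed lookup tables.
#' @export
validate_config <- function(raw) {
  fail <- function(...) stop("rule config invalid: ", sprintf(...), call. = FALSE)

  for (key in c("config_id", "domains", "parameters", "elements",
                "decision_rules", "instruments")) {
    if (is.null(raw[[key]])) fail("missing top-level key '%s'", key)
  }

  # domains ---------------------------------------------------------------
  domains <- raw$domains
  dom_ids <- vapply(domains, function(d) d$id %||% NA_character_, "")
  if (anyNA(dom_ids) || anyDuplicated(dom_ids)) {
    fail("domains must carry unique 'id' fields")
  }
  if (length(domains) != 4L || !setequal(dom_ids, DOMAIN_IDS)) {
    fail("exactly the 4 domains {%s} are required, found {%s}",
         paste(DOMAIN_IDS, collapse = ", "), paste(dom_ids, collapse = ", "))
  }

  # parameters ------------------------------------------------------------
  params <- raw$parameters
  par_ids <- vapply(params, function(p) p$id %||% NA_character_, "")
  if (anyNA(par_ids) || anyDuplicated(par_ids)) fail("parameter ids must be unique")
  for (p in params) {
    if (is.null(p$domain_id) || !p$domain_id %in% dom_ids) {
      fail("parameter '%s' references unknown domain '%s'", p$id, p$domain_id %||% "<absent>")
    }
    if (is.null(p$icon_id)) fail("parameter '%s' has no icon_id", p$id)
  }
  for (d in domains) {
    members <- par_ids[vapply(params, function(p) identical(p$domain_id, d$id), TRUE)]
    declared <- unlist(d$parameter_ids)
    if (!identical(sort(members), sort(declared))) {
      fail("domain '%s': parameter_ids do not match parameters declaring domain_id '%s'",
           d$id, d$id)
    }
    if (length(declared) < 1L || length(declared) > 6L) {
      fail("domain '%s' has %d parameters; each domain must have between 1 and 6",
           d$id, length(declared))
    }
  }

  # elements ---------------------------------------------------------------
  elements <- raw$elements
  el_ids <- vapply(elements, function(e) e$id %||% NA_character_, "")
  if (anyNA(el_ids) || anyDuplicated(el_ids)) fail("element ids must be unique")
  for (e in elements) {
    if (is.null(e$parameter_id) || !e$parameter_id %in% par_ids) {
      fail("element '%s' references unknown parameter '%s'", e$id,
           e$parameter_id %||% "<absent>")
    }
    kind <- e$value_kind %||% "<absent>"
    if (!kind %in% c("numeric", "categorical", "derived_score")) {
      fail("element '%s': unknown value_kind '%s'", e$id, kind)
    }
    if (kind == "categorical") {
      if (length(e$categories) < 1L) fail("element '%s': categorical without categories", e$id)
      validate_category_bands(e, fail)
    } else {
      if (length(e$range) != 2L) fail("element '%s': numeric element needs range [lo, hi]", e$id)
      validate_numeric_bands(e, fail)
    }
  }
  # element membership is declared on both sides; they must agree
  for (p in params) {
    owned <- el_ids[vapply(elements, function(e) identical(e$parameter_id, p$id), TRUE)]
    declared <- unlist(p$element_ids)
    if (!identical(sort(owned), sort(declared))) {
      fail("parameter '%s': element_ids disagree with elements declaring parameter_id '%s'",
           p$id, p$id)
    }
    if (length(declared) < 1L) {
      fail("parameter '%s' has no elements; single-score parameters carry their score as one element",
           p$id)
    }
  }

  # decision rules ----------------------------------------------------------
  rules <- raw$decision_rules
  rule_par <- vapply(rules, function(r) r$parameter_id %||% NA_character_, "")
  if (!setequal(rule_par, par_ids) || anyDuplicated(rule_par)) {
    fail("decision_rules must contain exactly one rule per parameter")
  }
  for (r in rules) {
    kind <- r$rule_kind %||% "worst_of"
    if (!kind %in% c("worst_of", "explicit_table")) {
      fail("decision rule for '%s': unknown rule_kind '%s'", r$parameter_id, kind)
    }
    if (kind == "explicit_table") {
      p <- params[[match(r$parameter_id, par_ids)]]
      n <- length(p$element_ids)
      combos <- expand.grid(rep(list(RANKED_STATUSES), n), stringsAsFactors = FALSE)
      keys <- apply(combos, 1L, paste, collapse = "|")
      have <- names(r$explicit_table)
      missing <- setdiff(keys, have)
      if (length(missing) > 0L) {
        fail("explicit_table for '%s' is missing %d status combination(s), e.g. '%s'",
             r$parameter_id, length(missing), missing[[1L]])
      }
      bad <- !unlist(r$explicit_table) %in% RANKED_STATUSES
      if (any(bad)) fail("explicit_table for '%s' maps to a non-ranked status", r$parameter_id)
    }
  }

  # instruments -------------------------------------------------------------
  instruments <- raw$instruments
  inst_ids <- vapply(instruments, function(i) i$instrument_id %||% NA_character_, "")
  if (anyNA(inst_ids) || anyDuplicated(inst_ids)) fail("instrument ids must be unique")
  for (inst in instruments) {
    if (is.null(inst$scoring) || !inst$scoring %in% names(SCORING_PROCEDURES)) {
      fail("instrument '%s': unknown scoring procedure '%s'",
           inst$instrument_id, inst$scoring %||% "<absent>")
    }
    outs <- unlist(inst$output_element_ids)
    if (length(outs) < 1L || !all(outs %in% el_ids)) {
      fail("instrument '%s': output_element_ids must name existing elements",
           inst$instrument_id)
    }
    n_items <- inst$n_items %||% NA
    if (!is_scalar_number(n_items) || n_items < 1L) {
      fail("instrument '%s': n_items missing or invalid", inst$instrument_id)
    }
    scales <- inst$item_scales
    if (length(scales) != n_items) {
      fail("instrument '%s': item_scales must list [min, max] for each of the %d items",
           inst$instrument_id, n_items)
    }
  }
  # every instrument output element belongs to a questionnaire (non-body) parameter
  clinical <- unlist(raw$clinical_element_ids)
  if (is.null(clinical)) fail("missing top-level key 'clinical_element_ids'")
  if (!all(clinical %in% el_ids)) fail("clinical_element_ids names unknown elements")
  scored <- unlist(lapply(instruments, function(i) unlist(i$output_element_ids)))
  uncovered <- setdiff(el_ids, c(clinical, scored))
  if (length(uncovered) > 0L) {
    fail("element(s) neither clinical nor produced by any instrument: %s",
         paste(uncovered, collapse = ", "))
  }

  build_config(raw, dom_ids, par_ids, el_ids, inst_ids)
}

validate_numeric_bands <- function(e, fail) {
  lo <- e$range[[1L]]; hi <- e$range[[2L]]
  if (!is_scalar_number(lo) || !is_scalar_number(hi) || lo >= hi) {
    fail("element '%s': invalid range", e$id)
  }
  bands <- e$bands
  if (length(bands) < 1L) fail("element '%s': no cutoff bands", e$id)
  for (b in bands) {
    if (!(b$status %||% "") %in% RANKED_STATUSES) {
      fail("element '%s': band with invalid status '%s'", e$id, b$status %||% "<absent>")
    }
    if (!is_scalar_number(b$lower) || !is_scalar_number(b$upper) || b$lower >= b$upper) {
      fail("element '%s': band with invalid bounds", e$id)
    }
  }
  ord <- order(vapply(bands, function(b) b$lower, 0))
  bands <- bands[ord]
  first <- bands[[1L]]; last <- bands[[length(bands)]]
  if (first$lower != lo || !isTRUE(first$lower_incl)) {
    fail("element '%s': bands do not cover the lower end of the valid range", e$id)
  }
  if (last$upper != hi || !isTRUE(last$upper_incl)) {
    fail("element '%s': bands do not cover the upper end of the valid range", e$id)
  }
  if (length(bands) > 1L) {
    for (i in seq_len(length(bands) - 1L)) {
      a <- bands[[i]]; b <- bands[[i + 1L]]
      if (a$upper != b$lower) {
        fail("element '%s': gap or overlap between bands at %s", e$id, a$upper)
      }
      if (identical(isTRUE(a$upper_incl), isTRUE(b$lower_incl))) {
        fail("element '%s': boundary %s must belong to exactly one band", e$id, a$upper)
      }
    }
  }
}

validate_category_bands <- function(e, fail) {
  cats <- unlist(e$categories)
  seen <- character(0)
  for (b in e$bands) {
    if (!(b$status %||% "") %in% RANKED_STATUSES) {
      fail("element '%s': band with invalid status", e$id)
    }
    bc <- unlist(b$categories)
    if (length(bc) < 1L || !all(bc %in% cats)) {
      fail("element '%s': band categories outside declared categories", e$id)
    }
    seen <- c(seen, bc)
  }
  if (anyDuplicated(seen) || !setequal(seen, cats)) {
    fail("element '%s': bands must partition the declared categories", e$id)
  }
}

build_config <- function(raw, dom_ids, par_ids, el_ids, inst_ids) {
  cfg <- list(
    config_id = raw$config_id,
    payload = raw,
    domain_order = vapply(raw$domains, function(d) d$id, ""),
    parameter_order = par_ids,
    element_order = el_ids,
    instrument_order = inst_ids,
    domains = stats::setNames(raw$domains, dom_ids),
    parameters = stats::setNames(raw$parameters, par_ids),
    elements = stats::setNames(raw$elements, el_ids),
    instruments = stats::setNames(raw$instruments, inst_ids),
    rules = stats::setNames(raw$decision_rules,
                            vapply(raw$decision_rules, function(r) r$parameter_id, "")),
    clinical_element_ids = unlist(raw$clinical_element_ids)
  )
  class(cfg) <- "diag360_config"
  cfg
}

# lookup helpers (internal) --------------------------------------------------

cfg_element <- function(config, element_id) {
  e <- config$elements[[element_id]]
  if (is.null(e)) stop("unknown element id: ", element_id)
  e
}

cfg_parameter <- function(config, parameter_id) {
  p <- config$parameters[[parameter_id]]
  if (is.null(p)) stop("unknown parameter id: ", parameter_id)
  p
}

cfg_instrument <- function(config, instrument_id) {
  i <- config$instruments[[instrument_id]]
  if (is.null(i)) stop("unknown instrument id: ", instrument_id)
  i
}

# lay display label with fallback to the technical label
cfg_label <- function(def) {
  def$label_lay %||% def$label %||% def$id
}
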