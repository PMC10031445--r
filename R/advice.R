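# Intervention advice: matching orange/red parameters of a profile to an
# intervention catalog filtered by availability context.

CATALOG_SCHEMA_ID <- "diag360/catalog"

#' Closed enumerations for intervention catalogs
#'
#' Seven intervention categories (group-based interventions, events,
#' experts and knowledge centers, apps, devices, programs, knowledge
#' platforms) and three availability classes (proximity to the general
#' practice, within the municipality, nationwide/web-based).
#'
#' @name catalog_enums
NULL

#' @rdname catalog_enums
#' @export
INTERVENTION_CATEGORIES <- c("group_based", "events", "experts_knowledge_centers",
                             "apps", "devices", "programs", "knowledge_platforms")

#' @rdname catalog_enums
#' @export
AVAILABILITY_CLASSES <- c("proximity_to_practice", "within_municipality",
                          "nationwide_web")

#' Load an intervention catalog
#'
#' @param path path to a catalog JSON document, or a CSV file with columns
#'   `id, name, category, availability, target_parameter_ids, description`
#'   (targets separated by `;`).
#' @return A `diag360_catalog` (list of validated entries).
#' @export
load_catalog <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    entries <- lapply(seq_len(nrow(df)), function(i) {
      list(id = df$id[[i]], name = df$name[[i]], category = df$category[[i]],
           availability = df$availability[[i]],
           target_parameter_ids = as.list(strsplit(df$target_parameter_ids[[i]], ";")[[1L]]),
           description = df$description[[i]] %||% "")
    })
  } else {
    raw <- read_json_file(path)
    check_schema(raw, CATALOG_SCHEMA_ID, path = path)
    entries <- raw$interventions %||% list()
  }
  validate_catalog_entries(entries)
}

#' Load the packaged example catalog
#'
#' A synthetic but category-faithful catalog of 27 interventions covering
#' all seven categories and three availability classes (real intervention
#' names and locations are not reproduced).
#'
#' @return A `diag360_catalog` with 27 entries.
#' @export
load_reference_catalog <- function() {
  load_catalog(system.file("extdata", "intervention_catalog.json",
                           package = "diag360", mustWork = TRUE))
}

validate_catalog_entries <- function(entries) {
  for (e in entries) {
    id <- e$id %||% "<missing id>"
    if (!is_scalar_string(e$id) || !is_scalar_string(e$name)) {
      stop("catalog entry ", id, ": id and name are required")
    }
    if (!(e$category %||% "") %in% INTERVENTION_CATEGORIES) {
      stop(sprintf("catalog entry '%s': unknown category '%s'",
                   id, e$category %||% "<absent>"))
    }
    if (!(e$availability %||% "") %in% AVAILABILITY_CLASSES) {
      stop(sprintf("catalog entry '%s': unknown availability '%s'",
                   id, e$availability %||% "<absent>"))
    }
    if (length(e$target_parameter_ids) < 1L) {
      stop(sprintf("catalog entry '%s': no target parameters", id))
    }
  }
  ids <- vapply(entries, function(e) e$id, "")
  if (anyDuplicated(ids)) stop("catalog entry ids must be unique")
  structure(list(interventions = entries), class = "diag360_catalog")
}

#' @export
print.diag360_catalog <- function(x, ...) {
  cat(sprintf("<diag360 intervention catalog: %d entries>\n",
              length(x$interventions)))
  invisible(x)
}

#' @export
length.diag360_catalog <- function(x) length(x$interventions)

#' Match interventions to a profile's flagged parameters
#'
#' Returns every catalog entry that (a) targets at least one parameter
#' classified orange or red in the profile (the middle- and low-ranking
#' scores) and (b) has an availability class in `context`. Entries
#' targeting a red parameter are listed before entries targeting only
#' orange ones; ties keep catalog order. Green and gray parameters
#' trigger nothing. Selection of a single intervention remains a human
#' step during the consultation.
#'
#' @param profile a `diag360_profile`.
#' @param catalog a `diag360_catalog`.
#' @param context character vector of allowed availability classes
#'   (default: all three).
#' @return A `data.frame` with one row per matched entry: `id`, `name`,
#'   `category`, `availability`, `priority` (`"red"`/`"orange"`) and
#'   `matched_parameters` (`;`-separated). Zero rows is a valid result.
#' @export
match_interventions <- function(profile, catalog,
                                context = AVAILABILITY_CLASSES) {
  stopifnot(inherits(profile, "diag360_profile"),
            inherits(catalog, "diag360_catalog"))
  bad <- setdiff(context, AVAILABILITY_CLASSES)
  if (length(bad) > 0L) {
    stop("unknown availability class(es): ", paste(bad, collapse = ", "))
  }
  red <- flagged_parameters(profile, "red")
  orange <- flagged_parameters(profile, "orange")

  rows <- list()
  for (e in catalog$interventions) {
    if (!e$availability %in% context) next
    targets <- unlist(e$target_parameter_ids)
    hit_red <- intersect(targets, red)
    hit_orange <- intersect(targets, orange)
    if (length(hit_red) + length(hit_orange) == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      id = e$id, name = e$name, category = e$category,
      availability = e$availability,
      priority = if (length(hit_red) > 0L) "red" else "orange",
      matched_parameters = paste(c(hit_red, hit_orange), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(id = character(0), name = character(0),
                      category = character(0), availability = character(0),
                      priority = character(0), matched_parameters = character(0),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  # red-targeting first, catalog order within each priority class
  df <- df[order(match(df$priority, c("red", "orange"))), , drop = FALSE]
  row.names(df) <- NULL
  df
}
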