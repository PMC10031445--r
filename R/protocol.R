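# Consultation protocol: the 15-card motivational-interviewing deck used
# to discuss the 360-degree diagnosis, as structured packaged data plus a
# printable markdown rendering.

DECK_SCHEMA_ID <- "diag360/card-deck"

DECK_TITLES <- c(
  "title page", "content", "MI basic attitude", "MI core skills 1",
  "MI core skills 2", "MI core skills 3", "diabetes coaching steps overview",
  "step 1 agenda", "step 2 current situation I", "step 2 current situation II",
  "step 3 motivation I", "step 3 motivation II", "step 4 planning I",
  "step 4 planning II", "step 5 rounding up")

#' Load the 15-card consultation deck
#'
#' The deck is immutable packaged data: title page, content, the
#' motivational-interviewing basic attitude, three MI core-skills cards, a
#' coaching-steps overview and eight step cards (agenda, current
#' situation, motivation, planning, rounding up). Every skill or step card
#' carries a goal, its underlying parts and examples; the final
#' rounding-up card additionally carries the consultation summary fields
#' (current situation, goal parameter, chosen intervention, backup plans,
#' resources). Card bodies are paraphrased placeholders keyed to the
#' printed titles.
#'
#' @return A `diag360_deck`: ordered list of 15 card records.
#' @export
get_card_deck <- function() {
  raw <- read_json_file(system.file("extdata", "card_deck.json",
                                    package = "diag360", mustWork = TRUE))
  check_schema(raw, DECK_SCHEMA_ID, path = "card_deck.json")
  cards <- raw$cards
  if (length(cards) != 15L) stop("card deck must contain exactly 15 cards")
  titles <- vapply(cards, function(c) c$title, "")
  if (!identical(titles, DECK_TITLES)) {
    stop("card deck titles or order do not match the protocol")
  }
  for (c in cards) {
    if (!c$kind %in% c("front_matter", "mi_skill", "step")) {
      stop("card ", c$index, ": unknown kind '", c$kind, "'")
    }
    if (c$kind %in% c("mi_skill", "step")) {
      if (!nzchar(c$goal %||% "") || length(c$parts) < 1L || length(c$examples) < 1L) {
        stop("card '", c$title, "' must carry goal, parts and examples")
      }
    }
  }
  structure(list(cards = cards), class = "diag360_deck")
}

#' @export
print.diag360_deck <- function(x, ...) {
  cat("<diag360 consultation card deck: 15 cards>\n")
  invisible(x)
}

#' Render the consultation deck to a printable markdown document
#'
#' One section per card. When a profile is supplied, the step-1 agenda
#' section embeds the list of orange/red parameters as discussion points
#' (or an explicit sentence that no parameters are flagged).
#'
#' @param deck a `diag360_deck` from [get_card_deck()].
#' @param profile optional `diag360_profile` whose flagged parameters
#'   populate the agenda.
#' @param config optional `diag360_config` used for display labels when a
#'   profile is supplied.
#' @return Markdown document as a character string.
#' @export
render_protocol <- function(deck, profile = NULL, config = NULL) {
  stopifnot(inherits(deck, "diag360_deck"))
  out <- c("# 360-degree diagnosis consultation protocol", "")
  for (card in deck$cards) {
    out <- c(out, sprintf("## %d. %s", card$index, card$title), "")
    if (nzchar(card$goal %||% "")) {
      out <- c(out, paste0("**Goal.** ", card$goal), "")
    }
    if (length(card$parts) > 0L) {
      out <- c(out, "**Parts:**", paste0("- ", unlist(card$parts)), "")
    }
    if (length(card$examples) > 0L) {
      out <- c(out, "**Examples:**", paste0("- ", unlist(card$examples)), "")
    }
    if (identical(card$title, "step 1 agenda") && !is.null(profile)) {
      flagged <- flagged_parameters(profile)
      out <- c(out, "**Agenda — parameters flagged for discussion:**")
      if (length(flagged) == 0L) {
        out <- c(out, "- No parameters are flagged; all measured scores are in the green range.")
      } else {
        labels <- vapply(flagged, function(pid) {
          lab <- if (!is.null(config)) cfg_label(config$parameters[[pid]]) else pid
          sprintf("%s (%s)", lab, profile$parameter_status[[pid]])
        }, "")
        out <- c(out, paste0("- ", labels))
      }
      out <- c(out, "")
    }
    if (identical(card$title, "step 5 rounding up")) {
      fields <- unlist(card$summary_fields)
      out <- c(out, "**Consultation summary fields:**",
               paste0("- ", fields, ": ____________________"), "")
    }
  }
  paste0(paste(out, collapse = "\n"), "\n")
}
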