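# Questionnaire scoring: converts raw item responses into element-level
# scores for the thinking-and-feeling, behavior and environment domains.
# All scorers are pure; a missing required item yields NA ("score
# unavailable", mapped to gray downstream), never a silent number.
# Malformed input (wrong item count, out-of-range response) is an error.

# Registry of named scoring procedures referenced by instrument configs.
# Each entry: function(items, inst) -> named list element_id -> score/NA.
SCORING_PROCEDURES <- list(
  who5 = function(items, inst) {
    list_one(inst, score_who5_items(items))
  },
  sum = function(items, inst) {
    list_one(inst, if (anyNA(items)) NA_real_ else sum(items))
  },
  sum_reverse = function(items, inst) {
    if (anyNA(items)) return(list_one(inst, NA_real_))
    rev_idx <- unlist(inst$reverse_items)
    item_max <- vapply(inst$item_scales, function(s) s[[2L]], 0)
    eff <- items
    eff[rev_idx] <- item_max[rev_idx] - items[rev_idx]
    list_one(inst, sum(eff))
  },
  direct = function(items, inst) {
    outs <- unlist(inst$output_element_ids)
    stats::setNames(as.list(as.numeric(items)), outs)
  },
  alcohol_fq = function(items, inst) {
    score_alcohol_items(items, inst)
  },
  smoking = function(items, inst) {
    outs <- unlist(inst$output_element_ids)
    smokes <- items[[1L]]
    if (is.na(smokes)) {
      return(stats::setNames(list(NA_real_, NA_real_), outs))
    }
    if (smokes == 0) {
      # non-smoker routing: no further answers required
      return(stats::setNames(list(0, 0), outs))
    }
    stats::setNames(list(as.numeric(items[[2L]]), as.numeric(items[[3L]])), outs)
  },
  squash = function(items, inst) {
    # items are (days, minutes) pairs per activity block; an absent block
    # counts as 0 minutes, but a fully absent instrument is unavailable.
    if (all(is.na(items))) return(list_one(inst, NA_real_))
    items[is.na(items)] <- 0
    n_blocks <- length(items) %/% 2L
    days <- items[seq(1L, by = 2L, length.out = n_blocks)]
    mins <- items[seq(2L, by = 2L, length.out = n_blocks)]
    list_one(inst, sum(days * mins))
  },
  sitting = function(items, inst) {
    # Marshall-style weekday/weekend sitting hours -> average hours/day
    if (anyNA(items)) return(list_one(inst, NA_real_))
    list_one(inst, (5 * items[[1L]] + 2 * items[[2L]]) / 7)
  },
  dsmq = function(items, inst) {
    # two 4-item subscales on a 0..3 scale, each transformed to 0..10
    outs <- unlist(inst$output_element_ids)
    sub <- function(idx) {
      x <- items[idx]
      if (anyNA(x)) NA_real_ else sum(x) / (3 * length(x)) * 10
    }
    stats::setNames(list(sub(1:4), sub(5:8)), outs)
  }
)

list_one <- function(inst, value) {
  stats::setNames(list(value), unlist(inst$output_element_ids)[[1L]])
}

#' Score the WHO-5 Well-being Index
#'
#' The five items are each answered on a 0..5 scale; the well-being score
#' is four times the raw sum, giving a percentage scale from 0 (absence of
#' well-being) to 100 (maximum well-being).
#'
#' @param items numeric vector of exactly 5 item responses in 0..5; `NA`
#'   marks an unanswered item.
#' @return Integer score in 0..100, or `NA` when any item is unanswered
#'   ("score unavailable"; callers map this to gray).
#' @examples
#' score_who5(c(5, 5, 5, 5, 5)) # 100
#' score_who5(c(3, 2, 3, 2, 2)) # 48
#' @export
score_who5 <- function(items) {
  if (length(items) != 5L || !is.numeric(items)) {
    stop("WHO-5 requires exactly 5 numeric items")
  }
  ok <- is.na(items) | (items >= 0 & items <= 5 & items == round(items))
  if (!all(ok)) {
    stop("WHO-5 item(s) out of range 0..5: ", paste(items[!ok], collapse = ", "))
  }
  score_who5_items(items)
}

score_who5_items <- function(items) {
  if (anyNA(items)) NA_real_ else 4 * sum(items)
}

#' Score the five-question alcohol frequency-quantity instrument
#'
#' Item order: `drinks` (0 = abstainer, 1 = drinks alcohol),
#' `weekday_days` (0..5 drinking days Mon-Fri), `glasses_weekday`
#' (glasses per weekday drinking day), `weekend_days` (0..2),
#' `glasses_weekend`, `binge_freq` (0 = never .. 4 = (almost) daily
#' episodes of at least `binge_threshold` glasses).
#'
#' The abstinence answer auto-routes: it forces both outputs to zero
#' without requiring any further answers. Average consumption is
#' `(weekday glasses x weekday days + weekend glasses x weekend days) / 7`.
#' Binge frequency is the stated episode-frequency answer, floored at
#' "weekly" whenever the reported glasses per occasion already reach the
#' binge threshold on a drinking day.
#'
#' @param responses numeric vector of 6 responses (see above); `NA` marks
#'   unanswered.
#' @param binge_threshold glasses per occasion counting as binge drinking
#'   (default 6, a common Dutch heavy-drinking definition).
#' @return Named list with `avg_glasses_per_day` and `binge_freq`
#'   (either may be `NA` when required answers are missing).
#' @examples
#' score_alcohol(c(0, NA, NA, NA, NA, NA)) # abstainer -> 0 / 0
#' score_alcohol(c(1, 5, 2, 2, 2, 0))      # 2 glasses every day -> 2.0
#' @export
score_alcohol <- function(responses, binge_threshold = 6) {
  if (is.logical(responses) && all(is.na(responses))) {
    responses <- as.numeric(responses)
  }
  if (length(responses) != 6L || !is.numeric(responses)) {
    stop("alcohol instrument requires exactly 6 numeric responses")
  }
  inst <- list(output_element_ids = list("avg_glasses_per_day", "binge_freq"),
               binge_threshold = binge_threshold)
  score_alcohol_items(responses, inst)
}

score_alcohol_items <- function(items, inst) {
  outs <- unlist(inst$output_element_ids)
  thr <- inst$binge_threshold %||% 6
  drinks <- items[[1L]]
  if (is.na(drinks)) {
    return(stats::setNames(list(NA_real_, NA_real_), outs))
  }
  if (drinks == 0) {
    return(stats::setNames(list(0, 0), outs))
  }
  wd_days <- items[[2L]]; wd_gl <- items[[3L]]
  we_days <- items[[4L]]; we_gl <- items[[5L]]
  reported <- items[[6L]]
  if (anyNA(c(wd_days, wd_gl, we_days, we_gl))) {
    avg <- NA_real_
    implied <- NA_real_
  } else {
    avg <- (wd_days * wd_gl + we_days * we_gl) / 7
    implied <- if ((wd_days > 0 && wd_gl >= thr) || (we_days > 0 && we_gl >= thr)) 3 else 0
  }
  binge <- if (is.na(reported)) implied else max(reported, implied, na.rm = TRUE)
  stats::setNames(list(avg, binge), outs)
}

#' Score one instrument's responses into element scores
#'
#' Dispatches to the named scoring procedure declared in the instrument
#' definition (WHO-5 percentage, plain and reverse-keyed sums, direct item
#' mapping, alcohol frequency-quantity, smoking with non-smoker routing,
#' SQUASH-style activity minutes, sitting hours, DSMQ subscales).
#'
#' @param instrument_id id of an instrument declared in `config`.
#' @param responses numeric vector of raw item responses in the declared
#'   item order; `NA`/`NULL` entries mark unanswered items. May also be a
#'   list (JSON array with nulls).
#' @param config a `diag360_config`.
#' @return Named list mapping each output element id to its score, with
#'   `NA` for unavailable scores.
#' @export
score_instrument <- function(instrument_id, responses, config) {
  inst <- cfg_instrument(config, instrument_id)
  items <- normalize_items(responses, inst)
  SCORING_PROCEDURES[[inst$scoring]](items, inst)
}

# Coerce a response list/vector to a validated numeric vector of length
# n_items with NA for unanswered; range-check every answered item.
normalize_items <- function(responses, inst) {
  n <- inst$n_items
  if (is.null(responses)) {
    return(rep(NA_real_, n))
  }
  if (is.list(responses)) {
    responses <- vapply(responses, function(x) {
      if (is_absent(x)) NA_real_
      else if (is_scalar_number(x)) as.numeric(x)
      else NA_real_ * stop_nonnumeric(inst$instrument_id, x)
    }, 0)
  }
  if (is.logical(responses) && all(is.na(responses))) {
    responses <- as.numeric(responses)  # plain NA vectors mean "unanswered"
  }
  if (!is.numeric(responses)) {
    stop(sprintf("instrument '%s': responses must be numeric", inst$instrument_id))
  }
  if (length(responses) != n) {
    stop(sprintf("instrument '%s': expected %d item responses, got %d",
                 inst$instrument_id, n, length(responses)))
  }
  for (i in seq_len(n)) {
    v <- responses[[i]]
    if (is.na(v)) next
    sc <- inst$item_scales[[i]]
    if (v < sc[[1L]] || v > sc[[2L]]) {
      stop(sprintf("instrument '%s': item %d response %s outside scale [%s, %s]",
                   inst$instrument_id, i, v, sc[[1L]], sc[[2L]]))
    }
  }
  as.numeric(responses)
}

stop_nonnumeric <- function(id, x) {
  stop(sprintf("instrument '%s': non-numeric item response %s", id, deparse(x)))
}
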