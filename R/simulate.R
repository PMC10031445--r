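# Synthetic patients: seeded generation of assessment records with
# configurable per-parameter traffic-light prevalence and missingness.
# The generator inverse-samples: it first draws each parameter's target
# status from the prevalence, then samples element values (or item
# responses, for questionnaire parameters) that classify into exactly
# that status. This guarantees exact prevalence control for testing and
# is deliberately non-epidemiological: no correlation structure between
# domains is emulated.

#' Construct a simulation specification
#'
#' @param n_patients number of patients to generate.
#' @param seed integer seed; all randomness derives from it. Patient `i`
#'   uses its own stream seeded from `seed + i`, so changing `n_patients`
#'   never changes the first patients' records.
#' @param prevalence default per-parameter status prevalence, a named
#'   numeric vector `c(green=, orange=, red=)` summing to 1 (tolerance
#'   1e-9). For parameters whose cutoff bands have no orange status (the
#'   two-color scales), the default's orange mass is folded into green.
#' @param parameter_prevalence named list of per-parameter prevalence
#'   overrides (same format). An explicit override demanding an
#'   unreachable status is a validation error.
#' @param missing_rate probability that an instrument's responses (or a
#'   clinical element's value) are absent: a scalar applied everywhere, or
#'   a named vector keyed by instrument id / clinical element id with a
#'   `.default` fallback.
#' @param timepoint ISO date stamped on the generated assessments.
#' @return A `diag360_simspec`.
#' @export
simulation_spec <- function(n_patients, seed,
                            prevalence = c(green = 0.6, orange = 0.25, red = 0.15),
                            parameter_prevalence = list(),
                            missing_rate = 0,
                            timepoint = "2026-01-01") {
  if (!is_scalar_number(n_patients) || n_patients < 1) {
    stop("n_patients must be a positive number")
  }
  if (!is_scalar_number(seed)) stop("seed must be a number")
  check_prev <- function(p, label) {
    if (!is.numeric(p) || length(p) != 3L ||
        !setequal(names(p), c("green", "orange", "red"))) {
      stop(label, ": prevalence must be c(green=, orange=, red=)")
    }
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop(label, ": prevalences must be non-negative and sum to 1 (tolerance 1e-9)")
    }
    p[c("green", "orange", "red")]
  }
  prevalence <- check_prev(prevalence, "default prevalence")
  parameter_prevalence <- lapply(stats::setNames(
    names(parameter_prevalence), names(parameter_prevalence)),
    function(pid) check_prev(parameter_prevalence[[pid]], pid))
  rates <- unlist(missing_rate)
  if (!is.numeric(rates) || any(rates < 0 | rates > 1)) {
    stop("missing_rate values must lie in [0, 1]")
  }
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 prevalence = prevalence,
                 parameter_prevalence = parameter_prevalence,
                 missing_rate = missing_rate, timepoint = timepoint),
            class = "diag360_simspec")
}

# statuses reachable for a parameter: a band of that color exists on some
# element
reachable_statuses <- function(param, config) {
  out <- character(0)
  for (eid in unlist(param$element_ids)) {
    e <- config$elements[[eid]]
    out <- union(out, vapply(e$bands, function(b) b$status, ""))
  }
  out
}

# effective per-parameter prevalence table; errors on explicit impossible
# demands, folds impossible default mass into green
effective_prevalence <- function(spec, config) {
  res <- list()
  for (pid in config$parameter_order) {
    p <- config$parameters[[pid]]
    reach <- reachable_statuses(p, config)
    explicit <- pid %in% names(spec$parameter_prevalence)
    prev <- if (explicit) spec$parameter_prevalence[[pid]] else spec$prevalence
    for (st in c("orange", "red")) {
      if (prev[[st]] > 0 && !st %in% reach) {
        if (explicit) {
          stop(sprintf("parameter '%s': target status '%s' is unreachable under the config's bands",
                       pid, st))
        }
        prev[["green"]] <- prev[["green"]] + prev[[st]]
        prev[[st]] <- 0
      }
    }
    res[[pid]] <- prev
  }
  res
}

missing_rate_for <- function(spec, key) {
  mr <- unlist(spec$missing_rate)
  if (length(mr) == 1L && is.null(names(mr))) return(as.numeric(mr))
  if (key %in% names(mr)) return(as.numeric(mr[[key]]))
  if (".default" %in% names(mr)) return(as.numeric(mr[[".default"]]))
  0
}

#' Generate synthetic patient assessments
#'
#' For each patient and parameter a target status is drawn from the
#' prevalence; element values (for clinical parameters) or item responses
#' (for questionnaire parameters) are then sampled so the classified
#' status equals the target exactly. Missingness is applied independently
#' per instrument / clinical element afterwards. Fully reproducible from
#' the spec's seed.
#'
#' @param spec a `diag360_simspec`.
#' @param config a `diag360_config`.
#' @return A list of `diag360_assessment` objects, with an attribute
#'   `target_status`: an `n x parameters` character matrix of the drawn
#'   targets (before missingness).
#' @export
generate_patients <- function(spec, config) {
  stopifnot(inherits(spec, "diag360_simspec"), inherits(config, "diag360_config"))
  prev <- effective_prevalence(spec, config)
  inst_for_param <- instrument_parameter_map(config)

  n <- spec$n_patients
  pids <- config$parameter_order
  targets <- matrix(NA_character_, nrow = n, ncol = length(pids),
                    dimnames = list(NULL, pids))
  patients <- vector("list", n)

  for (i in seq_len(n)) {
    set.seed((spec$seed + i) %% .Machine$integer.max)
    clinical <- list()
    responses <- list()
    for (pid in pids) {
      p <- config$parameters[[pid]]
      status <- sample(c("green", "orange", "red"), 1L, prob = prev[[pid]])
      targets[i, pid] <- status
      el_targets <- assign_element_targets(p, status, config)
      iid <- inst_for_param[[pid]]
      if (is.null(iid)) {
        for (eid in names(el_targets)) {
          clinical[[eid]] <- sample_element_value(config$elements[[eid]],
                                                 el_targets[[eid]])
        }
      } else {
        responses[[iid]] <- sample_instrument_items(config$instruments[[iid]],
                                                    el_targets, config)
      }
    }
    # missingness: drop whole instruments / single clinical elements
    for (iid in names(responses)) {
      if (stats::runif(1) < missing_rate_for(spec, iid)) {
        responses[[iid]] <- rep(NA_real_, config$instruments[[iid]]$n_items)
      }
    }
    for (eid in names(clinical)) {
      if (stats::runif(1) < missing_rate_for(spec, eid)) {
        clinical[[eid]] <- NA
      }
    }
    patients[[i]] <- new_assessment(
      patient_id = sprintf("sim-%05d", i),
      timepoint = spec$timepoint,
      clinical_values = clinical,
      item_responses = responses)
  }
  rownames(targets) <- vapply(patients, function(p) p$patient_id, "")
  attr(patients, "target_status") <- targets
  patients
}

# maps each questionnaire parameter to the single instrument producing its
# elements; clinical parameters map to NULL
instrument_parameter_map <- function(config) {
  map <- list()
  for (iid in config$instrument_order) {
    outs <- unlist(config$instruments[[iid]]$output_element_ids)
    owners <- unique(vapply(outs, function(eid) config$elements[[eid]]$parameter_id, ""))
    if (length(owners) != 1L) {
      stop(sprintf("instrument '%s' feeds multiple parameters; the generator requires one instrument per parameter",
                   iid))
    }
    if (!is.null(map[[owners]])) {
      stop(sprintf("parameter '%s' is fed by multiple instruments", owners))
    }
    map[[owners]] <- iid
  }
  map
}

# pick per-element target statuses realizing a parameter target under the
# worst-of rule: the carrier element gets the target band, all others green
assign_element_targets <- function(param, status, config) {
  eids <- unlist(param$element_ids)
  out <- stats::setNames(rep("green", length(eids)), eids)
  if (status == "green") return(out)
  eligible <- eids[vapply(eids, function(eid) {
    any(vapply(config$elements[[eid]]$bands, function(b) b$status == status, TRUE))
  }, TRUE)]
  if (length(eligible) == 0L) {
    stop(sprintf("parameter '%s': no element has a '%s' band", param$id, status))
  }
  carrier <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
  out[[carrier]] <- status
  out
}

band_for_status <- function(e, status) {
  for (b in e$bands) if (b$status == status) return(b)
  stop(sprintf("element '%s' has no '%s' band", e$id, status))
}

# uniform draw inside a band; integer elements draw integer values
sample_element_value <- function(e, status) {
  if (identical(e$value_kind, "categorical")) {
    b <- band_for_status(e, status)
    cats <- unlist(b$categories)
    return(cats[[sample.int(length(cats), 1L)]])
  }
  b <- band_for_status(e, status)
  if (isTRUE(e$integer)) {
    vals <- integers_in_band(b)
    if (length(vals) == 0L) {
      stop(sprintf("element '%s': no integer value inside its '%s' band", e$id, status))
    }
    return(vals[[sample.int(length(vals), 1L)]])
  }
  repeat {
    x <- stats::runif(1L, b$lower, b$upper)
    in_lo <- x > b$lower || isTRUE(b$lower_incl)
    in_hi <- x < b$upper || isTRUE(b$upper_incl)
    if (in_lo && in_hi) return(x)
  }
}

integers_in_band <- function(b, limit = NULL) {
  lo <- ceiling(b$lower); hi <- floor(b$upper)
  if (lo == b$lower && !isTRUE(b$lower_incl)) lo <- lo + 1L
  if (hi == b$upper && !isTRUE(b$upper_incl)) hi <- hi - 1L
  if (!is.null(limit)) hi <- min(hi, limit)
  if (lo > hi) return(numeric(0))
  seq(lo, hi)
}

value_in_band <- function(v, b) {
  (v > b$lower || (isTRUE(b$lower_incl) && v == b$lower)) &&
    (v < b$upper || (isTRUE(b$upper_incl) && v == b$upper))
}

# distribute a target sum uniformly-ish over n items each in 0..item_max
compose_sum <- function(total, n, item_max) {
  items <- numeric(n)
  remaining <- total
  for (k in seq_len(n)) {
    slots_left <- n - k
    lo <- max(0, remaining - slots_left * item_max)
    hi <- min(item_max, remaining)
    items[[k]] <- lo + sample.int(hi - lo + 1L, 1L) - 1L
    remaining <- remaining - items[[k]]
  }
  items
}

# item responses for one instrument realizing the element targets; the
# sampler is keyed by the instrument's scoring procedure
sample_instrument_items <- function(inst, el_targets, config) {
  outs <- unlist(inst$output_element_ids)
  item_max <- vapply(inst$item_scales, function(s) s[[2L]], 0)
  scoring <- inst$scoring

  if (scoring %in% c("who5", "sum", "sum_reverse")) {
    e <- config$elements[[outs[[1L]]]]
    band <- band_for_status(e, el_targets[[outs[[1L]]]])
    transform <- switch(scoring, who5 = function(s) 4 * s, function(s) s)
    sums <- 0:sum(item_max)
    feasible <- sums[vapply(sums, function(s) value_in_band(transform(s), band), TRUE)]
    if (length(feasible) == 0L) {
      stop(sprintf("instrument '%s': no attainable sum lands in the target band", inst$instrument_id))
    }
    s <- feasible[[sample.int(length(feasible), 1L)]]
    items <- compose_sum(s, inst$n_items, item_max[[1L]])
    if (scoring == "sum_reverse") {
      rev_idx <- unlist(inst$reverse_items)
      items[rev_idx] <- item_max[rev_idx] - items[rev_idx]
    }
    return(items)
  }

  if (scoring == "direct") {
    items <- numeric(length(outs))
    for (k in seq_along(outs)) {
      items[[k]] <- sample_element_value(config$elements[[outs[[k]]]],
                                         el_targets[[outs[[k]]]])
    }
    return(items)
  }

  if (scoring == "dsmq") {
    items <- numeric(8L)
    for (sub in 1:2) {
      e <- config$elements[[outs[[sub]]]]
      band <- band_for_status(e, el_targets[[outs[[sub]]]])
      sums <- 0:12
      feasible <- sums[vapply(sums, function(s) value_in_band(s / 12 * 10, band), TRUE)]
      if (length(feasible) == 0L) {
        stop("dsmq: no attainable subscale sum lands in the target band")
      }
      s <- feasible[[sample.int(length(feasible), 1L)]]
      idx <- if (sub == 1L) 1:4 else 5:8
      items[idx] <- compose_sum(s, 4L, 3)
    }
    return(items)
  }

  if (scoring == "sitting") {
    e <- config$elements[[outs[[1L]]]]
    h <- sample_element_value(e, el_targets[[outs[[1L]]]])
    return(c(h, h)) # weekday = weekend = target hours/day
  }

  if (scoring == "squash") {
    e <- config$elements[[outs[[1L]]]]
    b <- band_for_status(e, el_targets[[outs[[1L]]]])
    # spread the weekly minutes over single-day activity blocks, <= block
    # max each; the draw is capped at that distribution capacity
    n_blocks <- inst$n_items %/% 2L
    block_max <- item_max[[2L]]
    minutes <- integers_in_band(b, limit = n_blocks * block_max)
    m <- minutes[[sample.int(length(minutes), 1L)]]
    items <- numeric(inst$n_items)
    remaining <- m
    for (blk in seq_len(n_blocks)) {
      take <- min(remaining, block_max)
      items[[2L * blk - 1L]] <- if (take > 0) 1 else 0  # days
      items[[2L * blk]] <- take                          # minutes
      remaining <- remaining - take
    }
    if (remaining > 0) stop("squash: target minutes exceed instrument capacity")
    return(items)
  }

  if (scoring == "alcohol_fq") {
    thr <- inst$binge_threshold %||% 6
    avg_e <- config$elements[["avg_glasses_per_day"]]
    binge_e <- config$elements[["binge_freq"]]
    avg_band <- band_for_status(avg_e, el_targets[["avg_glasses_per_day"]])
    binge_band <- band_for_status(binge_e, el_targets[["binge_freq"]])
    # daily glasses x drunk on all 7 days gives avg = x; cap below the
    # binge threshold so the derived binge flag never overrides the target
    xs <- integers_in_band(avg_band, limit = thr - 1)
    if (length(xs) == 0L) {
      stop("alcohol: no integer daily-glass count realizes the target band below the binge threshold")
    }
    x <- xs[[sample.int(length(xs), 1L)]]
    bf <- integers_in_band(binge_band)
    binge <- bf[[sample.int(length(bf), 1L)]]
    if (x == 0 && binge == 0) {
      return(c(0, NA, NA, NA, NA, NA)) # abstainer routing
    }
    return(c(1, 5, x, 2, x, binge))
  }

  if (scoring == "smoking") {
    cpd_e <- config$elements[["cigarettes_per_day"]]
    crav_e <- config$elements[["craving"]]
    cpd <- sample_element_value(cpd_e, el_targets[["cigarettes_per_day"]])
    crav <- sample_element_value(crav_e, el_targets[["craving"]])
    if (cpd == 0 && crav == 0) {
      return(c(0, NA, NA)) # non-smoker routing
    }
    return(c(1, cpd, crav))
  }

  stop("no synthetic-item sampler for scoring procedure: ", scoring)
}

#' @export
print.diag360_simspec <- function(x, ...) {
  cat(sprintf("<diag360 simulation spec: n=%d, seed=%d>\n", x$n_patients, x$seed))
  cat(sprintf("  default prevalence: green %.2f / orange %.2f / red %.2f\n",
              x$prevalence[["green"]], x$prevalence[["orange"]], x$prevalence[["red"]]))
  invisible(x)
}
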