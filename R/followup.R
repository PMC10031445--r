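# Follow-up: comparing two diagnosis profiles of the same patient
# (baseline and the second diagnosis ~3 months later) and reporting
# per-parameter transitions.

TRANSITIONS_SCHEMA_ID <- "diag360/transitions"

TRANSITION_KINDS <- c("improved", "worsened", "unchanged", "newly_measured",
                      "no_longer_measured", "still_unmeasured")

#' Compare a baseline and a follow-up profile
#'
#' Transitions are computed at parameter level for every parameter of the
#' shared config: a severity decrease is `improved`, an increase
#' `worsened`, equal ranked statuses `unchanged`; gray-to-ranked is
#' `newly_measured`, ranked-to-gray `no_longer_measured`, gray-to-gray
#' `still_unmeasured`. Profiles built against different rule-config
#' versions are not comparable and raise an error. No minimum interval is
#' enforced (the roughly three-month follow-up is procedural guidance).
#'
#' @param p0 baseline `diag360_profile`.
#' @param p1 follow-up `diag360_profile`; same patient and config, with a
#'   timepoint not earlier than the baseline's.
#' @return A `diag360_transitions` object: data frame of transitions plus
#'   patient/timepoint metadata.
#' @export
compare_profiles <- function(p0, p1) {
  stopifnot(inherits(p0, "diag360_profile"), inherits(p1, "diag360_profile"))
  if (!identical(p0$patient_id, p1$patient_id)) {
    stop("profiles belong to different patients: ",
         p0$patient_id, " vs ", p1$patient_id)
  }
  if (!identical(p0$config_id, p1$config_id)) {
    stop(sprintf("config versions differ ('%s' vs '%s'); statuses are not comparable",
                 p0$config_id, p1$config_id))
  }
  if (!setequal(names(p0$parameter_status), names(p1$parameter_status))) {
    stop("profiles cover different parameter sets")
  }
  if (as.Date(p1$timepoint) < as.Date(p0$timepoint)) {
    stop("follow-up timepoint precedes the baseline")
  }

  pids <- names(p0$parameter_status)
  trans <- vapply(pids, function(pid) {
    transition_kind(p0$parameter_status[[pid]], p1$parameter_status[[pid]])
  }, "")
  report <- list(
    patient_id = p0$patient_id,
    timepoints = c(t0 = p0$timepoint, t1 = p1$timepoint),
    config_id = p0$config_id,
    transitions = data.frame(
      parameter_id = pids,
      status_t0 = unlist(p0$parameter_status[pids]),
      status_t1 = unlist(p1$parameter_status[pids]),
      transition = trans,
      stringsAsFactors = FALSE, row.names = NULL)
  )
  class(report) <- "diag360_transitions"
  report
}

transition_kind <- function(s0, s1) {
  g0 <- s0 == "gray"; g1 <- s1 == "gray"
  if (g0 && g1) return("still_unmeasured")
  if (g0) return("newly_measured")
  if (g1) return("no_longer_measured")
  r0 <- status_rank(s0); r1 <- status_rank(s1)
  if (r1 < r0) "improved" else if (r1 > r0) "worsened" else "unchanged"
}

#' Serialize a transition report to canonical JSON
#'
#' @param report a `diag360_transitions`.
#' @param path optional output path.
#' @return JSON string, or `path` invisibly.
#' @export
write_transitions <- function(report, path = NULL) {
  stopifnot(inherits(report, "diag360_transitions"))
  tr <- report$transitions
  payload <- list(
    schema_id = TRANSITIONS_SCHEMA_ID,
    schema_version = "1.0",
    patient_id = report$patient_id,
    timepoints = list(t0 = unname(report$timepoints[["t0"]]),
                      t1 = unname(report$timepoints[["t1"]])),
    config_id = report$config_id,
    transitions = lapply(seq_len(nrow(tr)), function(i) {
      list(parameter_id = tr$parameter_id[[i]],
           status_t0 = tr$status_t0[[i]],
           status_t1 = tr$status_t1[[i]],
           transition = tr$transition[[i]])
    })
  )
  canonical_json(payload, path)
}

#' @export
print.diag360_transitions <- function(x, ...) {
  cat(sprintf("<diag360 transitions: patient '%s', %s -> %s>\n",
              x$patient_id, x$timepoints[["t0"]], x$timepoints[["t1"]]))
  print(table(x$transitions$transition))
  invisible(x)
}
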