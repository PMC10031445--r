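# Shared fixtures, built in code. `ref_cfg` is loaded once per test run.

ref_cfg <- load_reference_config()

# An assessment in which every element value sits inside a green band.
healthy_assessment <- function(patient_id = "healthy-001",
                               timepoint = "2026-01-10") {
  new_assessment(
    patient_id = patient_id, timepoint = timepoint,
    clinical_values = list(
      hba1c = 45, fasting_glucose = 5.5, glucose_2h = 6, systolic = 120,
      diastolic = 80, hdl = 1.4, ldl = 2.0, total_cholesterol = 4.2,
      chol_hdl_ratio = 3.0, triglycerides = 1.0, bmi = 23,
      waist_circumference = 85, waist_hip_ratio = 0.85, egfr = 90,
      albuminuria_stage = "A1"),
    item_responses = list(
      who5 = c(4, 4, 4, 4, 4),
      pss = c(1, 1, 1, 3, 3, 1, 3, 3, 1, 1),  # reverse-keyed items at 3 -> low stress
      paid5 = c(1, 1, 1, 1, 1),
      alcohol = c(0, NA, NA, NA, NA, NA),      # abstainer routing
      smoking = c(0, NA, NA),                  # non-smoker routing
      eating = c(2, 250, 0, 0, 0),
      squash_activity = c(0, 0, 0, 0, 0, 0, 5, 40, 0, 0),
      sedentary = c(6, 7),
      dsmq = rep(3, 8),
      perceived_health = 1, pain = 1,
      family = c(1, 1), loneliness = 1, work = 1, income = 1,
      housing = c(1, 1)))
}

demo_assessment <- function() {
  read_assessment(system.file("extdata", "demo_assessment.json",
                              package = "diag360"), ref_cfg)
}

# Independent banding/worst-of oracle working directly off the raw config
# payload (no classify_element / combine_statuses involved).
oracle_band_status <- function(payload_element, value) {
  if (is.null(value) || (length(value) == 1 && is.na(value))) return("gray")
  if (identical(payload_element$value_kind, "categorical")) {
    for (b in payload_element$bands) {
      if (value %in% unlist(b$categories)) return(b$status)
    }
    stop("oracle: category not found")
  }
  for (b in payload_element$bands) {
    lo_ok <- if (isTRUE(b$lower_incl)) value >= b$lower else value > b$lower
    hi_ok <- if (isTRUE(b$upper_incl)) value <= b$upper else value < b$upper
    if (lo_ok && hi_ok) return(b$status)
  }
  stop("oracle: no band")
}

oracle_worst_of <- function(statuses) {
  if (any(statuses == "gray")) return("gray")
  sev <- c(green = 0, orange = 1, red = 2)
  statuses[[which.max(sev[statuses])]]
}
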