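# Classification: cutoff banding, decision rules, profile building.

test_that("systolic banding follows the printed cutoffs (left-closed)", {
  expect_identical(classify_element("systolic", 135, ref_cfg), "green")
  expect_identical(classify_element("systolic", 150, ref_cfg), "orange")
  expect_identical(classify_element("systolic", 165, ref_cfg), "red")
  expect_identical(classify_element("systolic", 140, ref_cfg), "orange")
  expect_identical(classify_element("systolic", 160, ref_cfg), "red")
  expect_identical(classify_element("systolic", NULL, ref_cfg), "gray")
  expect_error(classify_element("systolic", 500, ref_cfg), "outside valid range")
})

test_that("combine_statuses implements worst-of with gray propagation", {
  expect_identical(combine_statuses(c("green", "green")), "green")
  expect_identical(combine_statuses(c("orange", "red")), "red")
  expect_identical(combine_statuses(c("green", "orange")), "orange")
  expect_identical(combine_statuses(c("gray", "green")), "gray")
  expect_identical(combine_statuses("red"), "red")
  expect_error(combine_statuses(character(0)), "empty")
  # explicit tables must cover the tuple
  rule <- list(rule_kind = "explicit_table",
               explicit_table = list("green|green" = "green"))
  expect_identical(combine_statuses(c("green", "green"), rule), "green")
  expect_error(combine_statuses(c("green", "red"), rule), "missing status combination")
})

test_that("blood pressure reproduces all 9 printed band combinations", {
  reps <- list(green = list(sys = 135, dia = 85),
               orange = list(sys = 150, dia = 95),
               red = list(sys = 165, dia = 105))
  expected <- matrix(c("green",  "orange", "red",
                       "orange", "orange", "red",
                       "red",    "red",    "red"),
                     nrow = 3, byrow = TRUE,
                     dimnames = list(names(reps), names(reps)))
  for (s in names(reps)) {
    for (d in names(reps)) {
      expect_identical(
        classify_blood_pressure(reps[[s]]$sys, reps[[d]]$dia, ref_cfg),
        expected[s, d], info = paste(s, d))
    }
  }
  expect_identical(classify_blood_pressure(150, NA, ref_cfg), "gray")
})

test_that("the printed blood-pressure table is exactly max-severity", {
  # worst_of equals an explicit table built from the printed combined rule
  printed <- list(
    "green|green" = "green",  "green|orange" = "orange", "green|red" = "red",
    "orange|green" = "orange", "orange|orange" = "orange", "orange|red" = "red",
    "red|green" = "red", "red|orange" = "red", "red|red" = "red")
  table_rule <- list(rule_kind = "explicit_table", explicit_table = printed)
  for (s in RANKED_STATUSES) {
    for (d in RANKED_STATUSES) {
      expect_identical(combine_statuses(c(s, d), "worst_of"),
                       combine_statuses(c(s, d), table_rule))
    }
  }
})

test_that("mental-health classification is a two-color rule at 50", {
  expect_identical(classify_mental_health(50, ref_cfg), "red")
  expect_identical(classify_mental_health(51, ref_cfg), "green")
  expect_identical(classify_mental_health(0, ref_cfg), "red")
  expect_identical(classify_mental_health(NA, ref_cfg), "gray")
  expect_error(classify_mental_health(101, ref_cfg), "outside valid range")
  statuses <- vapply(0:100, function(s) classify_mental_health(s, ref_cfg), "")
  expect_false(any(statuses == "orange"))
  expect_identical(statuses, ifelse(0:100 <= 50, "red", "green"))
})

test_that("increasing a value never decreases severity on ascending bands", {
  for (eid in ref_cfg$element_order) {
    e <- ref_cfg$elements[[eid]]
    if (!identical(e$value_kind, "categorical")) {
      bands <- e$bands[order(vapply(e$bands, function(b) b$lower, 0))]
      sev <- status_rank(vapply(bands, function(b) b$status, ""))
      if (is.unsorted(sev)) next  # protective elements (HDL, eGFR, ...) excluded
      lo <- e$range[[1L]]; hi <- e$range[[2L]]
      grid <- seq(lo, hi, length.out = 41)
      ranks <- status_rank(vapply(grid, function(v)
        classify_element(eid, v, ref_cfg), ""))
      expect_false(is.unsorted(ranks), info = eid)
    }
  }
})

test_that("build_profile: all-healthy fixture is green on all 21 parameters", {
  p <- build_profile(healthy_assessment(), ref_cfg)
  expect_length(p$parameter_status, 21L)
  expect_true(all(unlist(p$parameter_status) == "green"))
  expect_identical(p$config_id, ref_cfg$config_id)
})

test_that("missing WHO-5 items gray out mental health and nothing else", {
  a <- healthy_assessment()
  a$item_responses$who5 <- c(4, NA, 4, 4, 4)
  p <- build_profile(a, ref_cfg)
  expect_identical(p$parameter_status$mental_health, "gray")
  others <- unlist(p$parameter_status[names(p$parameter_status) != "mental_health"])
  expect_true(all(others == "green"))
  expect_false("who5_score" %in% names(p$element_status))
})

test_that("build_profile matches the independent band+rule oracle on the demo fixture", {
  a <- demo_assessment()
  p <- build_profile(a, ref_cfg)

  # oracle element values, computed by hand from the fixture's raw answers
  oracle_values <- c(a$clinical_values, list(
    who5_score = 48, pss_score = 12, paid5_score = 3,
    avg_glasses_per_day = 9 / 7, binge_freq = 0,
    cigarettes_per_day = 0, craving = 0,
    fruit_portions = 2, vegetable_grams = 250, soda_glasses = 0,
    fastfood_per_week = 1, snacks_per_day = 1,
    activity_minutes = 150, sitting_hours = 57 / 7,
    glucose_monitoring = 10, medication_adherence = 10,
    perceived_health_score = 3, pain_score = 2,
    worries_children = 1, worries_relations = 2, loneliness_score = 2,
    work_score = 1, income_score = 2, neighborhood_score = 1, house_score = 1))

  for (par in ref_cfg$payload$parameters) {
    el_status <- vapply(unlist(par$element_ids), function(eid) {
      oracle_band_status(ref_cfg$elements[[eid]], oracle_values[[eid]])
    }, "")
    expect_identical(p$parameter_status[[par$id]], oracle_worst_of(el_status),
                     info = par$id)
  }
  # frozen expectation for the headline counts
  tab <- table(unlist(p$parameter_status))
  expect_identical(as.integer(tab[c("green", "orange", "red")]), c(9L, 11L, 1L))
})

test_that("build_profile is pure given assessment and config", {
  a <- demo_assessment()
  expect_identical(write_profile(build_profile(a, ref_cfg)),
                   write_profile(build_profile(a, ref_cfg)))
})

test_that("assessments referencing unknown elements or instruments list them all", {
  a <- healthy_assessment()
  a$clinical_values$chakra <- 7
  a$item_responses$tarot <- c(1, 2)
  err <- tryCatch(build_profile(a, ref_cfg), error = conditionMessage)
  expect_match(err, "chakra")
  expect_match(err, "tarot")
})
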