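# Intervention matching against the catalog.

ref_catalog <- load_reference_catalog()

test_that("the packaged catalog has 27 entries in the closed enumerations", {
  expect_length(ref_catalog, 27L)
  cats <- vapply(ref_catalog$interventions, function(e) e$category, "")
  avail <- vapply(ref_catalog$interventions, function(e) e$availability, "")
  expect_true(all(cats %in% INTERVENTION_CATEGORIES))
  expect_true(all(avail %in% AVAILABILITY_CLASSES))
  expect_length(INTERVENTION_CATEGORIES, 7L)
  expect_length(AVAILABILITY_CLASSES, 3L)
  # every target parameter resolves in the reference config
  targets <- unique(unlist(lapply(ref_catalog$interventions,
                                  function(e) unlist(e$target_parameter_ids))))
  expect_true(all(targets %in% ref_cfg$parameter_order))
})

test_that("catalog loading validates enumerations and accepts empty catalogs", {
  path <- withr::local_tempfile(fileext = ".json")
  canonical_json(list(schema_id = "diag360/catalog", schema_version = "1.0",
                      interventions = list()), path)
  expect_length(load_catalog(path), 0L)

  bad <- list(schema_id = "diag360/catalog", schema_version = "1.0",
              interventions = list(list(
                id = "gym-card", name = "Gym", category = "gym",
                availability = "nationwide_web",
                target_parameter_ids = list("weight"))))
  canonical_json(bad, path)
  expect_error(load_catalog(path), "gym-card.*unknown category 'gym'")
})

test_that("an all-green profile matches nothing", {
  p <- build_profile(healthy_assessment(), ref_cfg)
  out <- match_interventions(p, ref_catalog)
  expect_identical(nrow(out), 0L)
})

test_that("matching respects targets, availability and red-first ordering", {
  p <- build_profile(healthy_assessment(), ref_cfg)
  p$parameter_status$perceived_stress <- "red"
  out <- match_interventions(p, ref_catalog, context = "nationwide_web")
  expect_gt(nrow(out), 0L)
  expect_true(all(out$availability == "nationwide_web"))
  expect_true(all(grepl("perceived_stress", out$matched_parameters)))
  expect_true("mindfulness-app" %in% out$id)
  expect_false("mindfulness-group" %in% out$id)  # proximity-only entry

  # orange weight + red glucose metabolism: glucose-targeting entries first
  p2 <- build_profile(healthy_assessment(), ref_cfg)
  p2$parameter_status$weight <- "orange"
  p2$parameter_status$glucose_metabolism <- "red"
  out2 <- match_interventions(p2, ref_catalog)
  expect_setequal(unique(out2$priority), c("red", "orange"))
  first_orange <- match("orange", out2$priority)
  last_red <- max(which(out2$priority == "red"))
  expect_lt(last_red, first_orange)
  expect_error(match_interventions(p2, ref_catalog, context = "moon"),
               "unknown availability")
})

test_that("matching is sound and complete against a brute-force oracle", {
  set.seed(77)
  for (rep in 1:20) {
    p <- build_profile(healthy_assessment(), ref_cfg)
    for (pid in ref_cfg$parameter_order) {
      p$parameter_status[[pid]] <- sample(STATUS_LEVELS, 1L)
    }
    context <- sample(AVAILABILITY_CLASSES, sample(1:3, 1L))
    got <- match_interventions(p, ref_catalog, context)
    flagged <- names(Filter(function(s) s %in% c("orange", "red"),
                            p$parameter_status))
    # oracle: double loop over catalog entries and flagged parameters
    want <- vapply(ref_catalog$interventions, function(e) {
      e$availability %in% context &&
        length(intersect(unlist(e$target_parameter_ids), flagged)) > 0L
    }, TRUE)
    want_ids <- vapply(ref_catalog$interventions, function(e) e$id, "")[want]
    expect_setequal(got$id, want_ids)
    # soundness: every row targets >= 1 non-green parameter in context
    if (nrow(got) > 0L) {
      expect_true(all(got$availability %in% context))
      expect_true(all(vapply(strsplit(got$matched_parameters, ";"),
                             function(m) all(m %in% flagged), TRUE)))
    }
  }
})
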