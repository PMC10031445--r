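# Questionnaire scoring: published scoring arithmetic, routing, missing
# data signalling, and output-range properties.

test_that("WHO-5 scoring matches the published 0..100 percentage scale", {
  expect_identical(score_who5(c(5, 5, 5, 5, 5)), 100)
  expect_identical(score_who5(c(0, 0, 0, 0, 0)), 0)
  # oracle: 4 x raw sum
  expect_identical(score_who5(c(3, 2, 3, 2, 2)), 4 * (3 + 2 + 3 + 2 + 2))
  expect_error(score_who5(c(3, 2, 3, 2)), "exactly 5")
  expect_error(score_who5(c(3, 2, 3, 2, 6)), "out of range")
  expect_true(is.na(score_who5(c(3, NA, 3, 2, 2))))
})

test_that("alcohol frequency-quantity scoring and routing", {
  abst <- score_alcohol(c(0, NA, NA, NA, NA, NA))
  expect_identical(abst$avg_glasses_per_day, 0)
  expect_identical(abst$binge_freq, 0)

  # 2 glasses on each of the 7 days
  daily2 <- score_alcohol(c(1, 5, 2, 2, 2, 0))
  expect_equal(daily2$avg_glasses_per_day, 2)
  expect_identical(daily2$binge_freq, 0)

  # 6 glasses on each of 2 weekend days, none on weekdays: 12/7 per day,
  # and the >= 6 glasses per occasion rule implies binge drinking
  weekend <- score_alcohol(c(1, 0, 0, 2, 6, NA))
  expect_equal(weekend$avg_glasses_per_day, 12 / 7)
  expect_gt(weekend$binge_freq, 0)

  # drinker with missing quantity answers never yields a silent number
  expect_true(is.na(score_alcohol(c(1, NA, NA, 2, 2, 0))$avg_glasses_per_day))
  expect_true(is.na(score_alcohol(c(NA, NA, NA, NA, NA, NA))$avg_glasses_per_day))
})

test_that("score_instrument dispatches published sum scores and fixtures", {
  expect_identical(score_instrument("paid5", c(0, 0, 0, 0, 0), ref_cfg),
                   list(paid5_score = 0))
  expect_identical(score_instrument("pss", rep(4, 10), ref_cfg)$pss_score,
                   # reverse-keyed items 4,5,7,8 score 0 when answered 4
                   6 * 4 + 4 * 0)
  expect_identical(score_instrument("pss", rep(0, 10), ref_cfg)$pss_score, 16)
  # eating fixture: direct per-food-group mapping
  expect_identical(
    score_instrument("eating", c(1, 150, 2, 0, 3), ref_cfg),
    list(fruit_portions = 1, vegetable_grams = 150, soda_glasses = 2,
         fastfood_per_week = 0, snacks_per_day = 3))
  # DSMQ: two 4-item subscales scaled to 0..10
  d <- score_instrument("dsmq", c(3, 3, 3, 3, 0, 1, 1, 0), ref_cfg)
  expect_equal(d$glucose_monitoring, 10)
  expect_equal(d$medication_adherence, 2 / 12 * 10)
  # activity minutes: sum of days x minutes; absent blocks count 0
  expect_identical(
    score_instrument("squash_activity", c(NA, NA, 2, 30, NA, NA, 5, 20, NA, NA),
                     ref_cfg)$activity_minutes, 160)
  expect_true(is.na(score_instrument("squash_activity", rep(NA, 10),
                                     ref_cfg)$activity_minutes))
  # sitting hours: weekday/weekend weighted average
  expect_equal(score_instrument("sedentary", c(7, 14), ref_cfg)$sitting_hours,
               (5 * 7 + 2 * 14) / 7)
  expect_error(score_instrument("horoscope", c(1), ref_cfg), "unknown instrument")
  expect_error(score_instrument("who5", c(1, 2, 3, 4, 9), ref_cfg),
               "outside scale")
})

test_that("scorers are pure and respect their declared output ranges", {
  set.seed(101)
  for (rep in 1:25) {
    for (iid in ref_cfg$instrument_order) {
      inst <- ref_cfg$instruments[[iid]]
      items <- vapply(inst$item_scales, function(s) {
        lo <- s[[1L]]; hi <- s[[2L]]
        if (iid %in% c("sedentary")) stats::runif(1, lo, hi)
        else sample(seq(lo, hi), 1L)
      }, 0)
      s1 <- score_instrument(iid, items, ref_cfg)
      s2 <- score_instrument(iid, items, ref_cfg)
      expect_identical(s1, s2)
      for (eid in names(s1)) {
        v <- s1[[eid]]
        if (is.na(v)) next
        rng <- ref_cfg$elements[[eid]]$range
        expect_gte(v, rng[[1L]])
        expect_lte(v, rng[[2L]])
      }
    }
  }
})

test_that("short scales require all items; missingness is always explicit", {
  for (case in list(list("who5", 5), list("pss", 10), list("paid5", 5))) {
    items <- rep(1, case[[2L]]); items[2] <- NA
    out <- score_instrument(case[[1L]], items, ref_cfg)
    expect_true(is.na(out[[1L]]), info = case[[1L]])
  }
  # a direct-mapped instrument leaves only the unanswered element absent
  out <- score_instrument("family", c(NA, 2), ref_cfg)
  expect_true(is.na(out$worries_children))
  expect_identical(out$worries_relations, 2)
})
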