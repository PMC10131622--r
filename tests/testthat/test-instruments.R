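test_that("GAD-7 scoring covers the banding boundaries", {
  zero <- score_gad7(rep(0, 7))
  expect_equal(zero$total, 0L)
  expect_equal(as.character(zero$band), "none")

  top <- score_gad7(rep(3, 7))
  expect_equal(top$total, 21L)
  expect_equal(as.character(top$band), "severe")

  # severe starts exactly at 15; 5-14 collapses to mild_to_moderate
  fifteen <- score_gad7(c(3, 3, 3, 3, 3, 0, 0))
  expect_equal(fifteen$total, 15L)
  expect_equal(as.character(fifteen$grouped_band), "severe")

  thirteen <- score_gad7(c(2, 2, 2, 2, 2, 2, 1))
  expect_equal(thirteen$total, 13L)
  expect_equal(as.character(thirteen$band), "moderate")
  expect_equal(as.character(thirteen$grouped_band), "mild_to_moderate")
})

test_that("PHQ-9 scoring returns the suicidality item and shares the banding", {
  zero <- score_phq9(rep(0, 9))
  expect_equal(zero$total, 0L)
  expect_equal(zero$item9, 0L)

  res <- score_phq9(c(1, 1, 1, 1, 1, 1, 1, 1, 2))
  expect_equal(res$total, 10L)
  expect_equal(as.character(res$band), "moderate")
  expect_equal(res$item9, 2L)

  fourteen <- score_phq9(c(2, 2, 2, 2, 2, 2, 2, 0, 0))
  expect_equal(fourteen$total, 14L)
  expect_equal(as.character(fourteen$grouped_band), "mild_to_moderate")
  expect_equal(as.character(score_phq9(c(3, 3, 3, 3, 3, 0, 0, 0, 0))$grouped_band),
               "severe")
})

test_that("burnout screen takes the mean of two 0-6 items with a presence cutoff", {
  expect_equal(score_burnout(c(0, 0)), tibble::tibble(score = 0, present = FALSE))
  expect_equal(score_burnout(c(2, 2)), tibble::tibble(score = 2, present = TRUE))
  # 0.5 sits below the default cutoff of 1.0
  expect_equal(score_burnout(c(1, 0)), tibble::tibble(score = 0.5, present = FALSE))
  expect_true(score_burnout(c(1, 0), threshold = 0.5)$present)
})

test_that("item validation errors name the offending index", {
  expect_error(score_gad7(rep(0, 6)), "exactly 7")
  expect_error(score_gad7(c(0, 0, 4, 0, 0, 0, 0)), "item 3")
  expect_error(score_phq9(c(rep(0, 8), -1)), "item 9")
  expect_error(score_burnout(c(7, 0)), "item 1")
  expect_error(score_burnout(c(0, 1.5)), "item 2")
})

test_that("classify populates totals, bands, and presence flags consistently", {
  zero <- classify(make_assessment())
  expect_false(any(zero$anxiety_present, zero$depression_present,
                   zero$burnout_present))
  expect_equal(as.character(zero$gad7_band), "none")

  # a typical moderately symptomatic baseline: both scales in 5-14
  both13 <- classify(make_assessment(g = c(2, 2, 2, 2, 2, 2, 1),
                                     p = c(2, 2, 2, 2, 2, 1, 1, 1, 0)))
  expect_equal(both13$gad7_total, 13L)
  expect_equal(both13$phq9_total, 13L)
  expect_equal(as.character(both13$gad7_grouped_band), "mild_to_moderate")
  expect_equal(as.character(both13$phq9_grouped_band), "mild_to_moderate")
  expect_true(both13$anxiety_present && both13$depression_present)

  # item 9 endorsed but total below the screening cutoff: flag stays off,
  # the item is still carried forward for alerting
  item9 <- classify(make_assessment(p = c(p9 = 1)))
  expect_false(item9$depression_present)
  expect_equal(item9$phq9_item9, 1L)
})

test_that("totals stay in range and bands are monotone over random valid inputs", {
  set.seed(424201)
  prev <- NULL
  for (i in 1:200) {
    prof <- classify(random_assessment())
    expect_true(prof$gad7_total >= 0 && prof$gad7_total <= 21)
    expect_true(prof$phq9_total >= 0 && prof$phq9_total <= 27)
    expect_true(prof$burnout_score >= 0 && prof$burnout_score <= 6)
  }
  # band is monotone non-decreasing in the total, and the grouped band is a
  # deterministic coarsening
  bands <- vapply(0:21, function(t) {
    items <- c(rep(3, t %/% 3), t %% 3, rep(0, 7))[1:7]
    as.character(severity <- score_gad7(items)$band)
  }, character(1))
  expect_true(all(diff(match(bands, c("none", "mild", "moderate", "severe"))) >= 0))
  for (t in 0:21) {
    items <- c(rep(3, t %/% 3), t %% 3, rep(0, 7))[1:7]
    res <- score_gad7(items)
    expected <- c(none = "none", mild = "mild_to_moderate",
                  moderate = "mild_to_moderate", severe = "severe")
    expect_equal(as.character(res$grouped_band),
                 unname(expected[as.character(res$band)]))
  }
})

test_that("classify is pure: same response gives an identical profile", {
  set.seed(77)
  resp <- random_assessment()
  expect_identical(classify(resp), classify(resp))
})
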