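test_that("the profile catalog covers the 17 simulated clinical situations", {
  cat <- profile_catalog()
  expect_equal(nrow(cat), 17)
  expect_equal(cat$expected_modules[[3]], c(1L, 3L, 4L, 5L, 6L, 7L, 10L))
  # symptom-free profile: empty plan, no alert
  expect_equal(cat$expected_modules[[8]], integer(0))
  expect_false(cat$expects_alert[8])
  # only the suicidal-thoughts profile expects an alert
  expect_equal(which(cat$expects_alert), 7)
  # all templates are valid item vectors
  for (i in seq_len(nrow(cat))) {
    resp <- generate_assessment(cat[i, ], "check")
    expect_silent(classify(resp))
  }
})

test_that("profile templates reach the labelled severity", {
  cat <- profile_catalog()
  scored <- score_assessments(profile_assessments())
  expect_gte(scored$gad7_total[1], 15)   # severe anxiety
  expect_gte(scored$phq9_total[3], 15)   # severe depression
  expect_true(all(scored$gad7_total[scored$user_id == "sim08"] == 0))
  # moderate profiles sit in 10-14
  expect_true(scored$gad7_total[2] >= 10 && scored$gad7_total[2] <= 14)
  expect_true(scored$phq9_total[4] >= 10 && scored$phq9_total[4] <= 14)
})

test_that("profile assessment generation is deterministic", {
  cat <- profile_catalog()
  expect_identical(generate_assessment(cat[5, ], "x"),
                   generate_assessment(cat[5, ], "x"))
})

test_that("end-to-end replay reproduces plans and alerts for every profile", {
  cat <- profile_catalog()
  assessments <- profile_assessments()
  plans <- build_plans(score_assessments(assessments))
  exact <- purrr::map_lgl(seq_len(17), function(i) {
    identical(plans$module_ids[[i]], cat$expected_modules[[i]])
  })
  expect_equal(sum(exact[cat$exact_expected]), 15)
  expect_true(all(c(11, 12) %in% plans$module_ids[[6]]))
  alerts <- check_assessment(assessments)
  expect_equal(alerts$user_id, "sim07")
  # the erratic profile triggers the insult intent instead
  msgs <- tibble::tibble(user_id = "sim17", text = cat$messages[[17]])
  expect_true("insult" %in% check_messages(msgs)$intent)
})

test_that("simulation config validates probabilities", {
  expect_error(sim_config(continuation = c(1.2, 0.1)),
               class = "mhtriage_validation_error")
  expect_error(sim_config(burnout_probs = rep(0.1, 10)),
               class = "mhtriage_validation_error")
  expect_error(sim_config(activity_prob = -0.1),
               class = "mhtriage_validation_error")
})

test_that("cohorts are byte-identical under a fixed seed", {
  cfg <- sim_config(n_baseline = 12)
  a <- generate_cohort(cfg, seed = 321)
  b <- generate_cohort(cfg, seed = 321)
  expect_identical(a, b)
  c <- generate_cohort(cfg, seed = 322)
  expect_false(identical(a$assessments, c$assessments))
})

test_that("generated artifacts pass every consuming validator", {
  cohort <- generate_cohort(sim_config(n_baseline = 25), seed = 11)
  expect_silent(classify(cohort$assessments))
  scored <- score_assessments(cohort$assessments)
  expect_true(all(scored$gad7_total <= 21 & scored$phq9_total <= 27))
  expect_silent(mhtriage:::validate_events(cohort$events))
  # timestamps non-decreasing per user
  by_user <- split(cohort$events$ts, cohort$events$user_id)
  expect_true(all(vapply(by_user, function(x) !is.unsorted(x), logical(1))))
  # assessments appear as events, 14 days apart
  sa <- cohort$events[cohort$events$kind == "self_assessment", ]
  expect_equal(nrow(sa), nrow(cohort$assessments))
  if (nrow(cohort$mauq) > 0) expect_silent(score_mauq(cohort$mauq))
  # alert events exactly for responses endorsing PHQ-9 item 9
  expect_equal(
    sort(unique(cohort$events$user_id[cohort$events$kind == "alert"])),
    sort(unique(scored$user_id[scored$phq9_item9 >= 1]))
  )
})

test_that("attrition matches the configured continuation probabilities", {
  # week-2 completers are Binomial(n, p1): check the mean over replicates
  reps <- 60
  n <- 34
  p1 <- 9 / 34
  cfg <- sim_config(n_baseline = n, activity_prob = 0, reminder_prob = 0,
                    audio_prob = 0)
  week2 <- vapply(seq_len(reps), function(i) {
    sum(generate_cohort(cfg, seed = 5000 + i)$users$enrolled_through >= 1)
  }, numeric(1))
  se <- sqrt(n * p1 * (1 - p1) / reps)
  expect_lt(abs(mean(week2) - n * p1), 4 * se)
})

test_that("a zero-effect configuration produces near-zero mean change", {
  cfg <- sim_config(n_baseline = 400, continuation = c(1, 0), effect_gad = 0,
                    effect_phq = 0, burnout_decay = 1, activity_prob = 0,
                    reminder_prob = 0, audio_prob = 0)
  cohort <- generate_cohort(cfg, seed = 606)
  scored <- score_assessments(cohort$assessments)
  pre <- scored[scored$timepoint_index == 0, ]
  post <- scored[scored$timepoint_index == 1, ]
  post <- post[match(pre$user_id, post$user_id), ]
  d <- pre$gad7_total - post$gad7_total
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)))
})

test_that("burnout decay drives the follow-up median to zero", {
  cfg <- sim_config(n_baseline = 300, continuation = c(1, 0),
                    activity_prob = 0, reminder_prob = 0, audio_prob = 0)
  cohort <- generate_cohort(cfg, seed = 42)
  scored <- score_assessments(cohort$assessments)
  expect_equal(median(scored$burnout_score[scored$timepoint_index == 0]), 2)
  expect_lte(median(scored$burnout_score[scored$timepoint_index == 1]), 0.5)
})
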