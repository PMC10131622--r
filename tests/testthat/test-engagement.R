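three_user_log <- function() {
  dplyr::bind_rows(
    make_event("a", 0, "signup", hour = 9),
    make_event("a", 0, "self_assessment", timepoint_index = 0),
    dplyr::bind_rows(lapply(1:14, function(d) make_event("a", d, "message"))),
    make_event("a", 29, "mauq_submitted", hour = 18),
    make_event("b", 0, "signup", hour = 9),
    make_event("c", 0, "self_assessment", timepoint_index = 0),
    make_event("c", 29, "message")
  )
}

test_that("active days deduplicate and exclude scheduling-only events", {
  log <- dplyr::bind_rows(
    make_event("u", 0, "self_assessment", hour = 10, timepoint_index = 0),
    make_event("u", 0, "message", hour = 15),
    make_event("u", 5, "module_complete", module_id = 2),
    make_event("u", 7, "reminder_set"),
    make_event("u", 9, "audio_recorded")
  )
  expect_equal(active_days(log, "u"), c(0L, 5L))  # 7 and 9 are not active use
  expect_equal(active_days(log, "nobody"), integer(0))
})

test_that("objective UEIs equal hand counts on a crafted 3-user log", {
  uei <- compute_objective_uei(three_user_log())
  # user a completes (MAUQ on day 29); b and c do not
  expect_equal(uei$completion, 1 / 3)
  # only c has active use on day >= 28
  expect_equal(uei$adherence, 1 / 3)
  # active days: a has 15 of 30, b none, c two (day 0 and day 29)
  expect_equal(uei$compliance, (15 / 30 + 0 + 2 / 30) / 3)
  # a is active 7 days in each of weeks 0 and 1; no other engaged weeks
  expect_equal(uei$engagement, 2 / 12)
  expect_true(all(unlist(uei[, -1]) >= 0 & unlist(uei[, -1]) <= 1))
})

test_that("single-user boundary cases match the metric definitions", {
  # 15 active days out of 30 -> compliance one half
  log <- dplyr::bind_rows(lapply(seq(0, 28, 2), function(d) {
    make_event("solo", d, "message")
  }))
  uei <- compute_objective_uei(log)
  expect_equal(uei$compliance, 0.5)
  # >= 5 active days in 2 of 4 weeks -> engagement one half
  log2 <- dplyr::bind_rows(lapply(c(0:4, 7:11), function(d) {
    make_event("solo", d, "message")
  }))
  expect_equal(compute_objective_uei(log2)$engagement, 0.5)
})

test_that("adding activity never decreases any objective metric", {
  base_log <- three_user_log()
  base <- compute_objective_uei(base_log)
  set.seed(515)
  for (i in 1:25) {
    extra <- make_event(sample(c("a", "b", "c"), 1), sample(0:29, 1),
                        sample(c("message", "module_complete",
                                 "self_assessment", "mauq_submitted"), 1))
    base_log <- dplyr::bind_rows(base_log, extra)
    grown <- compute_objective_uei(base_log)
    for (m in c("completion", "adherence", "compliance", "engagement")) {
      expect_gte(grown[[m]], base[[m]])
    }
    base <- grown
  }
})

test_that("an empty cohort is an error", {
  expect_error(compute_objective_uei(three_user_log(), cohort = character(0)),
               class = "mhtriage_validation_error")
})

test_that("MAUQ scoring summarizes agreement and the user-mean distribution", {
  all7 <- dplyr::bind_rows(make_mauq("a", rep(7, 18)), make_mauq("b", rep(7, 18)))
  res <- score_mauq(all7)
  expect_equal(res$mean, 7)
  expect_equal(res$sd, 0)
  expect_true(all(res$agreement$agreement == 1))

  # one statement rated 5 and 4 across two users: agreement one half
  mixed <- dplyr::bind_rows(make_mauq("a", c(5, rep(7, 17))),
                            make_mauq("b", c(4, rep(7, 17))))
  expect_equal(score_mauq(mixed)$agreement$agreement[1], 0.5)

  floor <- score_mauq(make_mauq("solo", rep(1, 18)))
  expect_equal(floor$mean, 1)
  expect_equal(floor$agreement$agreement, rep(0, 18))

  expect_error(score_mauq(make_mauq("bad", rep(8, 18))),
               class = "mhtriage_validation_error")
  expect_error(score_mauq(dplyr::bind_rows(make_mauq("a", rep(7, 18)))[, 1:10]),
               class = "mhtriage_validation_error")
})

test_that("the feasibility verdict follows the subjective/objective contrast", {
  expect_equal(feasibility_verdict("high", "high"), "high")
  expect_equal(feasibility_verdict("low", "low"), "low")
  expect_equal(feasibility_verdict("high", "low"), "moderate")
  expect_equal(feasibility_verdict("low", "high"), "moderate")
  expect_error(feasibility_verdict("medium", "low"),
               class = "mhtriage_validation_error")
})

test_that("a highly rated but barely used tool is moderately feasible", {
  mauq <- dplyr::bind_rows(make_mauq("a", rep(7, 18)), make_mauq("c", rep(6, 18)))
  rep <- uei_report(three_user_log(), mauq_data = mauq)
  expect_equal(rep$verdict, "moderate")
  lv <- tidy(rep)
  expect_equal(lv$level[lv$metric == "mauq_mean"], "high")
  expect_true(all(lv$level[lv$metric %in% c("adherence", "compliance",
                                            "engagement")] == "low"))
  g <- glance(rep)
  expect_equal(g$mauq_mean, 6.5)
  expect_equal(g$verdict, "moderate")
})

test_that("half-up percentage reporting reproduces printed study figures", {
  counts <- study_counts()
  log <- counts_to_log(counts)
  s <- usage_summary(log, n_invited = counts$invited)
  get <- function(m, col = "pct") s[[col]][s$metric == m]
  expect_equal(pct(get("signup_conversion", "value")), 26)
  expect_equal(pct(get("signup_conversion", "value"), 1), 26.2)
  expect_equal(get("third_selfassessment", "num"), 2)
  expect_equal(pct(get("third_selfassessment", "value")), 6)
  expect_equal(round_half_up(get("modules_per_active_user", "value"), 1), 4.5)

  uei <- compute_objective_uei(log)
  expect_equal(uei$completion, 8 / 34)
  expect_equal(pct(uei$completion), 24)
  expect_equal(uei$adherence, 2 / 34)
  expect_equal(pct(uei$adherence), 6)
})

test_that("round_half_up rounds half away from zero", {
  expect_equal(round_half_up(c(0.5, 1.5, 2.5, -0.5)), c(1, 2, 3, -1))
  expect_equal(round_half_up(23.45, 1), 23.5)
  expect_equal(pct(8 / 34), 24)
})
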