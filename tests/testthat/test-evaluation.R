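test_that("the normality gate separates normal from clearly non-normal samples", {
  # a coarse uniform grid, scaled: decisively non-normal at n = 100
  grid <- rep(seq(0, 1, length.out = 10), 10) * 100
  res <- normality_check(grid)
  expect_false(res$is_normal)
  expect_equal(nrow(res$qq), 100)

  set.seed(42)
  gauss <- rnorm(50)
  res2 <- normality_check(gauss)
  expect_true(res2$is_normal)
  # same W and p as the reference implementation
  sw <- shapiro.test(gauss)
  expect_equal(res2$W, unname(sw$statistic))
  expect_equal(res2$p, sw$p.value)

  expect_error(normality_check(rep(2, 10)), class = "mhtriage_validation_error")
  expect_error(normality_check(c(1, 2)), class = "mhtriage_validation_error")
})

test_that("the paired t statistic matches the closed form", {
  # identical samples: no change
  same <- paired_t_test(c(3, 4, 5), c(3, 4, 5))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  # differences (1, 2, 3): t = 2 / (1 / sqrt(3)) = 2 sqrt(3)
  res <- paired_t_test(c(5, 7, 9), c(4, 5, 6))
  expect_equal(res$statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(round_half_up(res$statistic, 3), 3.464)

  # closed form to 1e-12 on arbitrary vectors, df = n - 1
  set.seed(99)
  pre <- rnorm(9, 10, 3); post <- rnorm(9, 9, 3)
  res9 <- paired_t_test(pre, post)
  d <- pre - post
  expect_equal(res9$statistic, mean(d) / (sd(d) / sqrt(9)), tolerance = 1e-12)
  expect_equal(res9$df, 8)
  expect_equal(res9$p, 2 * pt(-abs(res9$statistic), 8), tolerance = 1e-12)

  # p is symmetric in the sign of the differences
  flipped <- paired_t_test(post, pre)
  expect_equal(flipped$p, res9$p, tolerance = 1e-12)
  expect_equal(flipped$statistic, -res9$statistic, tolerance = 1e-12)

  expect_error(paired_t_test(1:3, 1:4), class = "mhtriage_validation_error")
})

test_that("effect size r follows |z| / sqrt(N)", {
  expect_equal(effect_size_r(1, 4), 0.5)
  expect_equal(effect_size_r(0, 10), 0)
  # a z of -2.07 over N = 42 lands at about 0.32
  expect_equal(round_half_up(effect_size_r(-2.07, 42), 2), 0.32)
  expect_error(effect_size_r(1, 0), class = "mhtriage_validation_error")
})

test_that("Pearson correlation matches the closed form", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)

  y <- c(2.3, 1.1, 4.8, 3.9, 4.1)
  res <- pearson_correlation(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  tstat <- r_hand * sqrt(3 / (1 - r_hand^2))
  expect_equal(res$p, 2 * pt(-abs(tstat), 3), tolerance = 1e-12)

  expect_error(pearson_correlation(x, rep(1, 5)),
               class = "mhtriage_validation_error")
  expect_error(pearson_correlation(1:2, 1:2), class = "mhtriage_validation_error")
})

test_that("evaluate_outcomes flags analyses without enough pairs", {
  solo <- dplyr::bind_rows(
    make_assessment("only", 0, g = c(g1 = 2)),
    make_assessment("only", 1, g = c(g1 = 1))
  )
  report <- evaluate_outcomes(solo)
  expect_true(all(report$tests$flag == "insufficient_pairs"))
  expect_s3_class(glance(report), "tbl_df")
  expect_equal(glance(report)$n_flagged, nrow(report$tests))
})

test_that("evaluate_outcomes is deterministic and gates per scale", {
  cfg <- sim_config(n_baseline = 40, continuation = c(1, 0))
  cohort <- generate_cohort(cfg, seed = 2024)
  rep1 <- evaluate_outcomes(cohort$assessments, events = cohort$events)
  rep2 <- evaluate_outcomes(cohort$assessments, events = cohort$events)
  expect_identical(rep1$tests, rep2$tests)
  expect_identical(rep1$correlations, rep2$correlations)

  whole <- rep1$tests[rep1$tests$subgroup == "all", ]
  expect_equal(whole$scale, c("gad7", "phq9", "burnout"))
  # the test chosen always matches the per-scale normality gate
  for (i in seq_len(nrow(whole))) {
    gate <- rep1$normality$is_normal[rep1$normality$scale == whole$scale[i]]
    if (!is.na(gate) && !is.na(whole$test[i])) {
      expect_equal(whole$test[i],
                   if (gate) "paired_t" else "wilcoxon_signed_rank")
    }
  }
  # tidy() exposes the analysis table
  expect_identical(tidy(rep1), rep1$tests)
  expect_true(all(c("mild_to_moderate", "high_engagement") %in%
                    rep1$tests$subgroup))
  # dose-response correlations cover both dose measures for all scales
  expect_equal(nrow(rep1$correlations), 6)
})
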