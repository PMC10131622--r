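# Pre/post statistical evaluation pipeline: normality gate, paired tests,
# effect sizes, dose-response correlations, subgroup reruns.

#' Shapiro-Wilk normality check
#'
#' Tests whether a sample is consistent with a normal distribution and
#' exports theoretical-vs-empirical quantile pairs for external Q-Q
#' plotting (the numerical counterpart of visual Q-Q inspection).
#'
#' @param x Numeric vector, n >= 3, non-constant.
#' @param alpha Significance level of the gate (default 0.05).
#' @return A list: `W`, `p`, `is_normal` (`p > alpha`) and `qq`, a tibble
#'   of `theoretical` and `sample` quantiles.
#' @examples
#' normality_check(c(-1.2, 0.3, 0.1, 0.9, -0.4, 1.5, -0.8))$is_normal
#' @export
normality_check <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 3) {
    abort("normality check requires at least 3 finite values",
          class = "mhtriage_validation_error")
  }
  if (length(unique(x)) == 1) {
    abort("normality check is undefined for a constant sample",
          class = "mhtriage_validation_error")
  }
  sw <- stats::shapiro.test(x)
  qq <- stats::qqnorm(x, plot.it = FALSE)
  list(W = unname(sw$statistic), p = sw$p.value,
       is_normal = sw$p.value > alpha,
       qq = tibble(theoretical = qq$x, sample = qq$y))
}

#' Paired two-tailed t test
#'
#' Tests the mean of the paired differences `d = pre - post` (positive
#' statistic = score reduction) against zero: `t = mean(d) / (sd(d) /
#' sqrt(n))` on `n - 1` degrees of freedom.
#'
#' @param pre,post Numeric vectors of paired measurements.
#' @return A one-row tibble: `test`, `statistic`, `df`, `p`, `n` and
#'   `mean_change` (mean of `pre - post`).
#' @examples
#' paired_t_test(c(4, 5, 6), c(3, 3, 3))
#' @export
paired_t_test <- function(pre, post) {
  if (length(pre) != length(post)) {
    abort("pre and post must have the same length",
          class = "mhtriage_validation_error")
  }
  if (length(pre) < 2) {
    abort("paired t test requires at least 2 pairs",
          class = "mhtriage_validation_error")
  }
  d <- pre - post
  if (stats::sd(d) == 0) {
    return(tibble(test = "paired_t", statistic = 0, df = length(d) - 1,
                  p = 1, n = length(d), mean_change = mean(d)))
  }
  tt <- stats::t.test(pre, post, paired = TRUE)
  tibble(test = "paired_t", statistic = unname(tt$statistic),
         df = unname(tt$parameter), p = tt$p.value, n = length(d),
         mean_change = mean(d))
}

#' Rank-test effect size r
#'
#' Converts a z statistic into the effect size `r = |z| / sqrt(N)`.
#'
#' @param z z statistic.
#' @param N Number of observations the z is based on; the package default
#'   elsewhere is the number of non-zero-difference pairs.
#' @return Effect size r in \[0, 1\] (for |z| <= sqrt(N)).
#' @examples
#' effect_size_r(1, 4)  # 0.5
#' @export
effect_size_r <- function(z, N) {
  if (length(N) != 1 || is.na(N) || N < 1) {
    abort("N must be a positive integer", class = "mhtriage_validation_error")
  }
  abs(z) / sqrt(N)
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return A one-row tibble: `r`, `p` (two-tailed, from the t transform)
#'   and `n`.
#' @examples
#' pearson_correlation(1:5, c(2, 4, 5, 4, 5))
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("correlation requires equal-length vectors with n >= 3",
          class = "mhtriage_validation_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("correlation is undefined for a constant input",
          class = "mhtriage_validation_error")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

scale_columns <- c(gad7 = "gad7_total", phq9 = "phq9_total",
                   burnout = "burnout_score")

# Run one pre/post analysis with the normality gate: paired t when the
# differences look normal, signed-rank otherwise (or when the gate cannot
# run). Returns a one-row tibble with a `flag` column instead of failing.
gated_pair_test <- function(pre, post, label, subgroup, alpha = 0.05,
                            wilcoxon_mode = "auto") {
  base <- tibble(scale = label, subgroup = subgroup, test = NA_character_,
                 statistic = NA_real_, df = NA_real_, z = NA_real_,
                 p = NA_real_, r = NA_real_, n = length(pre),
                 mean_change = NA_real_, flag = NA_character_)
  if (length(pre) < 3) {
    base$flag <- "insufficient_pairs"
    return(base)
  }
  d <- pre - post
  use_t <- if (stats::sd(d) == 0) {
    TRUE  # no variability: t path reports statistic 0, p 1
  } else {
    tryCatch(normality_check(d, alpha = alpha)$is_normal,
             error = function(e) FALSE)
  }
  if (use_t) {
    res <- paired_t_test(pre, post)
    base$test <- "paired_t"
    base$statistic <- res$statistic
    base$df <- res$df
    base$p <- res$p
    base$mean_change <- res$mean_change
  } else {
    res <- wilcoxon_signed_rank(pre, post, mode = wilcoxon_mode)
    base$test <- "wilcoxon_signed_rank"
    base$statistic <- res$statistic
    base$z <- res$z
    base$p <- res$p
    base$r <- res$r
    base$mean_change <- mean(d)
  }
  base
}

#' Evaluate pre/post intervention outcomes
#'
#' The full evaluation pipeline for a longitudinal cohort: for each scale
#' (GAD-7 total, PHQ-9 total, burnout score) it pairs the baseline with a
#' follow-up timepoint by user, gates on Shapiro-Wilk normality of the
#' differences (paired t when normal, Wilcoxon signed-rank otherwise),
#' reruns the anxiety/depression analyses in the mild-to-moderate baseline
#' subgroup (total 5-14), reruns all scales in the high-engagement
#' subgroup (users with >= `engagement_cutoff` of expected active days,
#' requires `events`), and computes dose-response Pearson correlations of
#' modules completed and days of use against score change. Analyses with
#' too few pairs are flagged, not fatal.
#'
#' @param assessments Longitudinal assessment tibble (raw items or scored)
#'   with `user_id` and `timepoint_index`.
#' @param events Optional event-log tibble enabling the engagement
#'   subgroup and dose-response correlations.
#' @param from,to Timepoint indices compared (default baseline 0 vs 1).
#' @param alpha Normality-gate significance level.
#' @param engagement_cutoff Active-day fraction defining the
#'   high-engagement subgroup (default 0.5).
#' @param study_days Study window for engagement (default 30).
#' @param wilcoxon_mode Mode passed to [wilcoxon_signed_rank()].
#' @return A list of class `evaluation_report`: `tests` (per-analysis
#'   tibble), `correlations` (dose-response tibble), `normality`
#'   (per-scale gate results), `n_pairs`, and the options used.
#' @export
evaluate_outcomes <- function(assessments, events = NULL, from = 0, to = 1,
                              alpha = 0.05, engagement_cutoff = 0.5,
                              study_days = 30, wilcoxon_mode = "auto") {
  if (!"gad7_total" %in% names(assessments)) {
    assessments <- score_assessments(assessments)
  }
  pre_df <- assessments[assessments$timepoint_index == from, , drop = FALSE]
  post_df <- assessments[assessments$timepoint_index == to, , drop = FALSE]
  users <- intersect(pre_df$user_id, post_df$user_id)
  pre_df <- pre_df[match(users, pre_df$user_id), , drop = FALSE]
  post_df <- post_df[match(users, post_df$user_id), , drop = FALSE]

  normality <- purrr::imap_dfr(scale_columns, function(col, label) {
    d <- pre_df[[col]] - post_df[[col]]
    res <- tryCatch(normality_check(d, alpha = alpha),
                    error = function(e) NULL)
    tibble(scale = label, n = length(d),
           W = if (is.null(res)) NA_real_ else res$W,
           p = if (is.null(res)) NA_real_ else res$p,
           is_normal = if (is.null(res)) NA else res$is_normal)
  })

  run_scales <- function(idx, subgroup, scales = names(scale_columns)) {
    purrr::map_dfr(scales, function(label) {
      col <- scale_columns[[label]]
      gated_pair_test(pre_df[[col]][idx], post_df[[col]][idx], label,
                      subgroup, alpha = alpha, wilcoxon_mode = wilcoxon_mode)
    })
  }

  tests <- run_scales(seq_along(users), "all")
  m2m_gad <- pre_df$gad7_total >= 5 & pre_df$gad7_total <= 14
  m2m_phq <- pre_df$phq9_total >= 5 & pre_df$phq9_total <= 14
  tests <- dplyr::bind_rows(
    tests,
    run_scales(which(m2m_gad), "mild_to_moderate", "gad7"),
    run_scales(which(m2m_phq), "mild_to_moderate", "phq9")
  )

  correlations <- NULL
  if (!is.null(events)) {
    per_user <- purrr::map_dfr(users, function(u) {
      days <- active_days(events, u, study_days = study_days)
      mods <- sum(events$kind == "module_complete" & events$user_id == u)
      tibble(user_id = u, days_of_use = length(days),
             modules_completed = mods,
             engagement = length(days) / study_days)
    })
    engaged <- per_user$engagement >= engagement_cutoff
    tests <- dplyr::bind_rows(tests, run_scales(which(engaged), "high_engagement"))
    correlations <- purrr::map_dfr(names(scale_columns), function(label) {
      col <- scale_columns[[label]]
      change <- pre_df[[col]] - post_df[[col]]
      purrr::map_dfr(c("modules_completed", "days_of_use"), function(dose) {
        res <- tryCatch(pearson_correlation(per_user[[dose]], change),
                        error = function(e) tibble(r = NA_real_, p = NA_real_,
                                                   n = length(change)))
        tibble(scale = label, dose = dose, r = res$r, p = res$p, n = res$n,
               flag = if (is.na(res$r)) "degenerate_or_insufficient" else NA_character_)
      })
    })
  }

  structure(
    list(tests = tests, correlations = correlations, normality = normality,
         n_pairs = length(users),
         options = list(from = from, to = to, alpha = alpha,
                        engagement_cutoff = engagement_cutoff,
                        study_days = study_days,
                        wilcoxon_mode = wilcoxon_mode)),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation report: %d paired users (timepoint %d vs %d)\n",
              x$n_pairs, x$options$from, x$options$to))
  t <- x$tests
  for (i in seq_len(nrow(t))) {
    if (!is.na(t$flag[i])) {
      cat(sprintf("  %-8s [%s]: %s\n", t$scale[i], t$subgroup[i], t$flag[i]))
    } else {
      cat(sprintf("  %-8s [%s]: %s stat %.2f p %.3f (n=%d)\n", t$scale[i],
                  t$subgroup[i], t$test[i], t$statistic[i], t$p[i], t$n[i]))
    }
  }
  invisible(x)
}

#' @describeIn evaluate_outcomes `tidy()` returns the per-analysis test
#'   tibble.
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @method tidy evaluation_report
#' @export
tidy.evaluation_report <- function(x, ...) x$tests

#' @describeIn evaluate_outcomes `glance()` returns a one-row summary.
#' @method glance evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) {
  whole <- x$tests[x$tests$subgroup == "all", , drop = FALSE]
  tibble(
    n_pairs = x$n_pairs,
    n_analyses = nrow(x$tests),
    n_flagged = sum(!is.na(x$tests$flag)),
    n_significant = sum(whole$p <= 0.05, na.rm = TRUE)
  )
}

#' @describeIn evaluate_outcomes `autoplot()` shows per-analysis p-values
#'   by scale and subgroup.
#' @param object An `evaluation_report`.
#' @method autoplot evaluation_report
#' @export
autoplot.evaluation_report <- function(object, ...) {
  t <- object$tests[!is.na(object$tests$p), , drop = FALSE]
  ggplot2::ggplot(t, ggplot2::aes(x = .data$scale, y = .data$p,
                                  shape = .data$test)) +
    ggplot2::geom_hline(yintercept = 0.05, linetype = "dashed") +
    ggplot2::geom_point(size = 3) +
    ggplot2::facet_wrap(~subgroup) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(y = "two-tailed p", x = NULL,
                  title = "Pre/post outcome tests") +
    ggplot2::theme_minimal()
}
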