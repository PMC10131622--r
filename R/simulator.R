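# Stochastic synthetic-cohort simulator: baseline score distributions,
# biweekly treatment effects, attrition, and usage event streams.

#' Simulation configuration
#'
#' Defaults encode the study conditions the simulator emulates: a cohort
#' of 34 baseline users; memoryless biweekly attrition with continuation
#' probabilities 9/34 (to the week-2 assessment) and 2/9 (week-2 to
#' week-4); baseline GAD-7 totals from a rounded, truncated Normal(13.4,
#' 4.9) on 0..21 and PHQ-9 from Normal(13.2, 6.6) on 0..27; a right-skewed
#' baseline burnout distribution with median score 2.0; mean biweekly
#' treatment effects of -0.4 (GAD-7) and -0.5 (PHQ-9) points with
#' discretized Normal change noise, and multiplicative burnout decay
#' toward 0; and a daily active-use probability of 0.425 while enrolled.
#'
#' @param n_baseline Number of baseline users.
#' @param continuation Length-2 vector of per-timepoint continuation
#'   probabilities (baseline to week 2, week 2 to week 4).
#' @param gad_mean,gad_sd,phq_mean,phq_sd Baseline total distributions.
#' @param burnout_probs Probabilities over the burnout item-sum 0..12
#'   (score = sum / 2).
#' @param effect_gad,effect_phq Mean score change added per biweekly
#'   timepoint (negative = improvement).
#' @param burnout_decay Multiplicative decay of the burnout item sum per
#'   timepoint.
#' @param change_sd SD of the discretized Normal noise on biweekly change.
#' @param activity_prob Probability that an enrolled user is active on a
#'   given day.
#' @param module_prob Probability that an active day includes completing a
#'   module from the user's plan.
#' @param reminder_prob,audio_prob Probability of setting a reminder at
#'   sign-up / recording an audio note after the baseline assessment.
#' @param mauq_probs Named probabilities over MAUQ ratings for completers.
#' @param study_days Study window in days.
#' @param start_date First study day (UTC).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_baseline = 34,
                       continuation = c(9 / 34, 2 / 9),
                       gad_mean = 13.4, gad_sd = 4.9,
                       phq_mean = 13.2, phq_sd = 6.6,
                       burnout_probs = c(0.15, 0.10, 0.10, 0.10, 0.30,
                                         0.05, 0.08, 0.05, 0.07, 0, 0, 0, 0),
                       effect_gad = -0.4, effect_phq = -0.5,
                       burnout_decay = 0.25, change_sd = 2,
                       activity_prob = 0.425, module_prob = 0.3,
                       reminder_prob = 0.65, audio_prob = 0.41,
                       mauq_probs = c("4" = 0.02, "5" = 0.05,
                                      "6" = 0.33, "7" = 0.60),
                       study_days = 30,
                       start_date = "2022-03-01") {
  cfg <- list(n_baseline = n_baseline, continuation = continuation,
              gad_mean = gad_mean, gad_sd = gad_sd,
              phq_mean = phq_mean, phq_sd = phq_sd,
              burnout_probs = burnout_probs,
              effect_gad = effect_gad, effect_phq = effect_phq,
              burnout_decay = burnout_decay, change_sd = change_sd,
              activity_prob = activity_prob, module_prob = module_prob,
              reminder_prob = reminder_prob, audio_prob = audio_prob,
              mauq_probs = mauq_probs, study_days = study_days,
              start_date = start_date)
  probs <- c(cfg$continuation, cfg$activity_prob, cfg$module_prob,
             cfg$reminder_prob, cfg$audio_prob, cfg$burnout_probs,
             cfg$mauq_probs)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    abort("all configured probabilities must be in [0, 1]",
          class = "mhtriage_validation_error")
  }
  if (length(cfg$burnout_probs) != 13 ||
      abs(sum(cfg$burnout_probs) - 1) > 1e-8) {
    abort("burnout_probs must be 13 probabilities (item-sum 0..12) summing to 1",
          class = "mhtriage_validation_error")
  }
  if (cfg$n_baseline < 1) {
    abort("n_baseline must be at least 1", class = "mhtriage_validation_error")
  }
  structure(cfg, class = "sim_config")
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

# Decompose an instrument total into an item vector. Points are assigned
# greedily toward per-item quotas proportional to `weights`, largest
# shortfall first (ties to the lowest index), respecting the per-item
# maximum — a capped largest-remainder allocation. The default PHQ-9
# weights down-weight item 9: suicidality is endorsed far less often than
# the somatic/mood items at the same total severity.
allocate_items <- function(total, n_items, max_item, weights = rep(1, n_items)) {
  stopifnot(total <= n_items * max_item, total >= 0)
  quota <- total * weights / sum(weights)
  items <- pmin(floor(quota), max_item)
  while (sum(items) < total) {
    shortfall <- ifelse(items < max_item, quota - items, -Inf)
    i <- which.max(shortfall)
    items[i] <- items[i] + 1
  }
  as.integer(items)
}

phq9_item_weights <- c(rep(1, 8), 0.15)

iso_ts <- function(start, day, hour, minute = 0) {
  as.POSIXct(start, tz = "UTC") + day * 86400 + hour * 3600 + minute * 60
}

#' Generate a synthetic longitudinal cohort
#'
#' Simulates a feasibility-study cohort end to end: baseline severity
#' drawn from the configured distributions and decomposed into item
#' vectors, biweekly follow-up assessments with treatment effects, noise
#' and attrition, and a usage event log (sign-up, self-assessments,
#' active-day messages, module starts/completions against each user's own
#' treatment plan, suicide alerts from the item-9 rule, reminders, audio
#' notes, and an end-of-study MAUQ submission for completers). A single
#' root seed drives a per-user seed sequence, so output is reproducible
#' and users are independent.
#'
#' @param config A [sim_config()].
#' @param seed Integer root seed.
#' @return A list of class `simulated_cohort`: `assessments` (long item
#'   tibble), `events` (event-log tibble), `mauq` (completer responses),
#'   `users` (per-user enrollment), `config`, `seed`.
#' @examples
#' cohort <- generate_cohort(sim_config(n_baseline = 6), seed = 42)
#' dplyr::count(cohort$events, kind)
#' @export
generate_cohort <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  n <- config$n_baseline
  user_seeds <- sample.int(.Machine$integer.max - 1, n)
  users <- sprintf("sim%03d", seq_len(n))
  rules <- default_rule_table()

  per_user <- purrr::map(seq_len(n), function(i) {
    set.seed(user_seeds[i])
    uid <- users[i]
    start <- config$start_date
    gad0 <- clamp(round(stats::rnorm(1, config$gad_mean, config$gad_sd)), 0, 21)
    phq0 <- clamp(round(stats::rnorm(1, config$phq_mean, config$phq_sd)), 0, 27)
    bo0 <- sample(0:12, 1, prob = config$burnout_probs)
    cont1 <- stats::runif(1) < config$continuation[1]
    cont2 <- cont1 && stats::runif(1) < config$continuation[2]
    enrolled_through <- sum(c(cont1, cont2))

    items <- matrix(0L, nrow = enrolled_through + 1, ncol = 18)
    for (t in 0:enrolled_through) {
      if (t == 0) {
        gad_t <- gad0; phq_t <- phq0; bo_t <- bo0
      } else {
        gad_t <- clamp(round(gad0 + t * config$effect_gad +
                               stats::rnorm(1, 0, config$change_sd)), 0, 21)
        phq_t <- clamp(round(phq0 + t * config$effect_phq +
                               stats::rnorm(1, 0, config$change_sd)), 0, 27)
        bo_t <- clamp(round(bo0 * config$burnout_decay^t +
                              stats::rnorm(1, 0, 1)), 0, 12)
      }
      items[t + 1, ] <- c(allocate_items(gad_t, 7, 3),
                          allocate_items(phq_t, 9, 3, phq9_item_weights),
                          allocate_items(bo_t, 2, 6))
    }
    assess <- tibble(user_id = uid, timepoint_index = 0:enrolled_through,
                     timestamp = iso_ts(start, 14 * (0:enrolled_through), 10))
    assess[assessment_item_cols] <- as.data.frame(items)

    plan <- build_plan(assess[1, ], rules = rules)
    # event accumulators: second-of-study offsets, kinds, payload fields
    e_off <- 9 * 3600  # signup, day 0 09:00
    e_kind <- "signup"
    e_tp <- NA_integer_
    e_mod <- NA_integer_
    add <- function(day, hour, minute, kind, tp = NA_integer_,
                    mod = NA_integer_) {
      e_off <<- c(e_off, day * 86400 + hour * 3600 + minute * 60)
      e_kind <<- c(e_kind, kind)
      e_tp <<- c(e_tp, tp)
      e_mod <<- c(e_mod, mod)
    }
    for (t in 0:enrolled_through) {
      add(14 * t, 10, 0, "self_assessment", tp = as.integer(t))
      if (items[t + 1, 16] >= 1) {  # PHQ-9 item 9 endorsed -> alert
        add(14 * t, 10, 5, "alert", tp = as.integer(t))
      }
    }
    if (stats::runif(1) < config$reminder_prob) add(0, 11, 0, "reminder_set")
    if (stats::runif(1) < config$audio_prob) add(0, 10, 30, "audio_recorded")
    last_day <- min(14 * (enrolled_through + 1) - 1, config$study_days - 1)
    for (day in seq(1, last_day)) {
      if (stats::runif(1) < config$activity_prob) {
        add(day, 12, 0, "message")
        if (length(plan) > 0 && stats::runif(1) < config$module_prob) {
          mod <- if (length(plan) == 1) plan else sample(plan, 1)
          add(day, 12, 15, "module_start", mod = as.integer(mod))
          add(day, 12, 30, "module_complete", mod = as.integer(mod))
        }
      }
    }
    mauq <- NULL
    if (enrolled_through == 2) {
      add(config$study_days - 1, 18, 0, "mauq_submitted")
      ratings <- sample(as.integer(names(config$mauq_probs)), 18,
                        replace = TRUE, prob = config$mauq_probs)
      mauq <- tibble(user_id = uid)
      mauq[paste0("m", 1:18)] <- as.list(as.integer(ratings))
    }
    events <- tibble(user_id = uid,
                     ts = as.POSIXct(start, tz = "UTC") + e_off,
                     kind = e_kind, timepoint_index = e_tp, module_id = e_mod)
    list(assessments = assess, events = events, mauq = mauq,
         user = tibble(user_id = uid, enrolled_through = enrolled_through,
                       baseline_gad7 = gad0, baseline_phq9 = phq0,
                       baseline_burnout = bo0 / 2))
  })

  events <- dplyr::arrange(dplyr::bind_rows(purrr::map(per_user, "events")),
                           .data$user_id, .data$ts)
  structure(
    list(assessments = dplyr::bind_rows(purrr::map(per_user, "assessments")),
         events = events,
         mauq = dplyr::bind_rows(purrr::compact(purrr::map(per_user, "mauq"))),
         users = dplyr::bind_rows(purrr::map(per_user, "user")),
         config = config, seed = seed),
    class = "simulated_cohort"
  )
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort (seed %d): %d baseline users\n",
              x$seed, nrow(x$users)))
  cat(sprintf("  completed week-2 assessment: %d; week-4: %d\n",
              sum(x$users$enrolled_through >= 1),
              sum(x$users$enrolled_through >= 2)))
  cat(sprintf("  events: %d; MAUQ respondents: %d\n",
              nrow(x$events), nrow(x$mauq)))
  invisible(x)
}

#' @describeIn generate_cohort `autoplot()` shows longitudinal scale
#'   trajectories of the simulated cohort.
#' @param object A `simulated_cohort`.
#' @param ... Unused.
#' @method autoplot simulated_cohort
#' @export
autoplot.simulated_cohort <- function(object, ...) {
  scored <- score_assessments(object$assessments)
  long <- tidyr::pivot_longer(
    scored[c("user_id", "timepoint_index", "gad7_total", "phq9_total",
             "burnout_score")],
    cols = c("gad7_total", "phq9_total", "burnout_score"),
    names_to = "scale", values_to = "score")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$timepoint_index,
                                     y = .data$score,
                                     group = .data$user_id)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::stat_summary(ggplot2::aes(group = NULL), fun = mean,
                          geom = "line", linewidth = 1.2, colour = "red") +
    ggplot2::facet_wrap(~scale, scales = "free_y") +
    ggplot2::labs(x = "assessment timepoint (biweekly)", y = "score",
                  title = "Simulated longitudinal trajectories") +
    ggplot2::theme_minimal()
}
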