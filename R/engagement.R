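# Objective user-engagement indicators (completion, adherence, compliance,
# engagement) from event logs; subjective UEIs (MAUQ); feasibility verdict.

event_kinds <- c("signup", "self_assessment", "module_start",
                 "module_complete", "weekly_objective_set",
                 "weekly_objective_rated", "reminder_set", "audio_recorded",
                 "message", "alert", "mauq_submitted")

# "Active" use means actually engaging with content, not scheduling:
# reminders and audio registration alone do not make a day active.
default_active_kinds <- c("self_assessment", "module_start",
                          "module_complete", "weekly_objective_rated",
                          "message")

validate_events <- function(events) {
  needed <- c("user_id", "ts", "kind")
  missing <- setdiff(needed, names(events))
  if (length(missing) > 0) {
    abort(paste0("event log is missing columns: ", paste(missing, collapse = ", ")),
          class = "mhtriage_validation_error")
  }
  bad <- setdiff(unique(events$kind), event_kinds)
  if (length(bad) > 0) {
    abort(paste0("unknown event kind(s): ", paste(bad, collapse = ", ")),
          class = "mhtriage_validation_error")
  }
  invisible(events)
}

user_day_index <- function(events, origin = NULL) {
  ts <- as.POSIXct(events$ts, tz = "UTC")
  if (is.null(origin)) {
    start <- stats::ave(as.numeric(ts), events$user_id, FUN = min)
  } else {
    start <- as.numeric(as.POSIXct(origin, tz = "UTC"))
  }
  as.integer(floor((as.numeric(ts) - start) / 86400))
}

#' Days on which a user actively used the intervention
#'
#' Returns the study-day indices (0-based, relative to the user's first
#' event unless an explicit origin is given) on which the user has at
#' least one active-kind event. Scheduling events (`reminder_set`) and
#' audio registration do not count as active use.
#'
#' @param events Event-log tibble (`user_id`, `ts`, `kind`, ...).
#' @param user_id The user to look up; unknown users yield an empty set.
#' @param study_start Optional POSIXct/character origin; default is the
#'   user's own first event.
#' @param study_days Length of the observation window in days (default 30).
#' @param active_kinds Event kinds that count as active use.
#' @return Sorted integer vector of day indices in `[0, study_days)`.
#' @export
active_days <- function(events, user_id, study_start = NULL, study_days = 30,
                        active_kinds = default_active_kinds) {
  validate_events(events)
  ev <- events[events$user_id == user_id, , drop = FALSE]
  if (nrow(ev) == 0) return(integer(0))
  day <- user_day_index(ev, origin = study_start)
  keep <- ev$kind %in% active_kinds & day >= 0 & day < study_days
  sort(unique(day[keep]))
}

#' Objective user-engagement indicators from an event log
#'
#' Computes the four objective UEIs over a cohort of baseline users:
#'
#' * **completion** — fraction of the cohort with a completion event
#'   (default `mauq_submitted`, i.e. responding to the end-of-study
#'   usability questionnaire) within the study window;
#' * **adherence** — fraction still actively using the intervention after
#'   the final study week (any active event on day >= `study_days - 2`,
#'   i.e. after 4 weeks for the default 30-day window);
#' * **compliance** — mean over users of the fraction of expected days
#'   with active use;
#' * **engagement** — fraction of expected user-weeks with sustained
#'   activity (>= `week_active_days` active days in the week).
#'
#' Day indices are per-user, 0-based from each user's first event.
#'
#' @param events Event-log tibble.
#' @param cohort Character vector of baseline user ids (the denominator);
#'   default: all users appearing in the log.
#' @param study_days Observation window in days (default 30).
#' @param week_active_days Active days needed for a week to count as
#'   engaged (default 5).
#' @param completion_kind Event kind marking completion
#'   (`"mauq_submitted"` or e.g. `"self_assessment"`).
#' @param adherence_after Day index after which activity counts as
#'   adherence; default `study_days - 2` (the fourth-week boundary, day 28
#'   for a 30-day study).
#' @param active_kinds Event kinds that count as active use.
#' @return A one-row tibble: `n_users`, `completion`, `adherence`,
#'   `compliance`, `engagement` (all fractions in \[0, 1\]).
#' @export
compute_objective_uei <- function(events, cohort = NULL, study_days = 30,
                                  week_active_days = 5,
                                  completion_kind = "mauq_submitted",
                                  adherence_after = study_days - 2,
                                  active_kinds = default_active_kinds) {
  validate_events(events)
  if (is.null(cohort)) cohort <- sort(unique(events$user_id))
  if (length(cohort) == 0) {
    abort("objective UEIs are undefined for an empty cohort",
          class = "mhtriage_validation_error")
  }
  n <- length(cohort)
  n_weeks <- floor(study_days / 7)
  per_user <- purrr::map(cohort, function(u) {
    ev <- events[events$user_id == u, , drop = FALSE]
    if (nrow(ev) == 0) {
      return(list(completed = FALSE, adherent = FALSE, days = integer(0)))
    }
    day <- user_day_index(ev)
    completed <- any(ev$kind == completion_kind & day >= 0 & day <= study_days)
    days <- sort(unique(day[ev$kind %in% active_kinds & day >= 0 & day < study_days]))
    adherent <- any(days >= adherence_after)
    list(completed = completed, adherent = adherent, days = days)
  })
  compliance <- mean(purrr::map_dbl(per_user, ~ length(.x$days) / study_days))
  engaged_weeks <- sum(purrr::map_int(per_user, function(x) {
    if (length(x$days) == 0) return(0L)
    wk <- x$days %/% 7
    sum(vapply(0:(n_weeks - 1), function(w) sum(wk == w) >= week_active_days,
               logical(1)))
  }))
  tibble(
    n_users = n,
    completion = mean(purrr::map_lgl(per_user, "completed")),
    adherence = mean(purrr::map_lgl(per_user, "adherent")),
    compliance = compliance,
    engagement = engaged_weeks / (n * n_weeks)
  )
}

mauq_item_cols <- paste0("m", 1:18)

#' Score MAUQ usability responses
#'
#' Summarizes responses to the 18-statement mHealth App Usability
#' Questionnaire (each statement rated 1 = strongly disagree to
#' 7 = strongly agree). The headline score is the mean of per-user mean
#' ratings, with the SD taken across users' means; per-statement agreement
#' is the fraction of respondents rating the statement at or above the
#' agreement cutoff.
#'
#' @param data A tibble with `user_id` and item columns `m1`..`m18`.
#' @param agreement_cutoff Minimum rating counted as agreement (default 5).
#' @return A list of class `mauq_summary`: `mean`, `sd`, `n_respondents`,
#'   and `agreement`, a tibble with `statement` (1..18) and `agreement`
#'   fraction.
#' @examples
#' resp <- tibble::as_tibble(c(list(user_id = c("a", "b")),
#'                             stats::setNames(rep(list(c(7L, 6L)), 18),
#'                                             paste0("m", 1:18))))
#' score_mauq(resp)
#' @export
score_mauq <- function(data, agreement_cutoff = 5) {
  missing <- setdiff(c("user_id", mauq_item_cols), names(data))
  if (length(missing) > 0) {
    abort(paste0("MAUQ data is missing columns: ", paste(missing, collapse = ", ")),
          class = "mhtriage_validation_error")
  }
  if (nrow(data) == 0) {
    abort("MAUQ scoring requires at least one response",
          class = "mhtriage_validation_error")
  }
  items <- as.matrix(data[mauq_item_cols])
  if (any(is.na(items)) || any(items < 1 | items > 7) || any(items != floor(items))) {
    abort("MAUQ items must be integers in 1..7",
          class = "mhtriage_validation_error")
  }
  user_means <- rowMeans(items)
  structure(
    list(
      mean = mean(user_means),
      sd = if (nrow(items) > 1) stats::sd(user_means) else 0,
      n_respondents = nrow(items),
      agreement = tibble(statement = 1:18,
                         agreement = unname(colMeans(items >= agreement_cutoff)))
    ),
    class = "mauq_summary"
  )
}

#' @export
print.mauq_summary <- function(x, ...) {
  cat(sprintf("MAUQ summary: mean %.2f (SD %.2f), n = %d respondents\n",
              x$mean, x$sd, x$n_respondents))
  full <- sum(x$agreement$agreement == 1)
  cat(sprintf("  statements with full agreement: %d of 18\n", full))
  invisible(x)
}

#' Combine subjective and objective engagement into a feasibility verdict
#'
#' High subjective and high objective engagement make the intervention
#' highly feasible, both low make it low, and a mismatch (e.g. users rate
#' the tool highly but barely use it) yields a moderate verdict.
#'
#' @param subjective_level,objective_level `"low"` or `"high"`.
#' @return `"low"`, `"moderate"` or `"high"`.
#' @examples
#' feasibility_verdict("high", "low")  # "moderate"
#' @export
feasibility_verdict <- function(subjective_level, objective_level) {
  levels_ok <- c("low", "high")
  if (!subjective_level %in% levels_ok || !objective_level %in% levels_ok) {
    abort("feasibility levels must be 'low' or 'high'",
          class = "mhtriage_validation_error")
  }
  if (subjective_level == objective_level) subjective_level else "moderate"
}

#' Full user-engagement report
#'
#' Combines objective UEIs from the event log with the MAUQ subjective
#' summary and thresholds both into a feasibility verdict: subjective
#' engagement is high when the MAUQ mean reaches `subjective_cutoff`;
#' objective engagement is high when all four objective metrics reach
#' `objective_cutoff`.
#'
#' @param events Event-log tibble.
#' @param mauq_data MAUQ response tibble (see [score_mauq()]), or `NULL`
#'   when no responses were collected.
#' @param cohort Baseline user ids (denominator for objective UEIs).
#' @param subjective_cutoff MAUQ mean at or above which subjective
#'   engagement is high (default 5, the agreement point of the 1-7 scale).
#' @param objective_cutoff Metric value at or above which an objective
#'   metric is high (default 0.5).
#' @param ... Passed to [compute_objective_uei()].
#' @return A list of class `uei_report`: `objective` (one-row tibble),
#'   `mauq` (`mauq_summary` or `NULL`), `levels` (per-metric tibble) and
#'   `verdict`.
#' @export
uei_report <- function(events, mauq_data = NULL, cohort = NULL,
                       subjective_cutoff = 5, objective_cutoff = 0.5, ...) {
  objective <- compute_objective_uei(events, cohort = cohort, ...)
  mauq <- if (!is.null(mauq_data) && nrow(mauq_data) > 0) score_mauq(mauq_data)
  metrics <- c("completion", "adherence", "compliance", "engagement")
  values <- as.numeric(objective[1, metrics])
  levels <- tibble(
    metric = c(metrics, "mauq_mean"),
    value = c(values, if (is.null(mauq)) NA_real_ else mauq$mean),
    level = c(ifelse(values >= objective_cutoff, "high", "low"),
              if (is.null(mauq)) NA_character_
              else if (mauq$mean >= subjective_cutoff) "high" else "low")
  )
  objective_level <- if (all(values >= objective_cutoff)) "high" else "low"
  verdict <- if (is.null(mauq)) {
    NA_character_
  } else {
    feasibility_verdict(levels$level[levels$metric == "mauq_mean"], objective_level)
  }
  structure(list(objective = objective, mauq = mauq, levels = levels,
                 verdict = verdict),
            class = "uei_report")
}

#' @export
print.uei_report <- function(x, ...) {
  cat("User-engagement report\n")
  cat(sprintf("  n users: %d\n", x$objective$n_users))
  for (m in c("completion", "adherence", "compliance", "engagement")) {
    lv <- x$levels$level[x$levels$metric == m]
    cat(sprintf("  %-11s %5.1f%%  (%s)\n", m, 100 * x$objective[[m]], lv))
  }
  if (!is.null(x$mauq)) {
    cat(sprintf("  MAUQ mean:  %.2f (SD %.2f), n = %d\n",
                x$mauq$mean, x$mauq$sd, x$mauq$n_respondents))
    cat(sprintf("  feasibility verdict: %s\n", x$verdict))
  }
  invisible(x)
}

#' Descriptive usage summary from an event log
#'
#' Computes the descriptive counts reported for a feasibility study:
#' per-timepoint self-assessment completion, modules performed, mean
#' modules per active user (users with at least one completed module),
#' alert activations, and — when the number of invited people is given —
#' the sign-up conversion rate.
#'
#' @param events Event-log tibble; `self_assessment` events should carry a
#'   `timepoint_index` payload column, and `module_complete` events a
#'   `module_id`.
#' @param cohort Baseline user ids; default: users with a baseline
#'   self-assessment (falling back to all users in the log).
#' @param n_invited Optional count of people invited to sign up.
#' @return A tibble with columns `metric`, `num`, `den`, `value` (the
#'   fraction or mean) and `pct` (the half-up percentage at 1 decimal,
#'   `NA` for non-fraction metrics).
#' @export
usage_summary <- function(events, cohort = NULL, n_invited = NULL) {
  validate_events(events)
  tp <- if ("timepoint_index" %in% names(events)) events$timepoint_index else NA
  sa <- events$kind == "self_assessment"
  if (is.null(cohort)) {
    cohort <- sort(unique(events$user_id[sa & (tp %na% 0) == 0]))
    if (length(cohort) == 0) cohort <- sort(unique(events$user_id))
  }
  n <- length(cohort)
  in_cohort <- events$user_id %in% cohort
  n_tp <- function(k) length(unique(events$user_id[sa & in_cohort & (tp %na% 0) == k]))
  mods <- events[events$kind == "module_complete" & in_cohort, , drop = FALSE]
  n_mod <- nrow(mods)
  n_active_mod <- length(unique(mods$user_id))
  alerts <- length(unique(events$user_id[events$kind == "alert" & in_cohort]))
  row <- function(metric, num, den) {
    value <- if (is.na(den)) num else num / den
    tibble(metric = metric, num = num, den = den, value = value,
           pct = if (is.na(den)) NA_real_ else pct(value, 1))
  }
  out <- dplyr::bind_rows(
    if (!is.null(n_invited)) row("signup_conversion", n, n_invited),
    row("baseline_selfassessment", n_tp(0), n),
    row("second_selfassessment", n_tp(1), n),
    row("third_selfassessment", n_tp(2), n),
    row("modules_performed", n_mod, NA_integer_),
    row("users_performing_modules", n_active_mod, n),
    row("modules_per_active_user",
        if (n_active_mod > 0) n_mod / n_active_mod else 0, NA_integer_),
    row("suicide_alert_users", alerts, n)
  )
  out
}
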