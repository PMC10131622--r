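# Deterministic clinical simulation profiles: item templates designed so
# that scoring + the default rule table reproduce each profile's expected
# module set, plus the expected alert behavior.

profile_row <- function(id, name, gad7, phq9, burnout, expected, alert,
                        exact = TRUE, messages = character(0)) {
  tibble(
    profile_id = id, name = name,
    gad7 = list(as.integer(gad7)), phq9 = list(as.integer(phq9)),
    burnout = list(as.integer(burnout)),
    expected_modules = list(as.integer(expected)),
    expects_alert = alert, exact_expected = exact,
    messages = list(messages)
  )
}

#' Catalog of the 17 clinical simulation profiles
#'
#' The deterministic item templates used to exercise the whole pipeline:
#' each profile encodes one simulated clinical situation (severe/moderate
#' anxiety or depression, burnout combinations, isolated symptoms,
#' suicidal thoughts, a symptom-free user, and an erratic user sending
#' insults) together with the module set the treatment algorithm is
#' expected to recommend and whether a suicide alert should fire.
#'
#' Two profiles are special: the burnout-with-moderate-depression profile
#' carries an expected set of only the two work modules even though the
#' depressive family set also fires (an acknowledged inconsistency in the
#' source scenario table, so `exact_expected` is `FALSE` and the produced
#' plan is a superset), and the erratic-behavior profile has no expected
#' plan — it is exercised through the intent-detection alerts on its
#' `messages` instead.
#'
#' @return A 17-row tibble with columns `profile_id`, `name`, `gad7`,
#'   `phq9`, `burnout` (list columns of item templates),
#'   `expected_modules` (list), `expects_alert`, `exact_expected` and
#'   `messages` (list of free-text messages the simulated user sends).
#' @examples
#' nrow(profile_catalog())  # 17
#' @export
profile_catalog <- function() {
  z7 <- rep(0, 7)
  z9 <- rep(0, 9)
  mod_anx <- c(2, 2, 2, 1, 1, 1, 1)      # GAD-7 total 10 (moderate)
  mod_dep <- c(2, 2, 2, 1, 1, 1, 1, 0, 0) # PHQ-9 total 10 (moderate)
  low_gad <- c(1, 1, 1, 0, 0, 0, 0)
  dplyr::bind_rows(
    profile_row(1, "Severe anxiety symptoms",
                rep(3, 7), z9, c(0, 0), c(2, 8, 9, 10), FALSE),
    profile_row(2, "Moderate anxiety symptoms",
                mod_anx, z9, c(0, 0), c(2, 8, 9, 10), FALSE),
    profile_row(3, "Severe depressive symptoms",
                low_gad, c(3, 3, 3, 3, 3, 3, 3, 3, 0), c(0, 0),
                c(1, 3, 4, 5, 6, 7, 10), FALSE),
    profile_row(4, "Moderate depressive symptoms without suicidal thoughts",
                low_gad, mod_dep, c(0, 0), c(1, 3, 4, 5, 6, 7, 10), FALSE),
    profile_row(5, "Work-related burnout with moderate anxiety symptoms",
                mod_anx, z9, c(4, 4), c(2, 8, 9, 10, 11, 12), FALSE),
    profile_row(6, "Work-related burnout with moderate depressive symptoms",
                low_gad, mod_dep, c(4, 4), c(11, 12), FALSE, exact = FALSE),
    profile_row(7, "Depressive symptoms with suicidal thoughts",
                low_gad, c(1, 1, 1, 0, 0, 0, 0, 0, 3), c(0, 0), 5, TRUE),
    profile_row(8, "Lack of anxiety-depressive symptoms and lack of work-related burnout",
                z7, z9, c(0, 0), integer(0), FALSE),
    profile_row(9, "Insomnia (solely)",
                z7, c(0, 0, 3, 0, 0, 0, 0, 0, 0), c(0, 0), 10, FALSE),
    profile_row(10, "Recurring concerns (solely)",
                c(0, 3, 0, 0, 0, 0, 0), z9, c(0, 0), 8, FALSE),
    profile_row(11, "Cognitive problems (solely)",
                z7, c(0, 0, 0, 0, 0, 0, 3, 0, 0), c(0, 0), 7, FALSE),
    profile_row(12, "Irritability (solely)",
                c(0, 0, 0, 0, 0, 3, 0), z9, c(0, 0), 9, FALSE),
    profile_row(13, "Depressive cognitions (solely)",
                z7, c(0, 0, 0, 0, 0, 3, 0, 0, 0), c(0, 0), 4, FALSE),
    profile_row(14, "Apathy (solely)",
                z7, c(3, 0, 0, 0, 0, 0, 0, 0, 0), c(0, 0), 3, FALSE),
    profile_row(15, "Insomnia and irritability (both solely)",
                c(0, 0, 0, 0, 0, 3, 0), c(0, 0, 3, 0, 0, 0, 0, 0, 0),
                c(0, 0), c(9, 10), FALSE),
    profile_row(16, "Depressive cognitions and recurring concerns (both solely)",
                c(0, 3, 0, 0, 0, 0, 0), c(0, 0, 0, 0, 0, 3, 0, 0, 0),
                c(0, 0), c(4, 8), FALSE),
    profile_row(17, "User with erratic behavior",
                c(3, 0, 3, 0, 3, 0, 3), c(0, 3, 0, 3, 0, 3, 0, 3, 0),
                c(6, 0), integer(0), FALSE, exact = FALSE,
                messages = c("eres una idiota", "esto no sirve, es basura"))
  )
}

#' Materialize an assessment response from a clinical profile
#'
#' @param profile A one-row slice of [profile_catalog()].
#' @param user_id Identifier for the simulated user.
#' @param timepoint_index Assessment timepoint (0 = baseline).
#' @param timestamp Assessment time (UTC); default is a fixed study date,
#'   so generation is fully deterministic.
#' @return A one-row assessment tibble with the standard item columns.
#' @examples
#' cat <- profile_catalog()
#' generate_assessment(cat[1, ], "sim01")
#' @export
generate_assessment <- function(profile, user_id,
                                timepoint_index = 0,
                                timestamp = as.POSIXct("2022-03-01 10:00:00",
                                                       tz = "UTC")) {
  stopifnot(nrow(profile) == 1)
  out <- tibble(user_id = user_id,
                timepoint_index = as.integer(timepoint_index),
                timestamp = timestamp + 14 * 86400 * timepoint_index)
  out[paste0("g", 1:7)] <- as.list(profile$gad7[[1]])
  out[paste0("p", 1:9)] <- as.list(profile$phq9[[1]])
  out[c("b1", "b2")] <- as.list(profile$burnout[[1]])
  out
}

#' Assessments for every simulation profile
#'
#' Convenience builder used by the end-to-end replay: one baseline
#' assessment per catalog profile, with `user_id` `"sim01"`..`"sim17"`.
#'
#' @inheritParams generate_assessment
#' @return A 17-row assessment tibble.
#' @export
profile_assessments <- function(timestamp = as.POSIXct("2022-03-01 10:00:00",
                                                       tz = "UTC")) {
  cat <- profile_catalog()
  purrr::map_dfr(seq_len(nrow(cat)), function(i) {
    generate_assessment(cat[i, ], sprintf("sim%02d", i), timestamp = timestamp)
  })
}
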