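# Self-assessment instruments: GAD-7, PHQ-9, and the two-item work-related
# burnout screen (emotional-exhaustion items on the MBI 0-6 frequency scale).

#' Score a GAD-7 response
#'
#' Sums the 7 anxiety items (each 0-3) and assigns both the canonical
#' four-band severity (none 0-4, mild 5-9, moderate 10-14, severe >= 15)
#' and its three-way coarsening in which mild and moderate collapse into a
#' single mild-to-moderate band (5-14).
#'
#' @param items Integer vector of exactly 7 item scores, each in 0..3.
#' @return A one-row tibble with columns `total`, `band` (ordered factor
#'   none < mild < moderate < severe) and `grouped_band` (ordered factor
#'   none < mild_to_moderate < severe).
#' @examples
#' score_gad7(c(2, 2, 2, 1, 1, 1, 1))
#' @export
score_gad7 <- function(items) {
  items <- validate_items(items, 7, 0, 3, "GAD-7")
  total <- sum(items)
  tibble(total = total,
         band = severity_band(total),
         grouped_band = collapse_band(severity_band(total)))
}

#' Score a PHQ-9 response
#'
#' Sums the 9 depression items (each 0-3) and assigns the same banding
#' scheme as [score_gad7()] (severe at total >= 15 for both scales). The
#' ninth item (thoughts of self-harm or of being better off dead) is
#' returned verbatim because it feeds the suicide-risk alert rule.
#'
#' @param items Integer vector of exactly 9 item scores, each in 0..3.
#' @return A one-row tibble with columns `total`, `band`, `grouped_band`
#'   and `item9`.
#' @examples
#' score_phq9(c(1, 1, 1, 1, 1, 1, 1, 1, 2))
#' @export
score_phq9 <- function(items) {
  items <- validate_items(items, 9, 0, 3, "PHQ-9")
  total <- sum(items)
  tibble(total = total,
         band = severity_band(total),
         grouped_band = collapse_band(severity_band(total)),
         item9 = items[9])
}

#' Score the two-item work-related burnout screen
#'
#' The screen asks two emotional-exhaustion questions rated on the 0-6
#' frequency scale; the burnout score is their arithmetic mean (range 0-6,
#' step 0.5). Burnout is flagged present when the score reaches the
#' screening threshold.
#'
#' @param items Integer vector of exactly 2 item scores, each in 0..6.
#' @param threshold Presence cutoff on the mean score; default 1.0.
#' @return A one-row tibble with columns `score` and `present`.
#' @examples
#' score_burnout(c(2, 2))
#' score_burnout(c(1, 0))  # score 0.5, below the default cutoff
#' @export
score_burnout <- function(items, threshold = 1) {
  items <- validate_items(items, 2, 0, 6, "burnout")
  score <- mean(items)
  tibble(score = score, present = score >= threshold)
}

assessment_item_cols <- c(paste0("g", 1:7), paste0("p", 1:9), "b1", "b2")

check_assessment_frame <- function(data) {
  missing <- setdiff(assessment_item_cols, names(data))
  if (length(missing) > 0) {
    abort(paste0("assessment data is missing item columns: ",
                 paste(missing, collapse = ", ")),
          class = "mhtriage_validation_error")
  }
  invisible(data)
}

#' Derive severity profiles from assessment responses
#'
#' The classifier turns raw item responses into a severity profile per row:
#' instrument totals, four-band and grouped severity bands, symptom-presence
#' flags (anxiety and depression present at total >= 5, the instruments'
#' conventional screening cutoffs; burnout at the configurable mean-score
#' cutoff) and the PHQ-9 suicidality item carried forward for alerting.
#'
#' @param data A data frame with one assessment per row: item columns
#'   `g1`..`g7`, `p1`..`p9`, `b1`, `b2`, plus any identifier columns
#'   (typically `user_id`, `timepoint_index`, `timestamp`), which are
#'   carried through.
#' @param burnout_threshold Burnout presence cutoff on the 0-6 mean score.
#' @return A tibble with the identifier columns plus `gad7_total`,
#'   `gad7_band`, `gad7_grouped_band`, `phq9_total`, `phq9_band`,
#'   `phq9_grouped_band`, `phq9_item9`, `burnout_score`, `anxiety_present`,
#'   `depression_present`, `burnout_present`.
#' @examples
#' resp <- tibble::tibble(
#'   user_id = "u1", timepoint_index = 0,
#'   g1 = 2, g2 = 2, g3 = 2, g4 = 2, g5 = 2, g6 = 2, g7 = 1,
#'   p1 = 2, p2 = 2, p3 = 2, p4 = 1, p5 = 1, p6 = 1, p7 = 1, p8 = 1, p9 = 0,
#'   b1 = 2, b2 = 2
#' )
#' classify(resp)
#' @export
classify <- function(data, burnout_threshold = 1) {
  check_assessment_frame(data)
  gad <- as.matrix(data[paste0("g", 1:7)])
  phq <- as.matrix(data[paste0("p", 1:9)])
  bo <- as.matrix(data[c("b1", "b2")])
  for (i in seq_len(nrow(data))) {
    validate_items(gad[i, ], 7, 0, 3, sprintf("row %d: GAD-7", i))
    validate_items(phq[i, ], 9, 0, 3, sprintf("row %d: PHQ-9", i))
    validate_items(bo[i, ], 2, 0, 6, sprintf("row %d: burnout", i))
  }
  id_cols <- setdiff(names(data), assessment_item_cols)
  gad_total <- as.integer(rowSums(gad))
  phq_total <- as.integer(rowSums(phq))
  burnout_score <- rowMeans(bo)
  out <- as_tibble(data[id_cols])
  out$gad7_total <- gad_total
  out$gad7_band <- severity_band(gad_total)
  out$gad7_grouped_band <- collapse_band(out$gad7_band)
  out$phq9_total <- phq_total
  out$phq9_band <- severity_band(phq_total)
  out$phq9_grouped_band <- collapse_band(out$phq9_band)
  out$phq9_item9 <- as.integer(phq[, 9])
  out$burnout_score <- burnout_score
  out$anxiety_present <- gad_total >= 5
  out$depression_present <- phq_total >= 5
  out$burnout_present <- burnout_score >= burnout_threshold
  out
}

#' Score a frame of assessment responses
#'
#' Convenience wrapper around [classify()] that keeps the raw item columns
#' alongside the derived severity profile, so downstream item-level rules
#' (the treatment-plan recommender, the alert module) can run on the same
#' tibble.
#'
#' @inheritParams classify
#' @return The input tibble plus all [classify()] output columns.
#' @export
score_assessments <- function(data, burnout_threshold = 1) {
  profile <- classify(data, burnout_threshold = burnout_threshold)
  derived <- setdiff(names(profile), names(data))
  out <- as_tibble(data)
  out[derived] <- profile[derived]
  out
}
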