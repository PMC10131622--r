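# Treatment-plan recommender: maps global severity and item-level scores to
# the 12 psychological modules via a serializable rule table.

#' The twelve psychological modules
#'
#' Catalog of the intervention's short, sequential psychological modules:
#' ten for anxiety-depressive symptoms and two for work-related stress and
#' burnout. Modules 1 and 2 carry only psychoeducation; the others add
#' weekly objectives, mindfulness, self-soothing strategies or metaphors.
#'
#' @return A 12-row tibble with columns `id`, `name`, `family`
#'   (depression / anxiety / work), `functions` (list column of content
#'   function tags) and `content_stub` (placeholder text; this package does
#'   not ship therapeutic content).
#' @examples
#' module_catalog()
#' @export
module_catalog <- function() {
  full <- c("psychoeducation", "weekly_objective", "mindfulness",
            "self_soothing", "metaphors")
  tibble(
    id = 1:12,
    name = c("depressed mood", "anxiety", "apathy-anhedonia",
             "depressive cognitions", "suicidal thoughts", "restlessness",
             "decreased concentration", "overthinking", "irritability",
             "sleep disturbance", "work-related stress", "burnout"),
    family = c("depression", "anxiety", "depression", "depression",
               "depression", "depression", "depression", "anxiety",
               "anxiety", "depression", "work", "work"),
    functions = c(list("psychoeducation", "psychoeducation"),
                  rep(list(full), 10)),
    content_stub = paste0("Module ", 1:12, " content placeholder")
  )
}

#' Default treatment-algorithm rule table
#'
#' The canonical trigger rules reconstructed from the intervention's
#' treatment algorithm, which considers both global scale severity and
#' item-level scores:
#'
#' * GAD-7 total >= 10 (moderate) activates the anxiety family set
#'   \{2, 8, 9, 10\}.
#' * PHQ-9 total >= 10 activates the depressive family set
#'   \{1, 3, 4, 5, 6, 7, 10\} (module 5 is part of the family set
#'   regardless of the suicidality item).
#' * Burnout presence activates \{11, 12\}.
#' * Item rules fire only when that instrument's family-set rule did not,
#'   so isolated symptoms still map to their module: a single PHQ-9 or
#'   GAD-7 item endorsed at >= 2 ("more than half the days") triggers the
#'   matching module, except PHQ-9 item 9 which triggers the
#'   suicidal-thoughts module at any endorsement (>= 1), mirroring the
#'   alert rule.
#'
#' The table is data, not code: it round-trips through
#' [write_rule_table()] / [read_rule_table()] so alternative clinic
#' policies can be loaded from configuration.
#'
#' @return A tibble with columns `rule_id`, `source` (one of `gad7_total`,
#'   `phq9_total`, `burnout_present`, `gad7_item`, `phq9_item`), `item`
#'   (item number, `NA` for non-item rules), `threshold` and `targets`
#'   (list column of module ids).
#' @examples
#' default_rule_table()
#' @export
default_rule_table <- function() {
  rule <- function(rule_id, source, item, threshold, targets) {
    tibble(rule_id = rule_id, source = source, item = as.integer(item),
           threshold = threshold, targets = list(as.integer(targets)))
  }
  dplyr::bind_rows(
    rule("anxiety_family", "gad7_total", NA, 10, c(2, 8, 9, 10)),
    rule("depression_family", "phq9_total", NA, 10, c(1, 3, 4, 5, 6, 7, 10)),
    rule("work_family", "burnout_present", NA, 1, c(11, 12)),
    rule("phq9_anhedonia", "phq9_item", 1, 2, 3),
    rule("phq9_depressed_mood", "phq9_item", 2, 2, 1),
    rule("phq9_sleep", "phq9_item", 3, 2, 10),
    rule("phq9_cognitions", "phq9_item", 6, 2, 4),
    rule("phq9_concentration", "phq9_item", 7, 2, 7),
    rule("phq9_restlessness", "phq9_item", 8, 2, 6),
    rule("phq9_suicidality", "phq9_item", 9, 1, 5),
    rule("gad7_anxiety_1", "gad7_item", 1, 2, 2),
    rule("gad7_anxiety_4", "gad7_item", 4, 2, 2),
    rule("gad7_anxiety_7", "gad7_item", 7, 2, 2),
    rule("gad7_overthinking_2", "gad7_item", 2, 2, 8),
    rule("gad7_overthinking_3", "gad7_item", 3, 2, 8),
    rule("gad7_restlessness", "gad7_item", 5, 2, 6),
    rule("gad7_irritability", "gad7_item", 6, 2, 9)
  )
}

validate_rule_table <- function(rules) {
  needed <- c("rule_id", "source", "item", "threshold", "targets")
  missing <- setdiff(needed, names(rules))
  if (length(missing) > 0) {
    abort(paste0("rule table is missing columns: ", paste(missing, collapse = ", ")),
          class = "mhtriage_validation_error")
  }
  sources <- c("gad7_total", "phq9_total", "burnout_present",
               "gad7_item", "phq9_item")
  bad <- setdiff(unique(rules$source), sources)
  if (length(bad) > 0) {
    abort(paste0("unknown rule source: ", paste(bad, collapse = ", ")),
          class = "mhtriage_validation_error")
  }
  targets <- unlist(rules$targets)
  if (length(targets) == 0 || any(!targets %in% 1:12)) {
    abort("rule targets must be module ids in 1..12",
          class = "mhtriage_validation_error")
  }
  invisible(rules)
}

# Evaluate the rule table against all scored assessment rows at once,
# returning an n-rows x n-rules logical matrix. Item rules are gated: they
# fire only if their instrument's family-set rule did not.
fire_rules <- function(data, rules) {
  g <- as.matrix(data[paste0("g", 1:7)])
  p <- as.matrix(data[paste0("p", 1:9)])
  gad_fam <- rep(FALSE, nrow(data))
  phq_fam <- rep(FALSE, nrow(data))
  for (i in which(is.na(rules$item))) {
    if (rules$source[i] == "gad7_total") {
      gad_fam <- gad_fam | data$gad7_total >= rules$threshold[i]
    } else if (rules$source[i] == "phq9_total") {
      phq_fam <- phq_fam | data$phq9_total >= rules$threshold[i]
    }
  }
  fired <- matrix(FALSE, nrow(data), nrow(rules),
                  dimnames = list(NULL, rules$rule_id))
  for (i in seq_len(nrow(rules))) {
    fired[, i] <- switch(rules$source[i],
      gad7_total = data$gad7_total >= rules$threshold[i],
      phq9_total = data$phq9_total >= rules$threshold[i],
      burnout_present = data$burnout_present,
      gad7_item = !gad_fam & g[, rules$item[i]] >= rules$threshold[i],
      phq9_item = !phq_fam & p[, rules$item[i]] >= rules$threshold[i]
    )
  }
  fired
}

#' Build treatment plans from scored assessments
#'
#' Applies the trigger-rule table to each scored assessment and returns one
#' plan per response: the union of all fired rules' target modules,
#' deduplicated and ordered ascending by module id (the modules are short
#' and sequential). An assessment that fires no rule yields an empty plan
#' (the algorithm's "null" outcome for symptom-free users).
#'
#' @param data A scored assessment tibble as produced by
#'   [score_assessments()] (raw item columns plus derived totals/flags).
#'   Plain item frames are scored on the fly.
#' @param rules A rule table; defaults to [default_rule_table()].
#' @return A tibble with one row per assessment: identifier columns,
#'   `module_ids` (list column of sorted module ids), `n_modules`, and
#'   `rationale` (list column naming the fired rules per plan).
#' @examples
#' resp <- tibble::tibble(
#'   user_id = "u1", timepoint_index = 0,
#'   g1 = 3, g2 = 3, g3 = 3, g4 = 3, g5 = 3, g6 = 3, g7 = 3,
#'   p1 = 0, p2 = 0, p3 = 0, p4 = 0, p5 = 0, p6 = 0, p7 = 0, p8 = 0, p9 = 0,
#'   b1 = 0, b2 = 0
#' )
#' build_plans(resp)$module_ids[[1]]  # 2 8 9 10
#' @export
build_plans <- function(data, rules = default_rule_table()) {
  validate_rule_table(rules)
  if (!"gad7_total" %in% names(data)) {
    data <- score_assessments(data)
  } else {
    check_assessment_frame(data)
    sums_g <- rowSums(as.matrix(data[paste0("g", 1:7)]))
    sums_p <- rowSums(as.matrix(data[paste0("p", 1:9)]))
    if (any(sums_g != data$gad7_total) || any(sums_p != data$phq9_total)) {
      abort("profile totals do not match item sums; profile and response are inconsistent",
            class = "mhtriage_validation_error")
    }
  }
  id_cols <- intersect(c("user_id", "timepoint_index", "timestamp"), names(data))
  fired <- fire_rules(data, rules)
  targets <- purrr::map(rules$targets, as.integer)
  out <- as_tibble(data[id_cols])
  out$module_ids <- purrr::map(seq_len(nrow(data)), function(i) {
    as.integer(sort(unique(unlist(targets[fired[i, ]]))))
  })
  out$n_modules <- lengths(out$module_ids)
  out$rationale <- purrr::map(seq_len(nrow(data)), function(i) {
    rules$rule_id[fired[i, ]]
  })
  out
}

#' Build a single treatment plan
#'
#' Scalar convenience over [build_plans()] for one response.
#'
#' @param response A one-row assessment data frame (see [classify()]).
#' @inheritParams build_plans
#' @return Integer vector of recommended module ids (possibly empty).
#' @export
build_plan <- function(response, rules = default_rule_table()) {
  stopifnot(nrow(response) == 1)
  build_plans(response, rules = rules)$module_ids[[1]]
}
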