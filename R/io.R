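# File formats: JSONL event logs, CSV assessments and MAUQ tables,
# JSON rule tables, YAML lexicons and run configuration.

format_ts <- function(ts) {
  format(as.POSIXct(ts, tz = "UTC"), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

parse_ts <- function(x) {
  as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

#' Write a usage event log as JSON lines
#'
#' One event per line, schema `{user_id, ts, kind, payload}`; payload
#' carries kind-specific fields (`timepoint_index`, `module_id`).
#'
#' @param events Event-log tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  validate_events(events)
  lines <- vapply(seq_len(nrow(events)), function(i) {
    payload <- list()
    if (!is.null(events$timepoint_index) && !is.na(events$timepoint_index[i])) {
      payload$timepoint_index <- events$timepoint_index[i]
    }
    if (!is.null(events$module_id) && !is.na(events$module_id[i])) {
      payload$module_id <- events$module_id[i]
    }
    jsonlite::toJSON(list(user_id = events$user_id[i],
                          ts = format_ts(events$ts[i]),
                          kind = events$kind[i],
                          payload = payload),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a usage event log from JSON lines
#'
#' Parses and validates one event per line; malformed lines and unknown
#' event kinds raise errors naming the offending line number. Events are
#' returned sorted by user and timestamp.
#'
#' @param path JSONL file path.
#' @return Event-log tibble with columns `user_id`, `ts` (POSIXct UTC),
#'   `kind`, `timepoint_index`, `module_id` and `line`.
#' @export
read_events <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) {
    return(tibble(user_id = character(0), ts = as.POSIXct(character(0), tz = "UTC"),
                  kind = character(0), timepoint_index = integer(0),
                  module_id = integer(0), line = integer(0)))
  }
  rows <- purrr::map(which(keep), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) {
      abort(sprintf("line %d of %s is not valid JSON: %s", i, path,
                    conditionMessage(e)),
            class = "mhtriage_parse_error")
    })
    for (field in c("user_id", "ts", "kind")) {
      if (is.null(rec[[field]])) {
        abort(sprintf("line %d of %s is missing field '%s'", i, path, field),
              class = "mhtriage_parse_error")
      }
    }
    if (!rec$kind %in% event_kinds) {
      abort(sprintf("line %d of %s has unknown event kind '%s'", i, path,
                    rec$kind),
            class = "mhtriage_validation_error")
    }
    ts <- parse_ts(rec$ts)
    if (is.na(ts)) {
      abort(sprintf("line %d of %s has unparseable timestamp '%s'", i, path,
                    rec$ts),
            class = "mhtriage_parse_error")
    }
    tibble(user_id = as.character(rec$user_id), ts = ts, kind = rec$kind,
           timepoint_index = as.integer(rec$payload$timepoint_index %||% NA),
           module_id = as.integer(rec$payload$module_id %||% NA),
           line = i)
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$user_id, .data$ts)
  validate_events(out)
  out
}

assessment_csv_cols <- c("user_id", "timepoint_index", "timestamp",
                         assessment_item_cols)

#' Write assessments to CSV
#'
#' One row per (user, timepoint) with columns `user_id`,
#' `timepoint_index`, `timestamp` (ISO-8601 UTC), `g1`..`g7`, `p1`..`p9`,
#' `b1`, `b2`.
#'
#' @param assessments Assessment tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_assessments <- function(assessments, path) {
  check_assessment_frame(assessments)
  out <- assessments[assessment_csv_cols]
  out$timestamp <- format_ts(out$timestamp)
  readr::write_csv(out, path)
  invisible(path)
}

#' Read assessments from CSV
#'
#' Strict: the file must contain exactly the columns written by
#' [write_assessments()]; extra or missing columns are rejected, and every
#' item is range-checked.
#'
#' @param path CSV file path.
#' @return Assessment tibble with a POSIXct UTC `timestamp`.
#' @export
read_assessments <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  if (!setequal(names(data), assessment_csv_cols)) {
    extra <- setdiff(names(data), assessment_csv_cols)
    missing <- setdiff(assessment_csv_cols, names(data))
    abort(paste0("assessment CSV columns do not match the schema",
                 if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")),
                 if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", "))),
          class = "mhtriage_validation_error")
  }
  data <- data[assessment_csv_cols]
  data$timestamp <- parse_ts(data$timestamp)
  data$timepoint_index <- as.integer(data$timepoint_index)
  classify(data)  # runs full item validation
  as_tibble(data)
}

#' Read MAUQ responses from CSV
#'
#' @param path CSV with columns `user_id`, `m1`..`m18`.
#' @return MAUQ tibble.
#' @export
read_mauq <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(c("user_id", mauq_item_cols), names(data))
  if (length(missing) > 0) {
    abort(paste0("MAUQ CSV is missing columns: ", paste(missing, collapse = ", ")),
          class = "mhtriage_validation_error")
  }
  as_tibble(data)
}

#' Serialize and load trigger-rule tables
#'
#' The rule table is policy data, not code: these functions round-trip it
#' through JSON so alternative clinic policies can be version-controlled
#' and loaded at run time.
#'
#' @param rules A rule table (see [default_rule_table()]).
#' @param path File path.
#' @return `write_rule_table()` returns `path` invisibly;
#'   `read_rule_table()` returns a validated rule tibble.
#' @export
write_rule_table <- function(rules, path) {
  validate_rule_table(rules)
  recs <- purrr::map(seq_len(nrow(rules)), function(i) {
    rec <- list(rule_id = rules$rule_id[i], source = rules$source[i],
                threshold = rules$threshold[i],
                targets = as.list(rules$targets[[i]]))
    if (!is.na(rules$item[i])) rec$item <- rules$item[i]
    rec
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_rule_table
#' @export
read_rule_table <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rules <- purrr::map_dfr(recs, function(r) {
    item <- unlist(r$item)
    tibble(rule_id = r$rule_id, source = r$source,
           item = if (length(item) == 1) as.integer(item) else NA_integer_,
           threshold = as.numeric(r$threshold),
           targets = list(as.integer(unlist(r$targets))))
  })
  validate_rule_table(rules)
  rules
}

#' Serialize and load intent lexicons
#'
#' @param lexicon An intent lexicon (named list of phrase vectors).
#' @param path YAML file path.
#' @return `write_lexicon()` returns `path` invisibly; `read_lexicon()`
#'   returns a validated `intent_lexicon`.
#' @export
write_lexicon <- function(lexicon, path) {
  validate_lexicon(lexicon)
  yaml::write_yaml(lapply(lexicon, as.list), path)
  invisible(path)
}

#' @rdname write_lexicon
#' @export
read_lexicon <- function(path) {
  lex <- lapply(yaml::read_yaml(path), function(x) as.character(unlist(x)))
  validate_lexicon(structure(lex, class = "intent_lexicon"))
}

#' Default run configuration
#'
#' The full set of tunable thresholds, with defaults reproducing the
#' engine's reference behavior. Unknown keys in a loaded configuration are
#' rejected.
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    instruments = list(burnout_threshold = 1),
    alerts = list(item9_threshold = 1),
    uei = list(study_days = 30, week_active_days = 5,
               completion_kind = "mauq_submitted",
               subjective_cutoff = 5, objective_cutoff = 0.5,
               agreement_cutoff = 5),
    evaluation = list(alpha = 0.05, engagement_cutoff = 0.5,
                      wilcoxon_mode = "auto")
  )
}

check_config_keys <- function(cfg, template, prefix = "") {
  unknown <- setdiff(names(cfg), names(template))
  if (length(unknown) > 0) {
    abort(paste0("unknown configuration key(s): ",
                 paste0(prefix, unknown, collapse = ", ")),
          class = "mhtriage_config_error")
  }
  for (k in names(cfg)) {
    if (is.list(template[[k]]) && !is.null(names(template[[k]]))) {
      check_config_keys(cfg[[k]], template[[k]], paste0(prefix, k, "."))
    }
  }
  invisible(cfg)
}

#' Load a run configuration from YAML
#'
#' Keys omitted from the file keep their [default_config()] values;
#' unknown keys are an error.
#'
#' @param path YAML file path.
#' @return A complete configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  template <- default_config()
  check_config_keys(cfg, template)
  modifyList(template, cfg)
}

#' @rdname read_config
#' @param config Configuration list to write.
#' @export
write_config <- function(config, path) {
  check_config_keys(config, default_config())
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Packaged study counts
#'
#' The printed headline counts of the reference feasibility study, shipped
#' as a plain-text fixture: invitations sent, baseline sign-ups,
#' second/third self-assessment completers, MAUQ respondents, users active
#' in the final study week, and modules performed.
#'
#' @param path Optional path to a counts JSON file; defaults to the
#'   packaged fixture.
#' @return A named list of counts.
#' @export
study_counts <- function(path = system.file("extdata", "study_counts.json",
                                            package = "mhtriage")) {
  jsonlite::fromJSON(path)
}

#' Expand study counts into a worked-example event log
#'
#' Builds a minimal, deterministic event log exactly consistent with a set
#' of headline counts, so the engagement analytics can recompute reported
#' rates from first principles: every baseline user signs up and completes
#' the baseline self-assessment on day 0; the counted numbers of users
#' complete the week-2 and week-4 self-assessments, respond to the MAUQ,
#' and perform the counted total of modules spread over the counted number
#' of module users.
#'
#' @param counts A counts list as returned by [study_counts()].
#' @return An event-log tibble.
#' @export
counts_to_log <- function(counts = study_counts()) {
  n <- counts$baseline
  users <- sprintf("p%03d", seq_len(n))
  ev <- list(
    tibble(user_id = users, ts = iso_ts("2022-03-01", 0, 9), kind = "signup",
           timepoint_index = NA_integer_, module_id = NA_integer_),
    tibble(user_id = users, ts = iso_ts("2022-03-01", 0, 10),
           kind = "self_assessment", timepoint_index = 0L,
           module_id = NA_integer_),
    tibble(user_id = users[seq_len(counts$second_selfassessment)],
           ts = iso_ts("2022-03-01", 14, 10), kind = "self_assessment",
           timepoint_index = 1L, module_id = NA_integer_),
    tibble(user_id = users[seq_len(counts$third_selfassessment)],
           ts = iso_ts("2022-03-01", 28, 10), kind = "self_assessment",
           timepoint_index = 2L, module_id = NA_integer_),
    tibble(user_id = users[seq_len(counts$mauq_respondents)],
           ts = iso_ts("2022-03-01", 29, 18), kind = "mauq_submitted",
           timepoint_index = NA_integer_, module_id = NA_integer_)
  )
  # spread the counted modules over the counted module users, one per day
  # starting day 1, wrapping across days
  m_users <- counts$users_performing_modules
  per_user <- rep(counts$modules_performed %/% m_users, m_users)
  extra <- counts$modules_performed %% m_users
  if (extra > 0) per_user[seq_len(extra)] <- per_user[seq_len(extra)] + 1
  for (u in seq_len(m_users)) {
    for (k in seq_len(per_user[u])) {
      ev <- c(ev, list(tibble(user_id = users[u],
                              ts = iso_ts("2022-03-01", k, 12, u),
                              kind = "module_complete",
                              timepoint_index = NA_integer_,
                              module_id = as.integer(1 + (k - 1) %% 12))))
    }
  }
  dplyr::arrange(dplyr::bind_rows(ev), .data$user_id, .data$ts)
}
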