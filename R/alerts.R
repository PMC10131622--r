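# Emergency detection: PHQ-9 item-9 rule, lexicon-based intent detection on
# free text, and the emergency-response payload.

alert_actions_item9 <- c("recommend_emergency_department",
                         "provide_emergency_phone", "notify_team")

#' Default bilingual intent lexicon
#'
#' Deterministic phrase lists for the two intents the engine recognizes:
#' `suicidal` (triggers the full emergency response) and `insult`
#' (logged, no emergency action). Matching is case-insensitive and
#' diacritic-folded, so "suicidarme" matches "Suicidárme". The lists ship
#' bilingual (Spanish/English) and are plain data: edit, extend or replace
#' them via [read_lexicon()] / [write_lexicon()].
#'
#' @return A named list of character vectors, class `intent_lexicon`.
#'   Intent order is matching priority.
#' @examples
#' names(default_lexicon())
#' @export
default_lexicon <- function() {
  lex <- list(
    suicidal = c(
      "quiero morir", "quiero morirme", "me quiero matar", "quiero matarme",
      "quiero suicidarme", "suicidarme", "voy a suicidarme",
      "quitarme la vida", "no quiero vivir", "no quiero seguir viviendo",
      "acabar con mi vida", "hacerme dano",
      "kill myself", "want to die", "end my life", "take my own life",
      "suicide", "better off dead", "hurt myself", "self harm"
    ),
    insult = c(
      "idiota", "estupido", "estupida", "imbecil", "inutil", "basura",
      "vete a la mierda", "eres una mierda",
      "stupid", "idiot", "useless", "shut up", "you suck", "piece of junk"
    )
  )
  structure(lex, class = "intent_lexicon")
}

fold_text <- function(x) {
  stringi::stri_trans_general(tolower(x), "Latin-ASCII")
}

validate_lexicon <- function(lexicon) {
  if (length(lexicon) == 0) {
    abort("intent lexicon is empty", class = "mhtriage_config_error")
  }
  empty <- names(lexicon)[lengths(lexicon) == 0]
  if (is.null(names(lexicon)) || any(!nzchar(names(lexicon))) || length(empty) > 0) {
    abort("every lexicon intent must be named and non-empty",
          class = "mhtriage_config_error")
  }
  invisible(lexicon)
}

#' Detect intents in free-text messages
#'
#' Scans each message for lexicon phrases after lower-casing and folding
#' diacritics to ASCII (the only text normalization applied; there is no
#' stemming or language model). The first matching intent in lexicon order
#' wins, and within an intent the first listed phrase found in the text is
#' reported.
#'
#' @param text Character vector of UTF-8 messages.
#' @param lexicon An intent lexicon; defaults to [default_lexicon()].
#' @return A tibble with one row per input message: `text`, `intent`
#'   (`NA` when nothing matched) and `phrase` (the matched lexicon entry).
#' @examples
#' detect_intent(c("hola, estoy bien", "No quiero vivir"))
#' @export
detect_intent <- function(text, lexicon = default_lexicon()) {
  validate_lexicon(lexicon)
  folded <- fold_text(text)
  match_one <- function(msg) {
    for (intent in names(lexicon)) {
      for (phrase in fold_text(lexicon[[intent]])) {
        if (nzchar(phrase) && grepl(phrase, msg, fixed = TRUE)) {
          return(c(intent, phrase))
        }
      }
    }
    c(NA_character_, NA_character_)
  }
  hits <- vapply(folded, match_one, character(2), USE.NAMES = FALSE)
  tibble(text = text, intent = hits[1, ], phrase = hits[2, ])
}

#' Screen assessments for suicide-risk alerts
#'
#' Applies the item-level emergency rule: any response whose PHQ-9 item 9
#' (suicidal thoughts) reaches the alert threshold emits exactly one alert
#' event recommending the emergency department, providing the emergency
#' phone resources and notifying the care team. The default threshold of 1
#' alerts on any endorsement of the item.
#'
#' @param data An assessment frame (raw items or [score_assessments()]
#'   output).
#' @param threshold Minimum item-9 score that triggers the alert.
#' @return A tibble of alert events (possibly zero rows) with columns
#'   `user_id`, `timepoint_index`, `timestamp` (when present in the
#'   input), `source` (`"item9"`), `trigger` (the item value) and
#'   `actions` (list column).
#' @examples
#' resp <- tibble::tibble(
#'   user_id = "u7", timepoint_index = 0,
#'   g1 = 0, g2 = 0, g3 = 0, g4 = 0, g5 = 0, g6 = 0, g7 = 0,
#'   p1 = 1, p2 = 1, p3 = 1, p4 = 0, p5 = 0, p6 = 0, p7 = 0, p8 = 0, p9 = 3,
#'   b1 = 0, b2 = 0
#' )
#' check_assessment(resp)
#' @export
check_assessment <- function(data, threshold = 1) {
  if (!"phq9_item9" %in% names(data)) data <- score_assessments(data)
  hit <- data$phq9_item9 >= threshold
  id_cols <- intersect(c("user_id", "timepoint_index", "timestamp"), names(data))
  out <- as_tibble(data[hit, id_cols, drop = FALSE])
  out$source <- rep("item9", sum(hit))
  out$trigger <- as.character(data$phq9_item9[hit])
  out$actions <- rep(list(alert_actions_item9), sum(hit))
  out
}

#' Screen free-text messages for alert intents
#'
#' Runs [detect_intent()] over a message frame and converts matches into
#' alert events. Suicidal matches carry the full emergency action set;
#' insult matches are logged with a team notification only.
#'
#' @param messages A data frame with columns `user_id`, `timestamp`
#'   (optional) and `text`.
#' @param lexicon An intent lexicon.
#' @return A tibble of alert events with `source = "nlp_intent"`, `intent`,
#'   `trigger` (the matched phrase) and `actions`.
#' @export
check_messages <- function(messages, lexicon = default_lexicon()) {
  hits <- detect_intent(messages$text, lexicon)
  keep <- !is.na(hits$intent)
  id_cols <- intersect(c("user_id", "timestamp"), names(messages))
  out <- as_tibble(messages[keep, id_cols, drop = FALSE])
  out$source <- rep("nlp_intent", sum(keep))
  out$intent <- hits$intent[keep]
  out$trigger <- hits$phrase[keep]
  out$actions <- purrr::map(out$intent, function(x) {
    if (identical(x, "suicidal")) alert_actions_item9 else "notify_team"
  })
  out
}

#' Default emergency resources
#'
#' @return A list with `phones` (emergency and suicide-prevention lines)
#'   and `locations` (guidance on nearby emergency departments).
#' @export
default_emergency_resources <- function() {
  list(
    phones = list(
      list(label = "Health emergencies", number = "112"),
      list(label = "Suicide prevention line", number = "024")
    ),
    locations = list(
      list(label = "Nearest hospital emergency department",
           instruction = "Go immediately to the nearest emergency department.")
    )
  )
}

#' Emergency-response payload
#'
#' Returns the configured emergency resources (phone numbers and hospital
#' guidance) verbatim, as handed to a user alongside an alert.
#'
#' @param resources Resource configuration; defaults to
#'   [default_emergency_resources()].
#' @return The resource list, unchanged.
#' @export
emergency_payload <- function(resources = default_emergency_resources()) {
  if (is.null(resources) || length(resources$phones %||% list()) == 0) {
    abort("emergency resources must configure at least one phone entry",
          class = "mhtriage_config_error")
  }
  resources
}
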