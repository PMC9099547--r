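# The smart speaker's three-question exhaustion conversation, modelled as a
# deterministic state machine over normalized text tokens.  Speech capture
# and recognition are out of scope: the machine consumes lowercase answer
# tokens (or NA for silence) and records a full transcript.

#' Default dialogue script
#'
#' Three questions asked in order: an availability gate (yes/no), the CES-D
#' exhaustion item (yes/no), and the frequency item (always/sometimes/rare).
#' Answer options are prompted with each question; each question is repeated
#' at most `max_retries_per_question` times after an unrecognized or silent
#' answer.
#'
#' @param max_retries_per_question integer, default 1 (single fallback
#'   repeat).
#' @param synonyms optional named character vector mapping raw tokens to
#'   canonical ones (e.g. `c(yeah = "yes")`); default empty (strict).
#' @return a `dialogue_script` object.
#' @export
dialogue_script <- function(max_retries_per_question = 1L, synonyms = c()) {
  structure(list(
    questions = list(
      availability = list(
        prompt = paste("Are you available to answer a few questions right",
                       "now? Please answer yes or no."),
        vocab = c("yes", "no")),
      exhaustion = list(
        prompt = paste("Do you feel that everything you did was an effort,",
                       "or you could not get going in the last week?",
                       "Please answer yes or no."),
        vocab = c("yes", "no")),
      frequency = list(
        prompt = paste("How often in the last week did you feel this way?",
                       "Please answer always, sometimes, or rare."),
        vocab = c("always", "sometimes", "rare"))
    ),
    max_retries_per_question = as.integer(max_retries_per_question),
    synonyms = synonyms
  ), class = "dialogue_script")
}

FRAIL_FREQUENCY_TOKENS <- c("always", "sometimes")

#' Run the exhaustion dialogue
#'
#' Deterministic: identical answer sequences produce identical outcomes and
#' transcripts.  Any question failing `1 + max_retries_per_question`
#' attempts (unrecognized token or silence), or an availability answer of
#' `"no"`, leaves the dialogue not completed.  The frequency question is
#' asked regardless of the exhaustion yes/no answer; categorization uses
#' only the frequency token.
#'
#' @param script a `dialogue_script`.
#' @param answer_source either a character vector of tokens consumed in
#'   order (exhaustion of the vector means silence), or a
#'   `function(question_id, attempt)` returning a token or `NA` for silence.
#' @return a `dialogue_outcome`: list with `completed`, `answers` (named
#'   list), `exhaustion_positive` (`NA` unless completed), `inconsistent`
#'   (exhaustion "no" but frail-range frequency) and `transcript`
#'   (`data.frame` of `role`, `question_id`, `text` turns).
#' @export
run_dialogue <- function(script = dialogue_script(), answer_source) {
  stopifnot(inherits(script, "dialogue_script"))
  if (is.character(answer_source) || (length(answer_source) == 0L &&
                                      !is.function(answer_source))) {
    tokens <- as.character(answer_source)
    cursor <- 0L
    answer_source <- function(question_id, attempt) {
      cursor <<- cursor + 1L
      if (cursor > length(tokens)) NA_character_ else tokens[cursor]
    }
  }
  stopifnot(is.function(answer_source))
  tr_role <- tr_qid <- tr_text <- character()
  say <- function(role, qid, text) {
    tr_role[length(tr_role) + 1L] <<- role
    tr_qid[length(tr_qid) + 1L] <<- qid
    tr_text[length(tr_text) + 1L] <<- if (is.na(text)) "<silence>" else text
  }
  answers <- list()
  completed <- TRUE
  for (qid in names(script$questions)) {
    q <- script$questions[[qid]]
    got <- NA_character_
    for (attempt in seq_len(1L + script$max_retries_per_question)) {
      say("speaker", qid, q$prompt)
      raw <- answer_source(qid, attempt)
      raw <- if (is.null(raw) || is.na(raw)) NA_character_ else
        tolower(trimws(as.character(raw)))
      say("user", qid, raw)
      if (!is.na(raw) && raw %in% names(script$synonyms)) {
        raw <- unname(script$synonyms[[raw]])
      }
      if (!is.na(raw) && raw %in% q$vocab) {
        got <- raw
        break
      }
    }
    if (is.na(got)) {
      completed <- FALSE
      break
    }
    answers[[qid]] <- got
    if (qid == "availability" && got == "no") {
      completed <- FALSE
      say("speaker", qid, "No problem, we can talk another time.")
      break
    }
  }
  exhaustion_positive <- if (completed) {
    answers$frequency %in% FRAIL_FREQUENCY_TOKENS
  } else NA
  inconsistent <- isTRUE(completed) &&
    identical(answers$exhaustion, "no") &&
    answers$frequency %in% FRAIL_FREQUENCY_TOKENS
  if (inconsistent) {
    say("speaker", "frequency",
        "[note] frequency answer in the frail range despite exhaustion 'no'")
  }
  structure(list(completed = completed, answers = answers,
                 exhaustion_positive = exhaustion_positive,
                 inconsistent = inconsistent,
                 transcript = data.frame(role = tr_role, question_id = tr_qid,
                                         text = tr_text,
                                         stringsAsFactors = FALSE)),
            class = "dialogue_outcome")
}

#' @export
print.dialogue_outcome <- function(x, ...) {
  cat("<dialogue_outcome>",
      if (x$completed) "completed," else "not completed,",
      "exhaustion:", score_exhaustion(x), "\n")
  invisible(x)
}

#' Score a dialogue outcome as a frailty criterion flag
#'
#' `"positive"` iff the dialogue completed with frequency `"sometimes"` or
#' `"always"`; `"negative"` iff it completed with `"rare"`; `"missing"`
#' otherwise (declined, silent, or unrecognized past the retry budget).
#'
#' @param outcome a `dialogue_outcome`.
#' @return `"positive"`, `"negative"` or `"missing"`.
#' @export
score_exhaustion <- function(outcome) {
  stopifnot(inherits(outcome, "dialogue_outcome"))
  if (!isTRUE(outcome$completed)) return("missing")
  if (outcome$answers$frequency %in% FRAIL_FREQUENCY_TOKENS) "positive"
  else "negative"
}

#' Percent agreement between recognized and reference answer tokens
#'
#' @param recognized character vector of tokens the speaker recognized.
#' @param reference equal-length character vector of reference tokens (e.g.
#'   transcribed from audio recordings).
#' @return percentage in \[0, 100\].
#' @export
percent_recognition_agreement <- function(recognized, reference) {
  if (length(recognized) != length(reference)) {
    stop("recognized and reference must have equal length", call. = FALSE)
  }
  if (length(recognized) == 0L) {
    stop("percent agreement undefined for empty input", call. = FALSE)
  }
  100 * mean(recognized == reference)
}

#' Serialize a dialogue transcript as JSON Lines
#' @param outcome a `dialogue_outcome`.
#' @param path destination file.
#' @export
write_transcript <- function(outcome, path) {
  stopifnot(inherits(outcome, "dialogue_outcome"))
  tr <- outcome$transcript
  lines <- vapply(seq_len(nrow(tr)), function(i) {
    jsonlite::toJSON(as.list(tr[i, ]), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
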