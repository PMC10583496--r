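#' Speech task identifiers and task types
#'
#' The protocol comprises five speech elicitation tasks: two expository tasks
#' (describe an important person, ET1; describe a meaningful place, ET2) and
#' three picture description tasks (PDT1-PDT3, e.g. the Cookie Theft picture).
#'
#' @return `speech_tasks()` returns the five task identifiers in protocol
#'   order. `task_type()` maps task identifiers to `"expository"` or
#'   `"picture"`.
#' @examples
#' speech_tasks()
#' task_type(c("ET1", "PDT3"))
#' @export
speech_tasks <- function() {
  c("ET1", "ET2", "PDT1", "PDT2", "PDT3")
}

#' @rdname speech_tasks
#' @param task_id character vector of task identifiers.
#' @export
task_type <- function(task_id) {
  bad <- setdiff(unique(task_id), speech_tasks())
  if (length(bad) > 0) {
    abort(paste0("Unknown task id(s): ", paste(bad, collapse = ", ")))
  }
  ifelse(startsWith(task_id, "ET"), "expository", "picture")
}

#' The sixteen lexical-semantic speech features
#'
#' Names of the sixteen features computed per transcript, in reporting order:
#' raw word count; nine proportion features scaled per 100 words (fillers,
#' empty words, definite/indefinite articles, pronouns, nouns, verbs,
#' determiners, content words); mean log10 word frequency per million;
#' type-token ratio; Honore statistic; Brunet index; and two timing features
#' (speech rate and filler rate, per second).
#'
#' @return character vector of length 16.
#' @examples
#' speech_feature_names()
#' @export
speech_feature_names <- function() {
  c(
    "word_count", "fillers", "empty_words", "definite_articles",
    "indefinite_articles", "pronouns", "nouns", "verbs", "determiners",
    "content_words", "frequency", "type_token_ratio", "honore_statistic",
    "brunet_index", "speech_rate", "filler_rate"
  )
}

# Penn Treebank tag groups used by the proportion features
PRONOUN_TAGS <- c("PRP", "PRP$", "WP", "WP$")
DETERMINER_TAGS <- c("DT", "PDT", "WDT")

duration_columns <- function() paste0("duration_", speech_tasks())
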