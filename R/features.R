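word_tokens <- function(tokens) {
  tokens[tokens$kind == "word", , drop = FALSE]
}

#' Lexical profile of a transcript: N, V, V1
#'
#' Counts the quantities underlying the lexical-richness features: `n_tokens`
#' (N, the number of lexical word tokens — fillers included, partial words and
#' nonwords excluded), `n_types` (V, distinct word forms) and `n_hapax` (V1,
#' types occurring exactly once, the hapax legomena).
#'
#' @param tokens a token tibble (columns `surface`, `kind`) as produced by
#'   [tokenize_transcript()].
#' @return one-row tibble with integer columns `n_tokens`, `n_types`,
#'   `n_hapax`.
#' @examples
#' lexical_profile(tokenize_transcript("the cat sat on the mat"))
#' @export
lexical_profile <- function(tokens) {
  w <- word_tokens(tokens)
  if (nrow(w) == 0) abort("empty transcript: no word tokens")
  counts <- table(w$surface)
  tibble::tibble(
    n_tokens = nrow(w),
    n_types = length(counts),
    n_hapax = sum(counts == 1L)
  )
}

#' Lexical diversity and richness statistics
#'
#' Closed-form indices computed from a transcript's lexical profile
#' (N word tokens, V types, V1 hapax legomena):
#' \describe{
#'   \item{`type_token_ratio()`}{V / N, in (0, 1]. Sensitive to text length.}
#'   \item{`honore_statistic()`}{Honore's R = 100 log(N) / (1 - V1/V); grows
#'     with the proportion of once-used words. Undefined when every type is a
#'     hapax (V1 = V): returns `NaN` with a warning.}
#'   \item{`brunet_index()`}{Brunet's W = N^(V^-0.165); a length-robust
#'     diversity index where lower values indicate richer vocabulary. Typical
#'     spontaneous-speech values fall in the 10-15 range.}
#' }
#' All three are vectorized over their arguments.
#'
#' @param n_tokens,n_types,n_hapax integer vectors: word-token count N, type
#'   count V, hapax count V1 (see [lexical_profile()]).
#' @param constant the Brunet exponent constant; 0.165 is the standard choice.
#' @return numeric vector.
#' @examples
#' type_token_ratio(6, 5)
#' honore_statistic(10, 7, 5)
#' brunet_index(100, 50)
#' @export
type_token_ratio <- function(n_tokens, n_types) {
  stopifnot(all(n_tokens >= 1))
  n_types / n_tokens
}

#' @rdname type_token_ratio
#' @export
honore_statistic <- function(n_tokens, n_types, n_hapax) {
  stopifnot(all(n_tokens >= 1))
  out <- rep(NaN, length(n_tokens))
  ok <- n_hapax < n_types
  if (any(!ok)) {
    warn("Honore statistic undefined when all types are hapax (V1 = V); returning NaN.")
  }
  out[ok] <- 100 * log(n_tokens[ok]) / (1 - n_hapax[ok] / n_types[ok])
  out
}

#' @rdname type_token_ratio
#' @export
brunet_index <- function(n_tokens, n_types, constant = 0.165) {
  stopifnot(all(n_tokens >= 1))
  n_tokens^(n_types^(-constant))
}

#' Mean log10 word frequency of a transcript
#'
#' The token-weighted mean (every spoken word token contributes once) of
#' log10 of each word's per-million corpus frequency, looked up in the
#' lexicon's frequency table; out-of-vocabulary words receive the lexicon's
#' floor frequency. Higher values mean the speaker used more common words.
#'
#' @inheritParams lexical_profile
#' @param lexicons a [lexicon_resources()] object.
#' @return numeric scalar.
#' @export
mean_log_frequency <- function(tokens, lexicons) {
  w <- word_tokens(tokens)
  if (nrow(w) == 0) abort("empty transcript: no word tokens")
  mean(log10(per_million_frequency(w$surface, lexicons)))
}

resolve_tags <- function(tokens, tags = NULL, tagger = NULL) {
  w <- word_tokens(tokens)
  if (is.null(tags) && "tag" %in% names(tokens)) {
    tags <- w$tag
  }
  if (is.null(tags) && !is.null(tagger)) {
    tags <- tagger(w$surface)
  }
  if (is.null(tags)) {
    abort("No part-of-speech tags: supply `tags`, a `tag` column, or a `tagger`.")
  }
  if (length(tags) != nrow(w) || anyNA(tags)) {
    abort("Untagged word token: tags must cover every word token, one tag each.")
  }
  tags
}

#' Proportion features scaled per 100 words
#'
#' The nine category-count features, each expressed as
#' 100 x (category count / N) where N is the word-token count:
#' fillers and empty words by lexicon membership; definite article (surface
#' "the"); indefinite articles ("a", "an"); pronouns (Penn Treebank tags PRP,
#' PRP$, WP, WP$); nouns (tags starting NN); verbs (tags starting VB);
#' determiners (tags DT, PDT, WDT); and content words (word tokens whose
#' surface is not in the stop-word list).
#'
#' @inheritParams mean_log_frequency
#' @param tags character vector of Penn Treebank tags, one per word token (in
#'   token order). May be omitted if `tokens` carries a `tag` column or
#'   `tagger` is given.
#' @param tagger a function mapping a character vector of word surfaces to an
#'   equal-length vector of Penn Treebank tags, e.g. [baseline_tagger()].
#' @return one-row tibble with the nine per-100-word proportions.
#' @export
proportion_features <- function(tokens, lexicons, tags = NULL, tagger = NULL) {
  w <- word_tokens(tokens)
  if (nrow(w) == 0) abort("empty transcript: no word tokens")
  tags <- resolve_tags(tokens, tags, tagger)
  n <- nrow(w)
  per100 <- function(count) 100 * count / n
  tibble::tibble(
    fillers = per100(sum(w$surface %in% lexicons$fillers)),
    empty_words = per100(sum(w$surface %in% lexicons$empty_words)),
    definite_articles = per100(sum(w$surface == "the")),
    indefinite_articles = per100(sum(w$surface %in% c("a", "an"))),
    pronouns = per100(sum(tags %in% PRONOUN_TAGS)),
    nouns = per100(sum(startsWith(tags, "NN"))),
    verbs = per100(sum(startsWith(tags, "VB"))),
    determiners = per100(sum(tags %in% DETERMINER_TAGS)),
    content_words = per100(sum(!(w$surface %in% lexicons$stop_words)))
  )
}

#' Timing features: speech rate and filler rate
#'
#' `speech_rate` counts every produced token — words, nonwords and partial
#' words alike — divided by the elapsed speaking time in seconds; it is the
#' only feature in which partial words and nonwords participate.
#' `filler_rate` is the number of filler word tokens divided by the same
#' elapsed time.
#'
#' @inheritParams mean_log_frequency
#' @param duration_seconds positive elapsed speaking time in seconds.
#' @return one-row tibble with columns `speech_rate` and `filler_rate`
#'   (tokens per second).
#' @export
rate_features <- function(tokens, duration_seconds, lexicons) {
  if (!is.numeric(duration_seconds) || length(duration_seconds) != 1 ||
      is.na(duration_seconds) || duration_seconds <= 0) {
    abort("`duration_seconds` must be a single positive number.")
  }
  w <- word_tokens(tokens)
  tibble::tibble(
    speech_rate = nrow(tokens) / duration_seconds,
    filler_rate = sum(w$surface %in% lexicons$fillers) / duration_seconds
  )
}

#' Extract the sixteen lexical-semantic features from one transcript
#'
#' Computes the full feature vector for a single participant x task
#' transcript: raw word count, the nine per-100-word proportion features, mean
#' log10 word frequency, type-token ratio, Honore statistic, Brunet index, and
#' the two per-second timing features. Deterministic given the tokens, the
#' lexicons, and the tag assignment.
#'
#' @inheritParams proportion_features
#' @inheritParams rate_features
#' @return one-row tibble with exactly the 16 columns of
#'   [speech_feature_names()], in that order.
#' @examples
#' toks <- tokenize_transcript("um the cat sat on the mat")
#' extract_features(toks, duration_seconds = 4, tagger = baseline_tagger)
#' @export
extract_features <- function(tokens, duration_seconds,
                             lexicons = lexicon_resources(),
                             tags = NULL, tagger = NULL) {
  prof <- lexical_profile(tokens)
  out <- dplyr::bind_cols(
    tibble::tibble(word_count = as.numeric(prof$n_tokens)),
    proportion_features(tokens, lexicons, tags, tagger),
    tibble::tibble(
      frequency = mean_log_frequency(tokens, lexicons),
      type_token_ratio = type_token_ratio(prof$n_tokens, prof$n_types),
      honore_statistic = honore_statistic(
        prof$n_tokens, prof$n_types, prof$n_hapax
      ),
      brunet_index = brunet_index(prof$n_tokens, prof$n_types)
    ),
    rate_features(tokens, duration_seconds, lexicons)
  )
  out[, speech_feature_names()]
}

#' Extract features for every transcript in a corpus
#'
#' Runs [extract_features()] over all participant x task transcripts of a
#' [read_corpus()] result (or equivalent list) and returns the long-format
#' feature matrix used by the reliability analyses. Durations are taken from
#' the metadata's `duration_*` columns; the participant group label comes from
#' the metadata `group` column when present, otherwise every participant is
#' labelled `"full"`.
#'
#' @param corpus a `speech_corpus` (list with `tokens` and `metadata`).
#' @inheritParams proportion_features
#' @return tibble with columns `participant_id`, `task_id`, `feature_name`,
#'   `value`, `group`: 16 rows per participant x task.
#' @export
extract_corpus_features <- function(corpus, lexicons = lexicon_resources(),
                                    tagger = NULL) {
  meta <- corpus$metadata
  if (nrow(meta) == 0) abort("Corpus has no admitted participants.")
  groups <- if ("group" %in% names(meta)) {
    setNames(as.character(meta$group), meta$participant_id)
  } else {
    setNames(rep("full", nrow(meta)), meta$participant_id)
  }
  durs <- meta |>
    dplyr::select("participant_id", dplyr::all_of(duration_columns())) |>
    tidyr::pivot_longer(
      -"participant_id",
      names_to = "task_id", names_prefix = "duration_",
      values_to = "duration_seconds"
    )
  corpus$tokens |>
    dplyr::group_by(.data$participant_id, .data$task_id) |>
    dplyr::group_modify(function(toks, key) {
      dur <- durs$duration_seconds[
        durs$participant_id == key$participant_id &
          durs$task_id == key$task_id
      ]
      extract_features(toks, dur, lexicons, tagger = tagger) |>
        tidyr::pivot_longer(
          dplyr::everything(),
          names_to = "feature_name", values_to = "value"
        )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(group = unname(groups[.data$participant_id]))
}
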