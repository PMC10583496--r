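# Classic English stop-word list (127 words), the de-facto standard list used
# throughout computational text analysis. Configurable: pass your own set via
# lexicon_resources(stop_words = ...).
STOP_WORDS_EN <- c(
  "i", "me", "my", "myself", "we", "our", "ours", "ourselves", "you", "your",
  "yours", "yourself", "yourselves", "he", "him", "his", "himself", "she",
  "her", "hers", "herself", "it", "its", "itself", "they", "them", "their",
  "theirs", "themselves", "what", "which", "who", "whom", "this", "that",
  "these", "those", "am", "is", "are", "was", "were", "be", "been", "being",
  "have", "has", "had", "having", "do", "does", "did", "doing", "a", "an",
  "the", "and", "but", "if", "or", "because", "as", "until", "while", "of",
  "at", "by", "for", "with", "about", "against", "between", "into", "through",
  "during", "before", "after", "above", "below", "to", "from", "up", "down",
  "in", "out", "on", "off", "over", "under", "again", "further", "then",
  "once", "here", "there", "when", "where", "why", "how", "all", "any",
  "both", "each", "few", "more", "most", "other", "some", "such", "no", "nor",
  "not", "only", "own", "same", "so", "than", "too", "very", "s", "t", "can",
  "will", "just", "don", "should", "now"
)

DEFAULT_FILLERS <- c("um", "uh", "hmm", "er", "eh", "mm")
DEFAULT_EMPTY_WORDS <- c(
  "thing", "things", "stuff", "place", "something", "someone", "anything"
)

#' Lexicon resources for feature extraction
#'
#' Bundles the word lists and the word-frequency table the feature extractor
#' consults: hesitation fillers (e.g. um, uh, hmm), semantically empty nouns
#' (e.g. thing, stuff, place), a stop-word list defining the complement of the
#' content words, and a word -> occurrences-per-million frequency table.
#' Words absent from the frequency table receive the floor `oov_frequency`.
#'
#' The defaults are documented supersets of the canonical examples; real
#' studies should substitute project-specific lists and a frequency table from
#' a large reference corpus.
#'
#' @param fillers,empty_words,stop_words character vectors (lowercased
#'   internally).
#' @param frequency named numeric vector: per-million frequency by word, all
#'   values > 0. May be empty, in which case every word falls back to
#'   `oov_frequency`.
#' @param oov_frequency positive per-million floor assigned to words missing
#'   from `frequency`; defaults to the table minimum (or 0.01 for an empty
#'   table). Must not exceed the minimum observed frequency.
#' @return an object of class `lexicon_resources` (a list with the five
#'   fields above).
#' @examples
#' lex <- lexicon_resources(frequency = c(the = 60000, cat = 25))
#' lex$oov_frequency
#' @export
lexicon_resources <- function(fillers = DEFAULT_FILLERS,
                              empty_words = DEFAULT_EMPTY_WORDS,
                              stop_words = STOP_WORDS_EN,
                              frequency = numeric(),
                              oov_frequency = NULL) {
  if (length(frequency) > 0) {
    if (is.null(names(frequency)) || any(!nzchar(names(frequency)))) {
      abort("`frequency` must be a named numeric vector (word -> per-million).")
    }
    if (any(frequency <= 0)) abort("Frequency values must be > 0.")
    names(frequency) <- tolower(names(frequency))
  }
  if (is.null(oov_frequency)) {
    oov_frequency <- if (length(frequency) > 0) min(frequency) else 0.01
  }
  if (oov_frequency <= 0) abort("`oov_frequency` must be > 0.")
  if (length(frequency) > 0 && oov_frequency > min(frequency)) {
    abort("`oov_frequency` must not exceed the minimum observed frequency.")
  }
  structure(
    list(
      fillers = unique(tolower(fillers)),
      empty_words = unique(tolower(empty_words)),
      stop_words = unique(tolower(stop_words)),
      frequency = frequency,
      oov_frequency = oov_frequency
    ),
    class = "lexicon_resources"
  )
}

#' @export
print.lexicon_resources <- function(x, ...) {
  cat(
    "<lexicon_resources>\n",
    "  fillers: ", length(x$fillers),
    " | empty words: ", length(x$empty_words),
    " | stop words: ", length(x$stop_words),
    " | frequency entries: ", length(x$frequency),
    " (oov floor ", format(x$oov_frequency), " per million)\n",
    sep = ""
  )
  invisible(x)
}

#' Read lexicon files from disk
#'
#' `read_word_list()` reads a one-token-per-line UTF-8 word list.
#' `read_frequency_table()` reads a two-column tab-separated table
#' (word, per-million frequency) with no header.
#'
#' @param path file path.
#' @return `read_word_list()`: a lowercased character vector.
#'   `read_frequency_table()`: a named numeric vector.
#' @export
read_word_list <- function(path) {
  x <- readr::read_lines(path)
  x <- tolower(trimws(x))
  unique(x[nzchar(x)])
}

#' @rdname read_word_list
#' @export
read_frequency_table <- function(path) {
  tbl <- readr::read_tsv(
    path,
    col_names = c("word", "per_million"),
    col_types = readr::cols(
      word = readr::col_character(),
      per_million = readr::col_double()
    ),
    progress = FALSE
  )
  setNames(tbl$per_million, tolower(tbl$word))
}

per_million_frequency <- function(words, lexicons) {
  freq <- unname(lexicons$frequency[words])
  freq[is.na(freq)] <- lexicons$oov_frequency
  freq
}

# Closed-class lookup for the baseline tagger
BASELINE_TAG_LEXICON <- c(
  the = "DT", a = "DT", an = "DT", this = "DT", that = "DT", these = "DT",
  those = "DT", some = "DT", any = "DT", each = "DT", every = "DT",
  all = "PDT", both = "PDT", half = "PDT", which = "WDT",
  i = "PRP", you = "PRP", he = "PRP", she = "PRP", it = "PRP", we = "PRP",
  they = "PRP", me = "PRP", him = "PRP", them = "PRP", us = "PRP",
  myself = "PRP", himself = "PRP", herself = "PRP", itself = "PRP",
  themselves = "PRP",
  my = "PRP$", your = "PRP$", his = "PRP$", her = "PRP$", its = "PRP$",
  our = "PRP$", their = "PRP$",
  who = "WP", whom = "WP", whose = "WP$",
  is = "VBZ", are = "VBP", was = "VBD", were = "VBD", am = "VBP",
  be = "VB", been = "VBN", being = "VBG", have = "VBP", has = "VBZ",
  had = "VBD", do = "VBP", does = "VBZ", did = "VBD", will = "MD",
  can = "MD", could = "MD", would = "MD", should = "MD", may = "MD",
  and = "CC", or = "CC", but = "CC",
  of = "IN", in1 = "IN", on = "IN", at = "IN", by = "IN", with = "IN",
  from = "IN", to = "TO", into = "IN", over = "IN", under = "IN",
  um = "UH", uh = "UH", hmm = "UH", er = "UH", eh = "UH", mm = "UH",
  oh = "UH", well = "UH",
  not = "RB", very = "RB", too = "RB", so = "RB", then = "RB",
  there = "EX", here = "RB", now = "RB"
)
names(BASELINE_TAG_LEXICON)[names(BASELINE_TAG_LEXICON) == "in1"] <- "in"

#' Baseline rule-based Penn Treebank tagger
#'
#' A deliberately simple tagger satisfying the tagging contract (character
#' vector of word surfaces in, equal-length vector of Penn Treebank tags out):
#' closed-class words by lookup, open-class words by suffix heuristics
#' (-ing/-ed -> verb forms, -ly -> adverb, -s -> plural noun), default NN.
#' It exists so a corpus can be processed end to end without an external NLP
#' stack; for linguistic research substitute a trained tagger via the `tagger`
#' argument of [extract_features()]. Synthetic corpora generated by
#' [generate_transcripts()] carry gold tags, so analyses of simulated data do
#' not depend on this baseline.
#'
#' @param surfaces character vector of lowercased word forms.
#' @return character vector of Penn Treebank tags, same length.
#' @examples
#' baseline_tagger(c("the", "cat", "jumped"))
#' @export
baseline_tagger <- function(surfaces) {
  tags <- unname(BASELINE_TAG_LEXICON[surfaces])
  open <- is.na(tags)
  s <- surfaces[open]
  guess <- rep("NN", length(s))
  guess[endsWith(s, "ing")] <- "VBG"
  guess[endsWith(s, "ed")] <- "VBD"
  guess[endsWith(s, "ly")] <- "RB"
  plural <- endsWith(s, "s") & !endsWith(s, "ss") & nchar(s) > 3
  guess[plural & guess == "NN"] <- "NNS"
  tags[open] <- guess
  tags
}
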