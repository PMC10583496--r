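# Independent brute-force oracles: plain loops and alternative algebraic
# forms, deliberately sharing no code with the package implementation.

oracle_counts <- function(tokens) {
  n <- 0L
  counts <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(tokens))) {
    if (tokens$kind[i] == "word") {
      n <- n + 1L
      w <- tokens$surface[i]
      prev <- if (exists(w, counts, inherits = FALSE)) get(w, counts) else 0L
      assign(w, prev + 1L, counts)
    }
  }
  words <- ls(counts)
  v1 <- 0L
  for (w in words) if (get(w, counts) == 1L) v1 <- v1 + 1L
  list(n = n, v = length(words), v1 = v1)
}

# alternative algebraic forms of the closed-form statistics
oracle_honore <- function(n, v, v1) {
  if (v1 >= v) return(NaN)
  100 * log(n) * v / (v - v1)
}

oracle_brunet <- function(n, v) {
  exp(log(n) * exp(-0.165 * log(v)))
}

oracle_proportions <- function(tokens, lexicons, tags) {
  counts <- c(
    fillers = 0, empty_words = 0, definite_articles = 0,
    indefinite_articles = 0, pronouns = 0, nouns = 0, verbs = 0,
    determiners = 0, content_words = 0
  )
  n <- 0L
  j <- 0L
  for (i in seq_len(nrow(tokens))) {
    if (tokens$kind[i] != "word") next
    n <- n + 1L
    j <- j + 1L
    w <- tokens$surface[i]
    tg <- tags[j]
    if (w %in% lexicons$fillers) counts["fillers"] <- counts["fillers"] + 1
    if (w %in% lexicons$empty_words) {
      counts["empty_words"] <- counts["empty_words"] + 1
    }
    if (w == "the") {
      counts["definite_articles"] <- counts["definite_articles"] + 1
    }
    if (w == "a" || w == "an") {
      counts["indefinite_articles"] <- counts["indefinite_articles"] + 1
    }
    if (tg %in% c("PRP", "PRP$", "WP", "WP$")) {
      counts["pronouns"] <- counts["pronouns"] + 1
    }
    if (substr(tg, 1, 2) == "NN") counts["nouns"] <- counts["nouns"] + 1
    if (substr(tg, 1, 2) == "VB") counts["verbs"] <- counts["verbs"] + 1
    if (tg %in% c("DT", "PDT", "WDT")) {
      counts["determiners"] <- counts["determiners"] + 1
    }
    if (!(w %in% lexicons$stop_words)) {
      counts["content_words"] <- counts["content_words"] + 1
    }
  }
  counts * 100 / n
}

oracle_mean_log_frequency <- function(tokens, lexicons) {
  total <- 0
  n <- 0L
  for (i in seq_len(nrow(tokens))) {
    if (tokens$kind[i] != "word") next
    w <- tokens$surface[i]
    f <- unname(lexicons$frequency[w])
    if (is.na(f)) f <- lexicons$oov_frequency
    total <- total + log(f, base = 10)
    n <- n + 1L
  }
  total / n
}

# random annotated transcript for oracle comparisons; word tokens always
# present, with a mix of fillers, articles, empty and stop words
ORACLE_POOL <- local({
  open_words <- c(
    "cat", "tree", "window", "cookie", "mother", "water", "jar", "kitchen",
    "fall", "falls", "reach", "reaching", "wash", "washing", "look", "tall",
    "small", "quickly", "slowly", "ladder", "bulb", "chair", "garden",
    "kitten", "branch", "climb", "climbing", "house", "boy", "girl"
  )
  c("the", "a", "an", "um", "uh", "thing", "stuff", "he", "she", "it",
    "is", "was", "on", "in", "and", open_words)
})

ORACLE_TAGS <- c(
  "NN", "NNS", "NNP", "VB", "VBD", "VBG", "VBZ", "PRP", "PRP$", "WP",
  "WP$", "DT", "PDT", "WDT", "JJ", "RB", "IN", "CC", "UH"
)

random_transcript <- function(n_min = 10, n_max = 150) {
  n <- sample(n_min:n_max, 1)
  kind <- sample(
    c("word", "partial_word", "nonword"), n,
    replace = TRUE, prob = c(0.92, 0.05, 0.03)
  )
  if (!any(kind == "word")) kind[1] <- "word"
  toks <- tibble::tibble(
    position = seq_len(n),
    surface = sample(ORACLE_POOL, n, replace = TRUE),
    kind = kind
  )
  tags <- sample(ORACLE_TAGS, sum(kind == "word"), replace = TRUE)
  freq_words <- sample(ORACLE_POOL, length(ORACLE_POOL) %/% 2)
  lex <- lexicon_resources(
    frequency = stats::setNames(
      stats::runif(length(freq_words), 0.5, 5000), freq_words
    )
  )
  list(
    tokens = toks,
    tags = tags,
    lexicons = lex,
    duration = stats::runif(1, 5, 120)
  )
}
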