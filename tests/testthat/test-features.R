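lex0 <- lexicon_resources(frequency = c(the = 60000, cat = 25, sat = 12))

test_that("lexical profile counts word tokens, types, and hapax legomena", {
  prof <- lexical_profile(tokenize_transcript("the cat sat on the mat"))
  expect_equal(prof$n_tokens, 6)
  expect_equal(prof$n_types, 5)
  expect_equal(prof$n_hapax, 4)

  # partial words and nonwords are excluded from N; fillers are included
  prof <- lexical_profile(tokenize_transcript("um the cat- sat"))
  expect_equal(prof$n_tokens, 3)
  expect_equal(prof$n_types, 3)
  expect_equal(prof$n_hapax, 3)

  expect_error(
    lexical_profile(tokenize_transcript("cat- &uh")),
    "empty transcript"
  )
})

test_that("type-token ratio hits its closed forms and boundaries", {
  expect_equal(type_token_ratio(6, 5), 5 / 6)
  expect_equal(type_token_ratio(7, 7), 1)        # all unique
  expect_equal(type_token_ratio(12, 1), 1 / 12)  # one type repeated
})

test_that("Honore statistic matches its closed form and guards V1 = V", {
  expect_equal(
    honore_statistic(10, 7, 5), 100 * log(10) / (1 - 5 / 7),
    tolerance = 1e-12
  )
  expect_equal(round(honore_statistic(10, 7, 5), 1), 805.9)
  # no hapax: reduces to 100 ln(N)
  expect_equal(honore_statistic(50, 10, 0), 100 * log(50))
  # every type a hapax: undefined
  expect_warning(h <- honore_statistic(5, 5, 5), "V1 = V")
  expect_true(is.nan(h))
})

test_that("Brunet index matches its closed form and the V = 1 limit", {
  expect_equal(
    brunet_index(100, 50), 100^(50^(-0.165)),
    tolerance = 1e-12
  )
  expect_equal(round(brunet_index(100, 50), 2), 11.19)
  expect_equal(brunet_index(37, 1), 37) # single type: W = N
})

test_that("proportion features scale category counts per 100 words", {
  toks <- tibble::tibble(
    position = 1:5,
    surface = c("um", "the", "cat", "um", "sat"),
    kind = "word"
  )
  props <- proportion_features(
    toks, lex0, tags = c("UH", "DT", "NN", "UH", "VBD")
  )
  expect_equal(props$fillers, 100 * 2 / 5)
  expect_equal(props$definite_articles, 20)
  expect_equal(props$nouns, 20)
  expect_equal(props$verbs, 20)

  toks2 <- tibble::tibble(
    position = 1:3, surface = c("the", "the", "a"), kind = "word"
  )
  props2 <- proportion_features(toks2, lex0, tags = c("DT", "DT", "DT"))
  expect_equal(props2$definite_articles, 100 * 2 / 3)
  expect_equal(props2$indefinite_articles, 100 * 1 / 3)
  expect_equal(props2$determiners, 100)

  expect_error(
    proportion_features(toks2, lex0, tags = c("DT", "DT")),
    "Untagged"
  )
  expect_error(proportion_features(toks2, lex0), "tags")
})

test_that("mean log frequency is token-weighted with an OOV floor", {
  lex <- lexicon_resources(frequency = c(common = 100, rare = 10))
  toks <- tibble::tibble(
    position = 1:2, surface = c("common", "rare"), kind = "word"
  )
  expect_equal(mean_log_frequency(toks, lex), (2 + 1) / 2)

  # all tokens identical: log10 of that word's frequency
  toks_same <- tibble::tibble(
    position = 1:4, surface = "common", kind = "word"
  )
  expect_equal(mean_log_frequency(toks_same, lex), 2)

  # unseen words get the floor (table minimum by default)
  toks_oov <- tibble::tibble(
    position = 1:2, surface = c("common", "zzz"), kind = "word"
  )
  expect_equal(mean_log_frequency(toks_oov, lex), (2 + 1) / 2)
})

test_that("rate features count every token kind over elapsed time", {
  toks <- tokenize_transcript(
    paste(c(rep("word", 16), "um", "um", "cat-", "&xx"), collapse = " ")
  )
  expect_equal(nrow(toks), 20)
  rates <- rate_features(toks, 10, lex0)
  expect_equal(rates$speech_rate, 2)       # all 20 tokens / 10 s
  expect_equal(rates$filler_rate, 0.2)     # 2 fillers / 10 s

  toks3 <- tokenize_transcript("um uh hmm quiet words here")
  expect_equal(rate_features(toks3, 30, lex0)$filler_rate, 0.1)
  expect_equal(rate_features(toks3, 30, lex0)$speech_rate, 6 / 30)
  expect_equal(
    rate_features(tokenize_transcript("no fillers here"), 30, lex0)$filler_rate,
    0
  )
  expect_error(rate_features(toks3, 0, lex0), "positive")
  expect_error(rate_features(toks3, -5, lex0), "positive")
})

test_that("extract_features returns exactly the 16 named features, deterministically", {
  tr <- random_transcript()
  fv <- extract_features(tr$tokens, tr$duration, tr$lexicons, tags = tr$tags)
  expect_named(fv, speech_feature_names())
  expect_equal(nrow(fv), 1)
  fv2 <- extract_features(tr$tokens, tr$duration, tr$lexicons, tags = tr$tags)
  expect_identical(fv, fv2)
})

test_that("features match brute-force oracles on random transcripts", {
  set.seed(2024)
  for (i in 1:60) {
    tr <- random_transcript()
    fv <- extract_features(tr$tokens, tr$duration, tr$lexicons, tags = tr$tags)
    cnt <- oracle_counts(tr$tokens)
    expect_equal(fv$word_count, cnt$n)
    expect_equal(fv$type_token_ratio, cnt$v / cnt$n, tolerance = 1e-12)
    props <- oracle_proportions(tr$tokens, tr$lexicons, tr$tags)
    for (nm in names(props)) {
      expect_equal(fv[[nm]], unname(props[nm]), tolerance = 1e-12)
    }
    expect_equal(
      fv$frequency, oracle_mean_log_frequency(tr$tokens, tr$lexicons),
      tolerance = 1e-12
    )
    if (cnt$v1 < cnt$v) {
      expect_equal(
        fv$honore_statistic, oracle_honore(cnt$n, cnt$v, cnt$v1),
        tolerance = 1e-9
      )
    }
    expect_equal(
      fv$brunet_index, oracle_brunet(cnt$n, cnt$v), tolerance = 1e-9
    )
    expect_equal(fv$speech_rate, nrow(tr$tokens) / tr$duration)
  }
})

test_that("all 16 features are invariant to token order", {
  set.seed(77)
  tr <- random_transcript(n_min = 80, n_max = 120)
  fv <- suppressWarnings(
    extract_features(tr$tokens, tr$duration, tr$lexicons, tags = tr$tags)
  )
  widx <- which(tr$tokens$kind == "word")
  for (i in 1:5) {
    perm <- sample(nrow(tr$tokens))
    shuffled <- tr$tokens[perm, ]
    shuffled$position <- seq_len(nrow(shuffled))
    # tags follow their word tokens through the shuffle
    tag_of_row <- rep(NA_character_, nrow(tr$tokens))
    tag_of_row[widx] <- tr$tags
    fv_s <- suppressWarnings(extract_features(
      shuffled, tr$duration, tr$lexicons,
      tags = tag_of_row[perm][shuffled$kind == "word"]
    ))
    expect_equal(fv_s, fv, tolerance = 1e-12)
  }
})

test_that("doubling a transcript preserves proportions and bounds diversity", {
  set.seed(31)
  tr <- random_transcript(n_min = 60, n_max = 100)
  fv <- suppressWarnings(
    extract_features(tr$tokens, tr$duration, tr$lexicons, tags = tr$tags)
  )
  doubled <- dplyr::bind_rows(tr$tokens, tr$tokens)
  doubled$position <- seq_len(nrow(doubled))
  fv2 <- suppressWarnings(extract_features(
    doubled, 2 * tr$duration, tr$lexicons, tags = c(tr$tags, tr$tags)
  ))
  for (nm in c("fillers", "empty_words", "definite_articles",
               "indefinite_articles", "pronouns", "nouns", "verbs",
               "determiners", "content_words", "frequency")) {
    expect_equal(fv2[[nm]], fv[[nm]], tolerance = 1e-12)
  }
  expect_lte(fv2$type_token_ratio, fv$type_token_ratio)
  expect_equal(fv2$speech_rate, fv$speech_rate, tolerance = 1e-12)
  expect_equal(fv2$filler_rate, fv$filler_rate, tolerance = 1e-12)
})

test_that("proportion features ignore duration; rates scale as 1/duration", {
  tr <- random_transcript()
  f1 <- suppressWarnings(
    extract_features(tr$tokens, 10, tr$lexicons, tags = tr$tags)
  )
  f2 <- suppressWarnings(
    extract_features(tr$tokens, 20, tr$lexicons, tags = tr$tags)
  )
  expect_equal(f1$fillers, f2$fillers)
  expect_equal(f1$content_words, f2$content_words)
  expect_equal(f1$speech_rate / f2$speech_rate, 2, tolerance = 1e-12)
})

test_that("the baseline tagger honours the contract shape", {
  s <- c("the", "cat", "jumped", "quickly", "um", "she")
  tags <- baseline_tagger(s)
  expect_length(tags, length(s))
  expect_equal(tags[1], "DT")
  expect_equal(tags[5], "UH")
  expect_equal(tags[6], "PRP")
})
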