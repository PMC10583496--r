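# Per-feature generative inter-task correlations used by default: the
# reliability profile observed for picture-description tasks in the full
# sample (strong features like word count and content words near 0.8-0.9,
# weak ones like the Honore statistic near 0.25), so simulated cohorts carry
# a realistic spread of reliabilities.
DEFAULT_RHO <- c(
  word_count = 0.814, fillers = 0.756, empty_words = 0.422,
  definite_articles = 0.461, indefinite_articles = 0.545, pronouns = 0.674,
  nouns = 0.722, verbs = 0.746, determiners = 0.647, content_words = 0.870,
  frequency = 0.774, type_token_ratio = 0.721, honore_statistic = 0.245,
  brunet_index = 0.784, speech_rate = 0.790, filler_rate = 0.730
)

#' Specification of a synthetic cohort
#'
#' Generative parameters for simulated cohorts with the structure the
#' reliability analyses assume: a two-group sample (10 MCI, 29 cognitively
#' intact by default, mirroring a 39-participant cohort with a 26% MCI rate),
#' person-stable feature traits, and a controlled inter-task correlation
#' (test-retest reliability) per feature.
#'
#' Under the generative model, participant i's trait for feature f is
#' theta_if ~ Normal(mu_group,f, sqrt(rho_f)) and the observation for task t
#' is theta_if + Normal(0, sqrt(1 - rho_f)), so the population inter-task
#' correlation of feature f is exactly rho_f and the marginal variance is 1.
#' Expository tasks additionally receive a constant additive offset,
#' mimicking the systematically longer expository productions.
#'
#' @param n_mci,n_intact group sizes (each >= 2); defaults 10 and 29.
#' @param n_features number of features (default 16; other values use generic
#'   names `f1`, `f2`, ...).
#' @param rho per-feature inter-task correlation in [0, 1), recycled to
#'   `n_features`. Default: the picture-task reliability profile above.
#' @param group_shift per-feature mean difference MCI minus intact, in z
#'   units (default 0, recycled).
#' @param expository_offset additive task-type offset for ET1/ET2 (default
#'   0.5 z units).
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @examples
#' cohort_spec(seed = 1)
#' @export
cohort_spec <- function(n_mci = 10, n_intact = 29, n_features = 16,
                        rho = NULL, group_shift = 0,
                        expository_offset = 0.5, seed = 1) {
  if (n_mci < 2 || n_intact < 2) abort("Group sizes must be >= 2.")
  if (is.null(rho)) {
    rho <- if (n_features == 16) unname(DEFAULT_RHO) else rep(0.6, n_features)
  }
  rho <- rep_len(rho, n_features)
  if (any(rho < 0 | rho >= 1)) abort("`rho` must lie in [0, 1).")
  group_shift <- rep_len(group_shift, n_features)
  feature_names <- if (n_features == 16) {
    speech_feature_names()
  } else {
    paste0("f", seq_len(n_features))
  }
  structure(
    list(
      n_mci = n_mci, n_intact = n_intact, n_features = n_features,
      rho = setNames(rho, feature_names),
      group_shift = setNames(group_shift, feature_names),
      expository_offset = expository_offset,
      feature_names = feature_names,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(
    "<cohort_spec> ", x$n_mci, " MCI + ", x$n_intact, " intact participants, ",
    x$n_features, " features; rho in [",
    format(round(min(x$rho), 3)), ", ", format(round(max(x$rho), 3)),
    "]; seed ", x$seed, "\n",
    sep = ""
  )
  invisible(x)
}

cohort_ids <- function(spec) {
  n <- spec$n_mci + spec$n_intact
  list(
    participant_id = sprintf("P%03d", seq_len(n)),
    group = rep(c("MCI", "intact"), c(spec$n_mci, spec$n_intact))
  )
}

#' Generate a feature matrix with controlled inter-task reliability
#'
#' Simulates the long-format feature matrix directly at the feature level
#' (no transcripts), following the trait-plus-task-noise model documented in
#' [cohort_spec()]: each participant x feature trait is shared by all five
#' tasks, task observations add independent noise scaled so the population
#' inter-task correlation equals the spec's `rho`, and expository tasks get
#' the spec's additive offset. Pure function of the spec (including its
#' seed); the caller's RNG state is left untouched.
#'
#' @param spec a [cohort_spec()].
#' @return long feature-matrix tibble (`participant_id`, `task_id`,
#'   `feature_name`, `value`, `group`).
#' @examples
#' fm <- generate_feature_matrix(cohort_spec(seed = 42))
#' dplyr::count(fm, task_id)
#' @export
generate_feature_matrix <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  ids <- cohort_ids(spec)
  n <- length(ids$participant_id)
  k <- spec$n_features
  tasks <- speech_tasks()
  with_preserved_seed(spec$seed, {
    mu <- outer(
      ifelse(ids$group == "MCI", 1, 0),
      unname(spec$group_shift)
    )
    theta <- mu + matrix(rnorm(n * k), n, k) %*% diag(sqrt(spec$rho), k)
    per_task <- lapply(tasks, function(task) {
      eps <- matrix(rnorm(n * k), n, k) %*% diag(sqrt(1 - spec$rho), k)
      val <- theta + eps +
        if (task_type(task) == "expository") spec$expository_offset else 0
      tibble::tibble(
        participant_id = rep(ids$participant_id, k),
        task_id = task,
        feature_name = rep(spec$feature_names, each = n),
        value = as.vector(val),
        group = rep(ids$group, k)
      )
    })
    dplyr::bind_rows(per_task)
  })
}

#' Speaker-population parameters for transcript simulation
#'
#' Distributions from which per-participant speaking profiles are drawn.
#' Person-level spread in these propensities is what makes the corresponding
#' extracted features reliable across tasks; shrinking a spread toward zero
#' turns the feature into task noise.
#'
#' Defaults emulate the magnitudes seen in elderly spontaneous speech:
#' picture descriptions of about 250 words with expository tasks roughly 2.5
#' times longer; speech rate near 2.3 words/second; fillers near 1 per 100
#' words; and a Zipf-like vocabulary skew.
#'
#' @param verbosity_meanlog,verbosity_sdlog lognormal parameters of the target
#'   picture-task word count.
#' @param expository_multiplier mean word-count multiplier for expository
#'   tasks (> 1).
#' @param filler_logit_mean,filler_logit_sd logit-normal parameters of the
#'   per-position filler insertion probability.
#' @param empty_logit_mean,empty_logit_sd logit-normal parameters of the
#'   probability that a drawn noun is replaced by an empty word.
#' @param zipf_mean,zipf_sd normal parameters of the per-person Zipf exponent
#'   (truncated below at 0.8).
#' @param rate_mean,rate_sd normal parameters of base speech rate in
#'   words/second (truncated below at 0.8).
#' @param mci_verbosity_factor,mci_filler_logit_shift,mci_rate_shift mild
#'   group-level adjustments applied to MCI participants' profile means.
#' @param partial_prob,nonword_prob per-position probabilities of emitting a
#'   partial word or a nonword vocalization.
#' @param duration_noise_sdlog lognormal SD of the multiplicative noise on
#'   elapsed duration.
#' @return a list of class `speaker_profile_params`.
#' @export
speaker_profile_params <- function(verbosity_meanlog = log(250),
                                   verbosity_sdlog = 0.45,
                                   expository_multiplier = 2.5,
                                   filler_logit_mean = stats::qlogis(0.012),
                                   filler_logit_sd = 0.6,
                                   empty_logit_mean = stats::qlogis(0.05),
                                   empty_logit_sd = 0.5,
                                   zipf_mean = 1.1, zipf_sd = 0.08,
                                   rate_mean = 2.3, rate_sd = 0.35,
                                   mci_verbosity_factor = 0.85,
                                   mci_filler_logit_shift = 0.3,
                                   mci_rate_shift = -0.15,
                                   partial_prob = 0.01,
                                   nonword_prob = 0.005,
                                   duration_noise_sdlog = 0.05) {
  structure(
    as.list(environment()),
    class = "speaker_profile_params"
  )
}

draw_speaker_profiles <- function(spec, params) {
  ids <- cohort_ids(spec)
  n <- length(ids$participant_id)
  mci <- ids$group == "MCI"
  tibble::tibble(
    participant_id = ids$participant_id,
    group = ids$group,
    verbosity = exp(
      rnorm(n, params$verbosity_meanlog, params$verbosity_sdlog)
    ) * ifelse(mci, params$mci_verbosity_factor, 1),
    filler_propensity = stats::plogis(
      rnorm(n, params$filler_logit_mean, params$filler_logit_sd) +
        ifelse(mci, params$mci_filler_logit_shift, 0)
    ),
    empty_word_propensity = stats::plogis(
      rnorm(n, params$empty_logit_mean, params$empty_logit_sd)
    ),
    zipf_exponent = pmax(0.8, rnorm(n, params$zipf_mean, params$zipf_sd)),
    base_speech_rate = pmax(
      0.8, rnorm(n, params$rate_mean, params$rate_sd) +
        ifelse(mci, params$mci_rate_shift, 0)
    )
  )
}

# A ranked vocabulary with realistic part-of-speech structure: high-frequency
# closed-class words at the top ranks, synthetic open-class words below.
build_synthetic_vocabulary <- function(vocab_size = 2000) {
  if (vocab_size < 30) abort("`vocab_size` must be at least 30.")
  closed <- tibble::tibble(
    word = c(
      "the", "and", "a", "to", "of", "in", "is", "it", "he", "she",
      "they", "that", "was", "on", "with", "an", "her", "his", "are",
      "this", "you", "i", "we", "at", "but", "or", "had", "my", "their"
    ),
    tag = c(
      "DT", "CC", "DT", "TO", "IN", "IN", "VBZ", "PRP", "PRP", "PRP",
      "PRP", "DT", "VBD", "IN", "IN", "DT", "PRP$", "PRP$", "VBP",
      "DT", "PRP", "PRP", "PRP", "IN", "CC", "CC", "VBD", "PRP$", "PRP$"
    )
  )
  n_open <- vocab_size - nrow(closed)
  open_tags <- rep(c("NN", "VB", "JJ", "NN", "RB"), length.out = n_open)
  idx <- stats::ave(seq_len(n_open), open_tags, FUN = seq_along)
  open <- tibble::tibble(
    word = paste0(
      c(NN = "nn", VB = "vb", JJ = "jj", RB = "rb")[open_tags],
      sprintf("%04d", idx)
    ),
    tag = open_tags
  )
  vocab <- dplyr::bind_rows(closed, open)
  vocab$rank <- seq_len(nrow(vocab))
  vocab
}

simulate_one_transcript <- function(profile, task, vocab, params,
                                    empty_words) {
  mult <- if (task_type(task) == "expository") {
    params$expository_multiplier
  } else {
    1
  }
  n_words <- max(5L, rpois(1, profile$verbosity * mult))
  weights <- vocab$rank^(-profile$zipf_exponent)
  draw <- sample.int(nrow(vocab), n_words, replace = TRUE, prob = weights)
  surface <- vocab$word[draw]
  tag <- vocab$tag[draw]
  # word-finding difficulty: some nouns come out as semantically empty words
  is_noun <- tag == "NN"
  empty <- is_noun & runif(n_words) < profile$empty_word_propensity
  surface[empty] <- sample(empty_words, sum(empty), replace = TRUE)
  # hesitation fillers inserted per position
  fill <- runif(n_words) < profile$filler_propensity
  surface[fill] <- sample(DEFAULT_FILLERS, sum(fill), replace = TRUE)
  tag[fill] <- "UH"
  kind <- rep("word", n_words)
  u <- runif(n_words)
  partial <- !fill & u < params$partial_prob
  nonword <- !fill & !partial & u < params$partial_prob + params$nonword_prob
  kind[partial] <- "partial_word"
  kind[nonword] <- "nonword"
  surface[partial] <- substr(surface[partial], 1, pmax(
    1, nchar(surface[partial]) - 2
  ))
  surface[nonword] <- "xx"
  tag[partial | nonword] <- NA_character_
  duration <- n_words / profile$base_speech_rate *
    exp(rnorm(1, 0, params$duration_noise_sdlog))
  list(
    tokens = tibble::tibble(
      participant_id = profile$participant_id,
      task_id = task,
      position = seq_len(n_words),
      surface = surface,
      kind = kind,
      tag = tag
    ),
    duration = duration
  )
}

# Table-1-style neuropsychological battery and its domain structure
TEST_BATTERY <- tibble::tibble(
  test = c(
    "digit_span_forward", "digit_span_backward", "tmt_a",
    "tmt_b", "fab",
    "cowa", "animal_naming", "bnt",
    "cft_copy",
    "cft_delayed_recall", "hvlt_total", "hvlt_delayed_recall",
    "hvlt_discrimination"
  ),
  domain = c(
    "attention", "attention", "attention",
    "executive", "executive",
    "language", "language", "language",
    "visuospatial",
    "memory", "memory", "memory",
    "memory"
  )
)

draw_tscores <- function(spec) {
  ids <- cohort_ids(spec)
  tests <- TEST_BATTERY$test
  per_participant <- purrr::map2(
    ids$participant_id, ids$group,
    function(pid, grp) {
      if (grp == "intact") {
        repeat {
          ts <- round(rnorm(length(tests), 52, 8), 1)
          low <- tapply(ts <= 40, TEST_BATTERY$domain, sum)
          if (all(low < 2)) break
        }
      } else {
        ts <- round(rnorm(length(tests), 47, 9), 1)
        dom <- sample(c("attention", "executive", "language", "memory"), 1)
        hit <- sample(which(TEST_BATTERY$domain == dom), 2)
        ts[hit] <- pmin(40, round(rnorm(2, 34, 3), 1))
      }
      tibble::tibble(participant_id = pid, test = tests, tscore = ts)
    }
  )
  dplyr::bind_rows(per_participant)
}

#' Simulate a transcript-level speech corpus
#'
#' Generates token-level transcripts for every participant x task, exercising
#' the whole extraction pipeline: words are drawn from a Zipf-weighted
#' vocabulary (per-person exponent), hesitation fillers are inserted
#' per position with a person-stable propensity, some nouns are replaced by
#' semantically empty words, a small fraction of tokens are partial words or
#' nonword vocalizations, word counts are Poisson around a person-stable
#' verbosity (expository tasks longer by a fixed multiplier), and elapsed
#' duration follows the person's base speech rate with multiplicative noise.
#' Gold Penn Treebank tags are carried on every word token, and T-scores
#' consistent with each participant's group are drawn for the cognitive
#' battery. Pure function of `(spec, params, vocab_size)`.
#'
#' @param spec a [cohort_spec()] (its `rho`/`group_shift` fields are unused at
#'   the transcript level; group sizes and seed apply).
#' @param params a [speaker_profile_params()].
#' @param vocab_size vocabulary size (>= 30; default 2000).
#' @return list of class `speech_corpus` with `tokens` (incl. gold `tag`),
#'   `metadata` (group, per-task durations), `tscores` (long tibble),
#'   `domains` (test -> domain map), `profiles` (the drawn speaker profiles),
#'   `lexicons` (a [lexicon_resources()] whose frequency table matches the
#'   generating vocabulary), and `excluded` (empty).
#' @examples
#' corpus <- generate_transcripts(cohort_spec(n_mci = 2, n_intact = 3, seed = 7))
#' corpus$metadata
#' @export
generate_transcripts <- function(spec, params = speaker_profile_params(),
                                 vocab_size = 2000) {
  stopifnot(inherits(spec, "cohort_spec"))
  vocab <- build_synthetic_vocabulary(vocab_size)
  with_preserved_seed(spec$seed, {
    profiles <- draw_speaker_profiles(spec, params)
    sims <- purrr::map(seq_len(nrow(profiles)), function(i) {
      prof <- profiles[i, ]
      per_task <- purrr::map(
        speech_tasks(),
        function(task) {
          simulate_one_transcript(prof, task, vocab, params,
                                  DEFAULT_EMPTY_WORDS)
        }
      )
      durations <- purrr::map_dbl(per_task, "duration")
      list(
        tokens = dplyr::bind_rows(purrr::map(per_task, "tokens")),
        meta = tibble::as_tibble(c(
          list(participant_id = prof$participant_id, group = prof$group),
          setNames(as.list(durations), duration_columns())
        ))
      )
    })
    tscores <- draw_tscores(spec)
    # frequency table implied by the generating Zipf law at the default
    # exponent, expressed per million tokens
    w <- vocab$rank^(-params$zipf_mean)
    freq <- setNames(1e6 * w / sum(w), vocab$word)
    structure(
      list(
        tokens = dplyr::bind_rows(purrr::map(sims, "tokens")),
        metadata = dplyr::bind_rows(purrr::map(sims, "meta")),
        tscores = tscores,
        domains = TEST_BATTERY,
        profiles = profiles,
        lexicons = lexicon_resources(frequency = freq),
        excluded = character()
      ),
      class = "speech_corpus"
    )
  })
}

#' Write a simulated corpus to disk in the readable corpus layout
#'
#' Serializes a [generate_transcripts()] corpus into the exact layout
#' [read_corpus()] reads: one `{participant}_{task}.txt` transcript per cell
#' in the annotation dialect (trailing `-` marks partial words, `&` prefixes
#' nonwords), one `.tags` gold-tag sidecar per transcript, `metadata.tsv`
#' with group and per-task durations, `tscores.tsv` / `domains.tsv`, and the
#' lexicon files (`fillers.txt`, `empty_words.txt`, `stop_words.txt`,
#' `frequency.tsv`).
#'
#' @param corpus a `speech_corpus` from [generate_transcripts()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cells <- dplyr::distinct(
    corpus$tokens, .data$participant_id, .data$task_id
  )
  purrr::pwalk(cells, function(participant_id, task_id) {
    toks <- corpus$tokens[
      corpus$tokens$participant_id == participant_id &
        corpus$tokens$task_id == task_id,
    ]
    surf <- toks$surface
    surf[toks$kind == "partial_word"] <-
      paste0(surf[toks$kind == "partial_word"], "-")
    surf[toks$kind == "nonword"] <-
      paste0("&", surf[toks$kind == "nonword"])
    base <- file.path(dir, paste0(participant_id, "_", task_id))
    # wrap to ~12 tokens per line for readability
    lines <- tapply(
      surf, (seq_along(surf) - 1) %/% 12, paste, collapse = " "
    )
    readr::write_lines(lines, paste0(base, ".txt"))
    if ("tag" %in% names(toks)) {
      readr::write_lines(
        toks$tag[toks$kind == "word"], paste0(base, ".tags")
      )
    }
  })
  readr::write_tsv(corpus$metadata, file.path(dir, "metadata.tsv"),
                   progress = FALSE)
  if (!is.null(corpus$tscores)) {
    readr::write_tsv(corpus$tscores, file.path(dir, "tscores.tsv"),
                     progress = FALSE)
    readr::write_tsv(corpus$domains, file.path(dir, "domains.tsv"),
                     progress = FALSE)
  }
  lex <- corpus$lexicons
  if (!is.null(lex)) {
    readr::write_lines(lex$fillers, file.path(dir, "fillers.txt"))
    readr::write_lines(lex$empty_words, file.path(dir, "empty_words.txt"))
    readr::write_lines(lex$stop_words, file.path(dir, "stop_words.txt"))
    readr::write_tsv(
      tibble::tibble(
        word = names(lex$frequency),
        per_million = unname(lex$frequency)
      ),
      file.path(dir, "frequency.tsv"),
      col_names = FALSE, progress = FALSE
    )
  }
  invisible(dir)
}
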