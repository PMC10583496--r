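#' Tokenize a transcript in the package's transcript dialect
#'
#' Transcripts are UTF-8 plain text, whitespace-tokenized, with a light
#' annotation dialect: everything is lowercased and sentence punctuation is
#' stripped; a token ending in `-` is a partial (abandoned) word; a token
#' prefixed `&` is a nonword vocalization. Fillers (um, uh, ...) are ordinary
#' word tokens — they are matched against the filler lexicon downstream, not
#' marked in the transcript. Partial words and nonwords are never counted as
#' lexical words; they enter only the speech-rate denominator-free token count.
#'
#' @param text character vector of transcript lines (or a single string).
#' @return a tibble with columns `position` (integer), `surface` (lowercased
#'   form, annotation markers removed) and `kind`
#'   (`"word"`, `"partial_word"`, `"nonword"`).
#' @examples
#' tokenize_transcript("Um, the cat- sat &uh on the mat.")
#' @export
tokenize_transcript <- function(text) {
  raw <- unlist(strsplit(paste(text, collapse = " "), "\\s+"))
  raw <- raw[nzchar(raw)]
  if (length(raw) == 0) {
    return(tibble::tibble(
      position = integer(), surface = character(), kind = character()
    ))
  }
  tok <- tolower(raw)
  # strip sentence punctuation but preserve the dialect markers & (prefix)
  # and - (suffix)
  nonword <- startsWith(tok, "&")
  tok <- sub("^&", "", tok)
  tok <- gsub("[.,!?;:\"()’']+", "", tok)
  partial <- endsWith(tok, "-") & !nonword
  tok <- sub("-+$", "", tok)
  keep <- nzchar(tok)
  if (any(!keep & (nonword | partial))) {
    abort("Malformed dialect marker: bare '&' or '-' token with no word form.")
  }
  tok <- tok[keep]
  nonword <- nonword[keep]
  partial <- partial[keep]
  kind <- rep("word", length(tok))
  kind[partial] <- "partial_word"
  kind[nonword] <- "nonword"
  tibble::tibble(
    position = seq_along(tok),
    surface = tok,
    kind = kind
  )
}

transcript_filename <- function(participant_id, task_id) {
  paste0(participant_id, "_", task_id, ".txt")
}

#' Read a transcript corpus and its metadata
#'
#' Reads a directory of per-participant, per-task transcripts
#' (`{participant_id}_{task_id}.txt`, dialect of [tokenize_transcript()])
#' together with a tab-separated metadata table holding one row per
#' participant: `participant_id`, optionally `group`, the five per-task
#' durations (`duration_ET1` ... `duration_PDT3`, seconds), and optionally
#' T-score columns for cognitive classification.
#'
#' Participants missing any of the five transcripts, any duration, or with a
#' nonpositive duration are excluded with a warning (complete-case rule), so
#' every admitted participant contributes exactly five transcripts.
#'
#' If gold part-of-speech sidecar files (`{participant_id}_{task_id}.tags`,
#' one Penn Treebank tag per word token line) are present they are attached as
#' a `tag` column on word tokens.
#'
#' @param transcript_dir directory containing the transcript files.
#' @param metadata path to the metadata TSV, or a data frame already read.
#' @return a list of class `speech_corpus` with elements `tokens` (tibble:
#'   `participant_id`, `task_id`, `position`, `surface`, `kind`, and `tag`
#'   when sidecars exist), `metadata` (tibble, admitted participants only) and
#'   `excluded` (character vector of excluded participant ids).
#' @export
read_corpus <- function(transcript_dir, metadata) {
  if (!dir.exists(transcript_dir)) {
    abort(paste0("Transcript directory not found: ", transcript_dir))
  }
  meta <- if (is.data.frame(metadata)) {
    tibble::as_tibble(metadata)
  } else {
    readr::read_tsv(metadata, col_types = readr::cols(), progress = FALSE)
  }
  if (!"participant_id" %in% names(meta)) {
    abort("Metadata must contain a `participant_id` column.")
  }
  meta$participant_id <- as.character(meta$participant_id)
  dur_cols <- duration_columns()
  missing_cols <- setdiff(dur_cols, names(meta))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Metadata is missing duration column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }

  admitted <- character()
  excluded <- character()
  token_tbls <- list()
  for (pid in meta$participant_id) {
    row <- meta[meta$participant_id == pid, ]
    durs <- as.numeric(row[1, dur_cols])
    files <- file.path(transcript_dir, transcript_filename(pid, speech_tasks()))
    have <- file.exists(files)
    if (any(is.na(durs)) || any(durs <= 0) || !all(have)) {
      warn(paste0(
        "Excluding participant ", pid, ": ",
        if (!all(have)) {
          paste0("missing transcript(s) ", paste(speech_tasks()[!have], collapse = ", "))
        } else {
          "missing or nonpositive duration(s)"
        }
      ))
      excluded <- c(excluded, pid)
      next
    }
    per_task <- purrr::map2(files, speech_tasks(), function(f, task) {
      toks <- tokenize_transcript(readr::read_lines(f))
      tagf <- sub("\\.txt$", ".tags", f)
      if (file.exists(tagf)) {
        tags <- readr::read_lines(tagf)
        n_word <- sum(toks$kind == "word")
        if (length(tags) != n_word) {
          abort(paste0(
            "Tag sidecar ", basename(tagf), " has ", length(tags),
            " tags for ", n_word, " word tokens."
          ))
        }
        toks$tag <- NA_character_
        toks$tag[toks$kind == "word"] <- tags
      }
      dplyr::mutate(toks, participant_id = pid, task_id = task, .before = 1)
    })
    token_tbls <- c(token_tbls, per_task)
    admitted <- c(admitted, pid)
  }
  structure(
    list(
      tokens = dplyr::bind_rows(token_tbls),
      metadata = meta[meta$participant_id %in% admitted, ],
      excluded = excluded
    ),
    class = "speech_corpus"
  )
}

#' @export
print.speech_corpus <- function(x, ...) {
  cat(
    "<speech_corpus> ", nrow(x$metadata), " participants x ",
    length(speech_tasks()), " tasks; ", nrow(x$tokens), " tokens",
    if (length(x$excluded) > 0) {
      paste0("; ", length(x$excluded), " participant(s) excluded")
    } else "",
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Classify cognitive status from neuropsychological T-scores
#'
#' Applies the MCI operationalization: a participant is classified as MCI when
#' they score at least 1 SD below the normative mean (T-score <= 40, boundary
#' inclusive) on at least `min_tests` tests — by default within the same
#' cognitive domain. T-scores are normed with population mean 50 and SD 10.
#' Setting `require_same_domain = FALSE` applies the looser variant in which
#' any `min_tests` low tests suffice regardless of domain.
#'
#' @param tscores a data frame with columns `participant_id`, `test`,
#'   `tscore` (long format, one row per participant x test).
#' @param domain_map a data frame with columns `test`, `domain` covering every
#'   test in `tscores` (required unless `require_same_domain = FALSE`).
#' @param threshold_t T-score cutoff, inclusive; default 40 (1 SD below the
#'   normative mean).
#' @param min_tests minimum number of tests at or below the cutoff; default 2.
#' @param require_same_domain must the low tests share a cognitive domain?
#'   Default `TRUE`.
#' @return tibble with columns `participant_id`, `group`
#'   (`"MCI"` or `"intact"`).
#' @examples
#' ts <- tibble::tibble(
#'   participant_id = "p1",
#'   test = c("HVLT", "CFT-DR", "TMT-A"),
#'   tscore = c(38, 35, 55)
#' )
#' dm <- tibble::tibble(
#'   test = c("HVLT", "CFT-DR", "TMT-A"),
#'   domain = c("memory", "memory", "attention")
#' )
#' classify_cognitive_status(ts, dm)
#' @export
classify_cognitive_status <- function(tscores, domain_map = NULL,
                                      threshold_t = 40, min_tests = 2,
                                      require_same_domain = TRUE) {
  need <- c("participant_id", "test", "tscore")
  if (!all(need %in% names(tscores))) {
    abort("`tscores` must have columns participant_id, test, tscore.")
  }
  if (nrow(tscores) == 0) abort("`tscores` is empty.")
  x <- tibble::as_tibble(tscores)
  if (require_same_domain) {
    if (is.null(domain_map)) {
      abort("`domain_map` is required when require_same_domain = TRUE.")
    }
    unmapped <- setdiff(unique(x$test), domain_map$test)
    if (length(unmapped) > 0) {
      abort(paste0(
        "Test(s) missing from domain_map: ", paste(unmapped, collapse = ", ")
      ))
    }
    x <- dplyr::left_join(
      x, dplyr::distinct(domain_map, .data$test, .data$domain),
      by = "test"
    )
  } else {
    x$domain <- "any"
  }
  x |>
    dplyr::group_by(.data$participant_id, .data$domain) |>
    dplyr::summarise(
      n_low = sum(.data$tscore <= threshold_t),
      .groups = "drop_last"
    ) |>
    dplyr::summarise(
      group = ifelse(any(.data$n_low >= min_tests), "MCI", "intact"),
      .groups = "drop"
    )
}

#' Write and read a long-format feature matrix
#'
#' The feature matrix is stored as comma-separated long-format text with
#' header `participant_id,task_id,feature_name,value,group`, values at full
#' precision, so a write/read round trip is lossless. Reading validates that
#' every `feature_name` is one of the sixteen recognized names and every
#' `task_id` one of the five tasks.
#'
#' @param matrix a feature-matrix tibble (`participant_id`, `task_id`,
#'   `feature_name`, `value`, `group`).
#' @param path file path.
#' @return `read_feature_matrix()` returns the tibble; `write_feature_matrix()`
#'   returns `path` invisibly.
#' @export
write_feature_matrix <- function(matrix, path) {
  cols <- c("participant_id", "task_id", "feature_name", "value", "group")
  if (!all(cols %in% names(matrix))) {
    abort(paste0(
      "Feature matrix must have columns: ", paste(cols, collapse = ", ")
    ))
  }
  out <- dplyr::select(matrix, dplyr::all_of(cols))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  fm <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      task_id = readr::col_character(),
      feature_name = readr::col_character(),
      value = readr::col_character(),
      group = readr::col_character()
    ),
    progress = FALSE
  )
  # parse doubles via strtod for an exact round trip of write_csv output
  fm$value <- as.numeric(fm$value)
  bad_feat <- setdiff(unique(fm$feature_name), speech_feature_names())
  if (length(bad_feat) > 0) {
    abort(paste0(
      "Unknown feature name(s): ", paste(bad_feat, collapse = ", ")
    ))
  }
  bad_task <- setdiff(unique(fm$task_id), speech_tasks())
  if (length(bad_task) > 0) {
    abort(paste0("Unknown task id(s): ", paste(bad_task, collapse = ", ")))
  }
  fm
}
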