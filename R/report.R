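#' Per-task summary of feature values
#'
#' Between-participant mean and SD of each feature within each task — the
#' standard descriptive layout for a speech-feature study (features as rows,
#' the five tasks as columns).
#'
#' @param matrix long feature matrix.
#' @param layout `"long"` (numeric columns `mean`, `sd`) or `"wide"`
#'   (one `mean (SD)` text column per task).
#' @param digits digits for the wide text rendering.
#' @return tibble.
#' @export
feature_summary <- function(matrix, layout = c("long", "wide"), digits = 2) {
  layout <- match.arg(layout)
  long <- matrix |>
    dplyr::group_by(.data$feature_name, .data$task_id) |>
    dplyr::summarise(
      mean = mean(.data$value), sd = sd(.data$value), .groups = "drop"
    ) |>
    dplyr::arrange(
      match(.data$feature_name, speech_feature_names()),
      match(.data$task_id, speech_tasks())
    )
  if (layout == "long") {
    return(long)
  }
  long |>
    dplyr::mutate(
      cell = paste0(
        format(round(.data$mean, digits), trim = TRUE), " (",
        format(round(.data$sd, digits), trim = TRUE), ")"
      )
    ) |>
    dplyr::select("feature_name", "task_id", "cell") |>
    tidyr::pivot_wider(names_from = "task_id", values_from = "cell")
}

#' Two-panel reliability report
#'
#' Reshapes a [reliability_analysis()] result into the familiar two-panel
#' report: an upper panel of within-task-type mean correlations (one row per
#' task type x group, features as columns) and a lower panel of cross-task
#' intraindividual variability (one row per group).
#'
#' @param rel a `speech_reliability` object.
#' @param digits rounding applied to the displayed values (default 3;
#'   use `NULL` for full precision).
#' @return list with tibbles `reliability` and `itv`.
#' @export
reliability_report <- function(rel, digits = 3) {
  stopifnot(inherits(rel, "speech_reliability"))
  maybe_round <- function(x) if (is.null(digits)) x else round(x, digits)
  upper <- rel$estimates |>
    dplyr::mutate(r_mean = maybe_round(.data$r_mean)) |>
    dplyr::select("task_type", "group", "feature_name", "r_mean") |>
    tidyr::pivot_wider(names_from = "feature_name", values_from = "r_mean") |>
    dplyr::arrange(.data$task_type, .data$group)
  lower <- rel$itv |>
    dplyr::mutate(itv = maybe_round(.data$itv)) |>
    dplyr::select("group", "feature_name", "itv") |>
    tidyr::pivot_wider(names_from = "feature_name", values_from = "itv") |>
    dplyr::arrange(.data$group)
  list(reliability = upper, itv = lower)
}

#' Render a tibble to CSV, JSON, or a markdown pipe table
#'
#' Markdown tables written by this function round-trip losslessly through
#' [parse_markdown_table()]: numeric cells are serialized at full precision.
#'
#' @param x a data frame.
#' @param format `"csv"`, `"json"`, or `"markdown"`.
#' @param path optional output file; when `NULL` the rendering is returned as
#'   a character vector (markdown/csv) or JSON string.
#' @return the rendering, invisibly when written to `path`.
#' @export
render_table <- function(x, format = c("csv", "json", "markdown"),
                         path = NULL) {
  format <- match.arg(format)
  out <- switch(format,
    csv = readr::format_csv(x),
    json = jsonlite::toJSON(x, dataframe = "rows", digits = NA, na = "null"),
    markdown = {
      cells <- lapply(x, function(col) {
        if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)
      })
      body <- do.call(cbind, cells)
      widths <- pmax(
        nchar(names(x)),
        if (nrow(x) > 0) apply(nchar(body), 2, max) else 0
      )
      pad <- function(row) {
        cells <- mapply(
          function(s, w) formatC(s, width = w, flag = "-"),
          row, widths
        )
        paste0("| ", paste(cells, collapse = " | "), " |")
      }
      c(
        pad(names(x)),
        paste0("|", paste(strrep("-", widths + 2), collapse = "|"), "|"),
        if (nrow(x) > 0) apply(body, 1, pad)
      )
    }
  )
  if (!is.null(path)) {
    if (format == "json") {
      readr::write_lines(as.character(out), path)
    } else {
      readr::write_lines(out, path)
    }
    return(invisible(out))
  }
  out
}

#' @rdname render_table
#' @param lines character vector of markdown table lines (or a file path of
#'   length 1 pointing to an existing file).
#' @export
parse_markdown_table <- function(lines) {
  if (length(lines) == 1 && file.exists(lines)) {
    lines <- readr::read_lines(lines)
  }
  lines <- lines[grepl("^\\|", lines)]
  if (length(lines) < 2) abort("Not a markdown table.")
  split_row <- function(l) {
    parts <- strsplit(sub("\\|\\s*$", "", sub("^\\|\\s*", "", l)),
                      "\\s*\\|\\s*")[[1]]
    trimws(parts)
  }
  header <- split_row(lines[1])
  body <- lines[-(1:2)]
  rows <- lapply(body, split_row)
  cols <- lapply(seq_along(header), function(j) {
    vals <- vapply(rows, `[`, character(1), j)
    num <- suppressWarnings(as.numeric(vals))
    if (length(vals) > 0 && !anyNA(num)) num else vals
  })
  tibble::as_tibble(setNames(cols, header))
}

config_defaults <- function() {
  list(
    corpus_dir = NULL,
    features_path = NULL,
    out_dir = ".",
    format = "csv",
    reps = 10000,
    seed = 1,
    itv_mode = "per_participant_sd",
    stratify_by_group = TRUE,
    require_same_domain = TRUE,
    threshold_t = 40,
    min_tests = 2,
    n_mci = 10,
    n_intact = 29,
    log_level = "info"
  )
}

#' Assemble a run configuration
#'
#' Merges, in increasing precedence: package defaults, a YAML config file,
#' and direct arguments (the command-line flags map onto these one-to-one).
#'
#' @param config_file optional YAML file of configuration keys.
#' @param ... overrides of individual keys (see [config_defaults] names:
#'   `corpus_dir`, `features_path`, `out_dir`, `format`, `reps`, `seed`,
#'   `itv_mode`, `stratify_by_group`, `require_same_domain`, `threshold_t`,
#'   `min_tests`, `n_mci`, `n_intact`, `log_level`).
#' @return a named list of class `run_config`.
#' @export
run_config <- function(config_file = NULL, ...) {
  cfg <- config_defaults()
  if (!is.null(config_file)) {
    if (!file.exists(config_file)) {
      abort(paste0("Config file not found: ", config_file))
    }
    file_cfg <- yaml::read_yaml(config_file)
    bad <- setdiff(names(file_cfg), names(cfg))
    if (length(bad) > 0) {
      abort(paste0("Unknown config key(s): ", paste(bad, collapse = ", ")))
    }
    cfg[names(file_cfg)] <- file_cfg
  }
  overrides <- list(...)
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad) > 0) {
    abort(paste0("Unknown config key(s): ", paste(bad, collapse = ", ")))
  }
  cfg[names(overrides)] <- overrides
  cfg$reps <- as.integer(cfg$reps)
  cfg$seed <- as.integer(cfg$seed)
  if (is.na(cfg$reps) || cfg$reps < 1) abort("`reps` must be >= 1.")
  structure(cfg, class = "run_config")
}

log_msg <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  inform(paste0("[speechlex ", format(Sys.time(), "%H:%M:%S"), "] ", ...))
}

#' Pipeline commands
#'
#' The high-level entry points behind the command-line interface; each takes
#' a [run_config()] and is fully reproducible given (inputs, config, seed).
#' \describe{
#'   \item{`run_simulate()`}{simulates a transcript corpus
#'     ([generate_transcripts()]) and writes it, plus a `manifest.json`
#'     echoing the configuration, under `corpus_dir`.}
#'   \item{`run_extract()`}{reads a corpus, derives group labels from
#'     T-scores when the metadata carries none, extracts all features and
#'     writes the long feature matrix to `features_path`.}
#'   \item{`run_reliability()`}{runs [reliability_analysis()] on a feature
#'     matrix and writes per-feature estimates, grand summaries and the group
#'     comparison under `out_dir` in the configured format.}
#'   \item{`run_itv()`}{writes the intraindividual-variability table.}
#'   \item{`run_report()`}{writes the combined two-panel report
#'     ([reliability_report()]) and the descriptive feature summary.}
#' }
#'
#' @param cfg a [run_config()].
#' @return the central object of each step, invisibly (`run_simulate`: the
#'   corpus; `run_extract`: the feature matrix; `run_reliability`/`run_itv`/
#'   `run_report`: the `speech_reliability` object or table written).
#' @export
run_simulate <- function(cfg) {
  if (is.null(cfg$corpus_dir)) abort("`corpus_dir` is required for simulate.")
  spec <- cohort_spec(
    n_mci = cfg$n_mci, n_intact = cfg$n_intact, seed = cfg$seed
  )
  corpus <- generate_transcripts(spec)
  write_corpus(corpus, cfg$corpus_dir)
  manifest <- c(
    unclass(cfg)[!vapply(unclass(cfg), is.null, logical(1))],
    list(
      package_version = as.character(utils::packageVersion("speechlex")),
      n_participants = nrow(corpus$metadata),
      n_transcripts = nrow(dplyr::distinct(
        corpus$tokens, .data$participant_id, .data$task_id
      ))
    )
  )
  jsonlite::write_json(
    manifest, file.path(cfg$corpus_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  log_msg(
    cfg, "simulated ", nrow(corpus$metadata), " participants (seed ",
    cfg$seed, ") -> ", cfg$corpus_dir
  )
  invisible(corpus)
}

#' @rdname run_simulate
#' @export
run_extract <- function(cfg) {
  if (is.null(cfg$corpus_dir)) abort("`corpus_dir` is required for extract.")
  meta_path <- file.path(cfg$corpus_dir, "metadata.tsv")
  if (!file.exists(meta_path)) {
    abort(paste0("Metadata not found: ", meta_path))
  }
  corpus <- read_corpus(cfg$corpus_dir, meta_path)
  if (nrow(corpus$metadata) == 0) abort("Empty corpus: no admitted participants.")
  log_msg(
    cfg, "admitted ", nrow(corpus$metadata), " participants, excluded ",
    length(corpus$excluded)
  )
  if (!"group" %in% names(corpus$metadata)) {
    ts_path <- file.path(cfg$corpus_dir, "tscores.tsv")
    dom_path <- file.path(cfg$corpus_dir, "domains.tsv")
    if (file.exists(ts_path)) {
      tsc <- readr::read_tsv(ts_path, col_types = readr::cols(),
                             progress = FALSE)
      dom <- if (file.exists(dom_path)) {
        readr::read_tsv(dom_path, col_types = readr::cols(), progress = FALSE)
      } else {
        NULL
      }
      cls <- classify_cognitive_status(
        tsc, dom,
        threshold_t = cfg$threshold_t, min_tests = cfg$min_tests,
        require_same_domain = cfg$require_same_domain
      )
      corpus$metadata <- dplyr::left_join(
        corpus$metadata, cls, by = "participant_id"
      )
      log_msg(cfg, "classified groups from T-scores: ",
              sum(cls$group == "MCI"), " MCI / ",
              sum(cls$group == "intact"), " intact")
    }
  }
  lexicons <- corpus_lexicons(cfg$corpus_dir)
  fm <- extract_corpus_features(corpus, lexicons, tagger = baseline_tagger)
  if (!is.null(cfg$features_path)) {
    dir.create(dirname(cfg$features_path), recursive = TRUE,
               showWarnings = FALSE)
    write_feature_matrix(fm, cfg$features_path)
    log_msg(cfg, "wrote ", nrow(fm), " feature rows -> ", cfg$features_path)
  }
  invisible(fm)
}

# Assemble lexicon resources from the optional lexicon files of a corpus
# directory, falling back to package defaults.
corpus_lexicons <- function(dir) {
  grab <- function(f, default) {
    p <- file.path(dir, f)
    if (file.exists(p)) read_word_list(p) else default
  }
  freq_path <- file.path(dir, "frequency.tsv")
  lexicon_resources(
    fillers = grab("fillers.txt", DEFAULT_FILLERS),
    empty_words = grab("empty_words.txt", DEFAULT_EMPTY_WORDS),
    stop_words = grab("stop_words.txt", STOP_WORDS_EN),
    frequency = if (file.exists(freq_path)) {
      read_frequency_table(freq_path)
    } else {
      numeric()
    }
  )
}

load_features <- function(cfg) {
  if (is.null(cfg$features_path) || !file.exists(cfg$features_path)) {
    abort("`features_path` must point to an existing feature matrix file.")
  }
  read_feature_matrix(cfg$features_path)
}

write_outputs <- function(cfg, tables) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  ext <- c(csv = "csv", json = "json", markdown = "md")[[cfg$format]]
  for (nm in names(tables)) {
    path <- file.path(cfg$out_dir, paste0(nm, ".", ext))
    render_table(tables[[nm]], cfg$format, path)
    log_msg(cfg, "wrote ", path)
  }
}

#' @rdname run_simulate
#' @export
run_reliability <- function(cfg) {
  fm <- load_features(cfg)
  rel <- reliability_analysis(
    fm, reps = cfg$reps, seed = cfg$seed, itv_mode = cfg$itv_mode,
    stratify_by_group = cfg$stratify_by_group
  )
  tables <- list(
    reliability_estimates = rel$estimates,
    reliability_grand = rel$grand
  )
  if (!is.null(rel$comparisons)) {
    tables$group_comparison <- rel$comparisons
  }
  write_outputs(cfg, tables)
  invisible(rel)
}

#' @rdname run_simulate
#' @export
run_itv <- function(cfg) {
  fm <- load_features(cfg)
  z <- zscore_features(fm, stratify_by_group = cfg$stratify_by_group)
  itv <- intraindividual_variability(z, mode = cfg$itv_mode)
  write_outputs(cfg, list(itv = itv))
  invisible(itv)
}

#' @rdname run_simulate
#' @export
run_report <- function(cfg) {
  fm <- load_features(cfg)
  rel <- reliability_analysis(
    fm, reps = cfg$reps, seed = cfg$seed, itv_mode = cfg$itv_mode,
    stratify_by_group = cfg$stratify_by_group
  )
  rep2 <- reliability_report(rel)
  write_outputs(cfg, list(
    feature_summary = feature_summary(fm, layout = "wide"),
    reliability_panel = rep2$reliability,
    itv_panel = rep2$itv
  ))
  invisible(rel)
}

parse_cli_flags <- function(args) {
  flags <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) abort(paste0("Unexpected argument: ", a))
    key <- gsub("-", "_", substring(a, 3))
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      abort(paste0("Flag ", a, " requires a value."))
    }
    flags[[key]] <- args[i + 1]
    i <- i + 2
  }
  for (k in c("reps", "seed", "n_mci", "n_intact", "min_tests")) {
    if (!is.null(flags[[k]])) flags[[k]] <- as.integer(flags[[k]])
  }
  for (k in c("stratify_by_group", "require_same_domain")) {
    if (!is.null(flags[[k]])) flags[[k]] <- as.logical(flags[[k]])
  }
  if (!is.null(flags$threshold_t)) {
    flags$threshold_t <- as.numeric(flags$threshold_t)
  }
  flags
}

#' Command-line dispatcher
#'
#' Implements the `speechlex` command line (see `inst/cli/speechlex.R`):
#' `speechlex <simulate|extract|reliability|itv|report> [--config FILE]
#' [--seed N] [--reps N] [--corpus-dir DIR] [--features-path FILE]
#' [--out-dir DIR] [--format csv|json|markdown] [--log-level info|quiet] ...`
#' Flags mirror [run_config()] keys one-to-one (`--out` is accepted as an
#' alias for `--out-dir`). Returns an exit status rather than quitting:
#' 0 on success, 2 on validation errors, 3 on statistical precondition
#' failures.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status, invisibly.
#' @export
speechlex_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  commands <- c("simulate", "extract", "reliability", "itv", "report")
  status <- tryCatch(
    {
      if (length(args) == 0 || !args[1] %in% commands) {
        abort(paste0(
          "Usage: speechlex <", paste(commands, collapse = "|"),
          "> [--flags]"
        ))
      }
      cmd <- args[1]
      flags <- parse_cli_flags(args[-1])
      if (!is.null(flags$out)) {
        flags$out_dir <- flags$out
        flags$out <- NULL
      }
      config_file <- flags$config
      flags$config <- NULL
      cfg <- do.call(run_config, c(list(config_file = config_file), flags))
      switch(cmd,
        simulate = run_simulate(cfg),
        extract = run_extract(cfg),
        reliability = run_reliability(cfg),
        itv = run_itv(cfg),
        report = run_report(cfg)
      )
      0L
    },
    speechlex_stat_error = function(e) {
      message("speechlex: statistical precondition failed: ",
              conditionMessage(e))
      3L
    },
    error = function(e) {
      message("speechlex: ", conditionMessage(e))
      2L
    }
  )
  invisible(status)
}
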