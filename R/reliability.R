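#' Fisher z machinery for averaging correlations
#'
#' Pearson correlations are averaged on the variance-stabilized Fisher z scale:
#' `fisher_z()` is atanh(r), `fisher_z_inverse()` is tanh(z), and
#' `fisher_average()` back-transforms the mean of the transformed values,
#' tanh(mean(atanh(r))). Averaging identical correlations returns that
#' correlation exactly.
#'
#' @param r numeric vector of correlations in [-1, 1].
#' @param z numeric vector of Fisher z values.
#' @return numeric vector (`fisher_average()` returns a scalar).
#' @examples
#' fisher_average(c(0.2, 0.6))
#' @export
fisher_z <- function(r) atanh(r)

#' @rdname fisher_z
#' @export
fisher_z_inverse <- function(z) tanh(z)

#' @rdname fisher_z
#' @export
fisher_average <- function(r) tanh(mean(atanh(r)))

#' Standardize a feature matrix within feature x task x group strata
#'
#' Converts raw feature values to z-scores so features measured on different
#' scales can be compared. Standardization is performed separately for every
#' (feature, task) cell — and additionally by cognitive status group when
#' `stratify_by_group = TRUE` — using the sample (n - 1) standard deviation.
#' After z-scoring, every stratum has mean 0 and sample SD 1.
#'
#' @param matrix long feature matrix (`participant_id`, `task_id`,
#'   `feature_name`, `value`, `group`).
#' @param stratify_by_group standardize within each group separately
#'   (default `TRUE`)? If `FALSE`, strata are (feature, task) over the full
#'   sample.
#' @return tibble of the same shape with `value` replaced by the z-score.
#' @export
zscore_features <- function(matrix, stratify_by_group = TRUE) {
  strata <- c("feature_name", "task_id", if (stratify_by_group) "group")
  out <- matrix |>
    dplyr::group_by(dplyr::across(dplyr::all_of(strata))) |>
    dplyr::mutate(
      .n = dplyr::n(),
      .sd = sd(.data$value),
      value = (.data$value - mean(.data$value)) / .data$.sd
    ) |>
    dplyr::ungroup()
  bad <- out$.n < 2 | !is.finite(out$.sd) | out$.sd == 0
  if (any(bad)) {
    b <- out[bad, ][1, ]
    abort_stat(paste0(
      "Cannot z-score constant or singleton stratum: feature ",
      b$feature_name, ", task ", b$task_id,
      if (stratify_by_group) paste0(", group ", b$group) else ""
    ))
  }
  dplyr::select(out, -".n", -".sd")
}

task_pairs <- function(type) {
  type <- match.arg(type, c("expository", "picture"))
  if (type == "expository") {
    list(c("ET1", "ET2"))
  } else {
    list(c("PDT1", "PDT2"), c("PDT1", "PDT3"), c("PDT2", "PDT3"))
  }
}

subset_group <- function(matrix, group) {
  if (identical(group, "full")) matrix else matrix[matrix$group == group, ]
}

# participants x features value matrix for one task, rows in `pids` order
task_matrix <- function(matrix, task, pids, features) {
  m <- matrix[matrix$task_id == task, ]
  wide <- tidyr::pivot_wider(
    m[, c("participant_id", "feature_name", "value")],
    names_from = "feature_name", values_from = "value"
  )
  missing_f <- setdiff(features, names(wide))
  if (length(missing_f) > 0 || !all(pids %in% wide$participant_id)) {
    abort(paste0("Incomplete feature matrix for task ", task))
  }
  out <- as.matrix(wide[match(pids, wide$participant_id), features])
  rownames(out) <- pids
  out
}

# column-standardize with the sample SD; errors on zero-variance columns
standardize_cols <- function(m, context) {
  mu <- colMeans(m)
  s <- apply(m, 2, sd)
  if (any(s == 0 | !is.finite(s))) {
    abort_stat(paste0(
      "Zero variance for feature(s) ",
      paste(colnames(m)[s == 0 | !is.finite(s)], collapse = ", "),
      " in ", context, "; correlation undefined."
    ))
  }
  sweep(sweep(m, 2, mu, "-"), 2, s, "/")
}

# per-feature correlations for each task pair: features x pairs matrix
pairwise_feature_correlations <- function(matrix, task_type, group) {
  m <- subset_group(matrix, group)
  pids <- sort(unique(m$participant_id))
  if (length(pids) < 3) {
    abort_stat(paste0("Group '", group, "' has fewer than 3 participants."))
  }
  features <- intersect(speech_feature_names(), unique(m$feature_name))
  pairs <- task_pairs(task_type)
  n <- length(pids)
  rs <- vapply(pairs, function(p) {
    a <- standardize_cols(
      task_matrix(m, p[1], pids, features), paste("task", p[1])
    )
    b <- standardize_cols(
      task_matrix(m, p[2], pids, features), paste("task", p[2])
    )
    colSums(a * b) / (n - 1)
  }, numeric(length(features)))
  rs <- matrix(rs, nrow = length(features), dimnames = list(features, NULL))
  list(r = rs, n = n, features = features, pairs = pairs, pids = pids)
}

#' Within-task-type test-retest reliability of each feature
#'
#' For every feature, correlates the (z-scored) feature with itself across
#' repeated instances of the same task type: the single ET1-ET2 Pearson
#' correlation for expository tasks, or the Fisher-z average of the three
#' pairwise picture-task correlations (PDT1-PDT2, PDT1-PDT3, PDT2-PDT3).
#' Because z-scoring is an affine transform within each stratum, the
#' correlations are numerically identical whether computed on raw or z-scored
#' values.
#'
#' @param matrix a (typically z-scored) long feature matrix; see
#'   [zscore_features()].
#' @param task_type `"expository"` or `"picture"`.
#' @param group `"full"` (all participants, default), `"MCI"`, or `"intact"`.
#' @return tibble with one row per feature: `feature_name`, `task_type`,
#'   `group`, `r_mean` (Fisher-averaged Pearson r), `n_pairs` (1 expository,
#'   3 picture), `n` (participants).
#' @export
within_feature_reliability <- function(matrix, task_type, group = "full") {
  pc <- pairwise_feature_correlations(matrix, task_type, group)
  tibble::tibble(
    feature_name = pc$features,
    task_type = task_type,
    group = group,
    r_mean = unname(apply(pc$r, 1, fisher_average)),
    n_pairs = length(pc$pairs),
    n = pc$n
  )
}

# uniformly random derangement by rejection sampling
random_derangement <- function(n) {
  if (n < 2) abort("Derangement requires n >= 2.")
  repeat {
    p <- sample.int(n)
    if (all(p != seq_len(n))) return(p)
  }
}

grand_fisher_mean <- function(r) tanh(mean(atanh(r)))

#' Resampling null distribution for within-feature reliability
#'
#' Builds the chance baseline against which the observed mean within-feature
#' correlation is judged. Each replicate re-pairs participants by a uniformly
#' random derangement (no participant is ever paired with themself, and each
#' participant's values are used exactly once): one side of every task pair is
#' permuted, all per-feature correlations are recomputed, and their Fisher-z
#' average over features and pairs gives one null value. A single derangement
#' is used for all features within a replicate, preserving the cross-feature
#' dependence structure. The one-sided p-value for the observed grand mean
#' uses add-one smoothing: (1 + #\{null >= observed\}) / (1 + reps), so it can
#' never be exactly zero.
#'
#' @inheritParams within_feature_reliability
#' @param reps number of resampling replicates (the study design uses 10,000).
#'   A warning is issued below 100.
#' @param seed integer seed; required, so every null distribution is exactly
#'   reproducible.
#' @return object of class `speech_resample_null`: a list with `observed`
#'   (grand Fisher-mean correlation), `null` (numeric vector of length
#'   `reps`), `null_mean`, `null_sd`, `p_value`, `task_type`, `group`, `reps`,
#'   `seed`, `n`.
#' @export
resample_null <- function(matrix, task_type, group = "full",
                          reps = 10000, seed) {
  if (missing(seed)) abort("`seed` is required for a reproducible null.")
  if (reps < 1) abort("`reps` must be >= 1.")
  if (reps < 100) warn("Fewer than 100 resampling replicates; p-values will be coarse.")
  pc <- pairwise_feature_correlations(matrix, task_type, group)
  if (pc$n < 4) abort_stat(paste0("Group '", group, "' has fewer than 4 participants."))
  observed <- grand_fisher_mean(pc$r)

  m <- subset_group(matrix, group)
  mats <- lapply(
    setNames(nm = unique(unlist(pc$pairs))),
    function(task) standardize_cols(
      task_matrix(m, task, pc$pids, pc$features), paste("task", task)
    )
  )
  n <- pc$n
  null <- with_preserved_seed(seed, vapply(seq_len(reps), function(i) {
    perm <- random_derangement(n)
    rs <- unlist(lapply(pc$pairs, function(p) {
      colSums(mats[[p[1]]] * mats[[p[2]]][perm, , drop = FALSE]) / (n - 1)
    }))
    grand_fisher_mean(rs)
  }, numeric(1)))

  structure(
    list(
      observed = observed,
      null = null,
      null_mean = mean(null),
      null_sd = sd(null),
      p_value = (1 + sum(null >= observed)) / (1 + reps),
      task_type = task_type,
      group = group,
      reps = reps,
      seed = seed,
      n = n
    ),
    class = "speech_resample_null"
  )
}

#' @export
print.speech_resample_null <- function(x, ...) {
  cat(
    "<speech_resample_null> ", x$task_type, " tasks, group ", x$group,
    " (n = ", x$n, ")\n",
    "  observed grand mean r = ", format(round(x$observed, 4)),
    "; null mean = ", format(round(x$null_mean, 4)),
    " (SD ", format(round(x$null_sd, 4)), ", ", x$reps, " reps)\n",
    "  one-sided p = ", format.pval(x$p_value), "\n",
    sep = ""
  )
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.speech_resample_null <- function(x, ...) {
  tibble::tibble(
    task_type = x$task_type, group = x$group, n = x$n,
    observed = x$observed, null_mean = x$null_mean, null_sd = x$null_sd,
    p_value = x$p_value, reps = x$reps
  )
}

#' Compare per-feature reliability between cognitive status groups
#'
#' Two-sample pooled-variance t-test on the Fisher-z-transformed per-feature
#' mean correlations of two groups (16 features per group gives 30 degrees of
#' freedom). The 95% confidence interval of the mean difference is
#' back-transformed to the correlation scale.
#'
#' @param r_mci,r_intact numeric vectors of per-feature mean correlations
#'   (equal length, one per feature).
#' @param conf_level confidence level for the interval (default 0.95).
#' @return object of class `speech_group_comparison` with fields `t`, `df`,
#'   `p_value`, `estimate` (mean z difference back-transformed to r),
#'   `ci_low`, `ci_high` (r scale).
#' @export
compare_groups <- function(r_mci, r_intact, conf_level = 0.95) {
  if (length(r_mci) != length(r_intact)) {
    abort("Both groups must supply one mean correlation per feature.")
  }
  if (length(r_mci) < 2) abort("Need at least 2 features per group.")
  z1 <- atanh(r_mci)
  z2 <- atanh(r_intact)
  n1 <- length(z1)
  n2 <- length(z2)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(z1) + (n2 - 1) * stats::var(z2)) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  diff_z <- mean(z1) - mean(z2)
  tstat <- if (se == 0) 0 else diff_z / se
  crit <- qt(1 - (1 - conf_level) / 2, df)
  structure(
    list(
      t = tstat,
      df = df,
      p_value = 2 * pt(-abs(tstat), df),
      estimate = tanh(diff_z),
      ci_low = tanh(diff_z - crit * se),
      ci_high = tanh(diff_z + crit * se),
      conf_level = conf_level,
      n_features = n1
    ),
    class = "speech_group_comparison"
  )
}

#' @export
print.speech_group_comparison <- function(x, ...) {
  cat(
    "<speech_group_comparison> t(", x$df, ") = ", format(round(x$t, 4)),
    ", p = ", format.pval(x$p_value),
    ", ", round(100 * x$conf_level), "% CI [",
    format(round(x$ci_low, 2)), ", ", format(round(x$ci_high, 2)),
    "] (r scale)\n",
    sep = ""
  )
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.speech_group_comparison <- function(x, ...) {
  tibble::tibble(
    estimate = x$estimate, statistic = x$t, df = x$df, p.value = x$p_value,
    conf.low = x$ci_low, conf.high = x$ci_high
  )
}

#' @exportS3Method generics::glance
glance.speech_group_comparison <- function(x, ...) {
  tidy.speech_group_comparison(x)
}

#' Intraindividual variability of features across all five tasks
#'
#' Quantifies how much a participant's standardized feature value moves across
#' the five tasks. In the default `per_participant_sd` mode, each
#' participant's sample SD of their five z-scores is computed per feature and
#' averaged over the group's participants. The alternative `variance_pooled`
#' mode computes, per feature, the sum over tasks of the squared
#' across-participant SDs divided by the number of participants. Larger
#' values reflect greater intraindividual variability.
#'
#' @inheritParams within_feature_reliability
#' @param mode `"per_participant_sd"` (default) or `"variance_pooled"`.
#' @param by_group compute separately per group in addition to the full
#'   sample (default `TRUE`).
#' @return tibble with columns `feature_name`, `group`, `itv`, `mode`.
#' @export
intraindividual_variability <- function(matrix,
                                        mode = c("per_participant_sd", "variance_pooled"),
                                        by_group = TRUE) {
  mode <- match.arg(mode)
  complete <- matrix |>
    dplyr::count(.data$participant_id, .data$feature_name) |>
    dplyr::filter(.data$n != length(speech_tasks()))
  if (nrow(complete) > 0) {
    abort(paste0(
      "Participant ", complete$participant_id[1], " is missing task values",
      " for feature ", complete$feature_name[1], "."
    ))
  }
  one_group <- function(m, label) {
    res <- if (mode == "per_participant_sd") {
      m |>
        dplyr::group_by(.data$feature_name, .data$participant_id) |>
        dplyr::summarise(psd = sd(.data$value), .groups = "drop_last") |>
        dplyr::summarise(itv = mean(.data$psd), .groups = "drop")
    } else {
      n_part <- dplyr::n_distinct(m$participant_id)
      m |>
        dplyr::group_by(.data$feature_name, .data$task_id) |>
        dplyr::summarise(tsd = sd(.data$value), .groups = "drop_last") |>
        dplyr::summarise(itv = sum(.data$tsd^2) / n_part, .groups = "drop")
    }
    dplyr::mutate(res, group = label, mode = mode, .after = "feature_name")
  }
  out <- one_group(matrix, "full")
  if (by_group && "group" %in% names(matrix) &&
      dplyr::n_distinct(matrix$group) > 1) {
    per <- lapply(
      sort(unique(matrix$group)),
      function(g) one_group(matrix[matrix$group == g, ], g)
    )
    out <- dplyr::bind_rows(out, per)
  }
  out
}

#' Full reliability analysis of a feature matrix
#'
#' One-call driver reproducing the study's analysis: z-scores the feature
#' matrix within (feature, task, group) strata, computes per-feature
#' within-task-type reliabilities for each group and the full sample, builds
#' the resampling null for each task type x group combination, tests the
#' MCI vs intact difference in per-feature correlations for each task type,
#' and computes cross-task intraindividual variability.
#'
#' @param matrix raw long feature matrix with a `group` column
#'   (`"MCI"` / `"intact"`, or a single group for an unstratified analysis).
#' @param reps resampling replicates per null distribution (default 10,000).
#' @param seed integer seed controlling all resampling.
#' @param itv_mode passed to [intraindividual_variability()].
#' @param stratify_by_group passed to [zscore_features()].
#' @return object of class `speech_reliability`: list with `estimates`
#'   (per-feature tibble incl. null summaries and grand p-values), `grand`
#'   (per task type x group summary), `comparisons` (group t-tests),
#'   `itv` (intraindividual variability tibble), `nulls` (list of
#'   `speech_resample_null`), `zscores` (the z-scored matrix).
#' @export
reliability_analysis <- function(matrix, reps = 10000, seed,
                                 itv_mode = "per_participant_sd",
                                 stratify_by_group = TRUE) {
  if (missing(seed)) abort("`seed` is required.")
  z <- zscore_features(matrix, stratify_by_group = stratify_by_group)
  groups_present <- sort(unique(matrix$group))
  two_groups <- all(c("MCI", "intact") %in% groups_present)
  groups <- c("full", if (two_groups) c("MCI", "intact"))

  grid <- tidyr::expand_grid(
    task_type = c("expository", "picture"), group = groups
  )
  nulls <- purrr::pmap(grid, function(task_type, group) {
    resample_null(
      z, task_type, group,
      reps = reps,
      seed = seed + 7L * (match(task_type, c("expository", "picture")) - 1L) +
        31L * (match(group, groups) - 1L)
    )
  })
  names(nulls) <- paste(grid$task_type, grid$group, sep = ".")

  estimates <- purrr::pmap(grid, function(task_type, group) {
    est <- within_feature_reliability(z, task_type, group)
    nul <- nulls[[paste(task_type, group, sep = ".")]]
    dplyr::mutate(
      est,
      null_mean = nul$null_mean, null_sd = nul$null_sd,
      p_value = nul$p_value
    )
  }) |> dplyr::bind_rows()

  grand <- purrr::map(nulls, tidy) |> dplyr::bind_rows()
  grand$r_sd <- purrr::pmap_dbl(
    grand[, c("task_type", "group")],
    function(task_type, group) {
      sd(estimates$r_mean[
        estimates$task_type == task_type & estimates$group == group
      ])
    }
  )

  comparisons <- NULL
  if (two_groups) {
    comparisons <- purrr::map(
      c("expository", "picture"),
      function(tt) {
        pick <- function(g) {
          e <- estimates[estimates$task_type == tt & estimates$group == g, ]
          e$r_mean[match(speech_feature_names(), e$feature_name)]
        }
        cmp <- compare_groups(pick("MCI"), pick("intact"))
        dplyr::mutate(tidy(cmp), task_type = tt, .before = 1)
      }
    ) |> dplyr::bind_rows()
  }

  structure(
    list(
      estimates = estimates,
      grand = grand,
      comparisons = comparisons,
      itv = intraindividual_variability(z, mode = itv_mode),
      nulls = nulls,
      zscores = z,
      reps = reps,
      seed = seed
    ),
    class = "speech_reliability"
  )
}

#' @export
print.speech_reliability <- function(x, ...) {
  cat(
    "<speech_reliability> ",
    dplyr::n_distinct(x$estimates$feature_name), " features, ",
    x$reps, " resampling reps (seed ", x$seed, ")\n",
    sep = ""
  )
  print(x$grand)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.speech_reliability <- function(x, ...) x$estimates

#' @exportS3Method generics::glance
glance.speech_reliability <- function(x, ...) x$grand
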