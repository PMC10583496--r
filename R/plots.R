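#' Plot per-feature reliability estimates
#'
#' Dot plot of the Fisher-averaged within-feature correlations, features on
#' the y axis (reporting order), one panel per task type, coloured by group,
#' with the corresponding null means as hollow points for reference.
#'
#' @param object a `speech_reliability` object from [reliability_analysis()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot speech_reliability
#' @export
autoplot.speech_reliability <- function(object, ...) {
  est <- object$estimates
  est$feature_name <- factor(
    est$feature_name, levels = rev(speech_feature_names())
  )
  ggplot2::ggplot(
    est,
    ggplot2::aes(
      x = .data$r_mean, y = .data$feature_name, colour = .data$group
    )
  ) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, colour = "grey50") +
    ggplot2::geom_point(
      ggplot2::aes(x = .data$null_mean), shape = 1, alpha = 0.6
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$task_type)) +
    ggplot2::labs(
      x = "mean within-feature correlation (Fisher-averaged r)",
      y = NULL, colour = "group",
      title = "Within-task-type reliability of speech features",
      subtitle = "hollow points: resampling null means"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.speech_reliability
#' @export
plot_reliability <- function(object, ...) autoplot.speech_reliability(object, ...)

#' Plot a resampling null distribution
#'
#' Histogram of the null grand-mean correlations with the observed value
#' marked; the one-sided p-value is shown in the subtitle.
#'
#' @param object a `speech_resample_null` object from [resample_null()].
#' @param bins histogram bins (default 50).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot speech_resample_null
#' @export
autoplot.speech_resample_null <- function(object, bins = 50, ...) {
  ggplot2::ggplot(
    tibble::tibble(null = object$null),
    ggplot2::aes(x = .data$null)
  ) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "white") +
    ggplot2::geom_vline(
      xintercept = object$observed, colour = "firebrick", linewidth = 0.8
    ) +
    ggplot2::labs(
      x = "null grand-mean correlation",
      y = "replicates",
      title = paste0(
        "Resampling null: ", object$task_type, " tasks, group ", object$group
      ),
      subtitle = paste0(
        "observed r = ", round(object$observed, 3),
        ", one-sided p = ", format.pval(object$p_value),
        " (", object$reps, " reps)"
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot intraindividual variability by feature and group
#'
#' @param itv the tibble returned by [intraindividual_variability()].
#' @return a ggplot object.
#' @export
plot_itv <- function(itv) {
  itv$feature_name <- factor(
    itv$feature_name, levels = rev(speech_feature_names())
  )
  ggplot2::ggplot(
    itv,
    ggplot2::aes(x = .data$itv, y = .data$feature_name, colour = .data$group)
  ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "intraindividual variability (mean within-person SD of z-scores)",
      y = NULL, colour = "group",
      title = "Cross-task intraindividual variability"
    ) +
    ggplot2::theme_minimal()
}
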