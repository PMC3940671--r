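# ggplot2 figures for condition summaries, score tables and reliability.

#' Plot condition medians
#'
#' Cohort distribution of per-subject median reaction time (or accuracy) in
#' each of the six cue-by-target cells.
#'
#' @param summaries A condition-summary tibble.
#' @param measure `"median_rt_ms"` (default) or `"accuracy"`.
#' @return A ggplot object.
#' @export
plot_condition_summary <- function(summaries,
                                   measure = c("median_rt_ms", "accuracy")) {
  measure <- match.arg(measure)
  data <- summaries |>
    dplyr::inner_join(ant_conditions(), by = "condition") |>
    dplyr::mutate(cue = factor(.data$cue, levels = c("none", "center", "spatial")))
  ggplot2::ggplot(data, ggplot2::aes(x = .data$cue, y = .data[[measure]],
                                     colour = .data$target)) +
    ggplot2::geom_boxplot(outlier.shape = NA, position = ggplot2::position_dodge(0.6),
                          width = 0.5) +
    ggplot2::geom_point(position = ggplot2::position_jitterdodge(
      jitter.width = 0.08, dodge.width = 0.6), alpha = 0.4, size = 1) +
    ggplot2::labs(x = "Cue", y = if (measure == "accuracy") "Accuracy"
                  else "Median RT (ms)",
                  colour = "Target") +
    ggplot2::theme_minimal()
}

#' @describeIn score_cohort Boxplots of every score item across the cohort.
#' @param object An `ant_scores` tibble.
#' @param ... Unused.
#' @export
autoplot.ant_scores <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(-"subject", names_to = "item", values_to = "score") |>
    dplyr::mutate(item = factor(.data$item, levels = unique(.data$item)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$item, y = .data$score)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_boxplot(width = 0.5, outlier.shape = NA) +
    ggplot2::geom_point(alpha = 0.35, size = 1,
                        position = ggplot2::position_jitter(width = 0.08)) +
    ggplot2::labs(x = NULL, y = "Score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @describeIn reliability_report Dot chart of ICC and split-half
#'   reliability per score item.
#' @param object A `reliability_report`.
#' @param ... Unused.
#' @export
autoplot.reliability_report <- function(object, ...) {
  long <- tidy(object) |>
    tidyr::pivot_longer(-"item", names_to = "index", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$item,
                                     colour = .data$index)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Reliability", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
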