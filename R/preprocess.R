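# Trial- and subject-level filters and per-condition reduction.

#' Remove reaction-time outliers by a fixed window
#'
#' Drops trials whose reaction time falls strictly below `low_ms` or strictly
#' above `high_ms`; responses exactly at either bound are retained.
#' Non-response trials carry no reaction time and pass through unchanged.
#' The fraction of responses removed is attached as the `removed_fraction`
#' attribute and retrievable with [removed_fraction()].
#'
#' @param trials A validated trial tibble.
#' @param low_ms,high_ms Window bounds in milliseconds (defaults 200 and
#'   1200).
#' @return The retained trials, with attribute `removed_fraction` =
#'   removed responses / total responses.
#' @examples
#' trials <- simulate_dataset(sim_config(n_subjects = 2, seed = 1))
#' kept <- filter_rt_window(trials)
#' removed_fraction(kept)
#' @export
filter_rt_window <- function(trials, low_ms = 200, high_ms = 1200) {
  if (low_ms >= high_ms) {
    abort("Invalid RT window: low_ms must be strictly less than high_ms")
  }
  has_rt <- !is.na(trials$rt_ms)
  out_of_window <- has_rt & (trials$rt_ms < low_ms | trials$rt_ms > high_ms)
  kept <- trials[!out_of_window, , drop = FALSE]
  n_responses <- sum(has_rt)
  frac <- if (n_responses == 0) 0 else sum(out_of_window) / n_responses
  attr(kept, "removed_fraction") <- frac
  kept
}

#' @rdname filter_rt_window
#' @param x A tibble returned by [filter_rt_window()].
#' @export
removed_fraction <- function(x) {
  frac <- attr(x, "removed_fraction", exact = TRUE)
  if (is.null(frac)) abort("No removed_fraction attribute; was filter_rt_window() applied?")
  frac
}

#' Per-subject, per-condition accuracy
#'
#' Accuracy is correct responses over all window-filtered trials of the
#' condition, so misses (no response before the deadline) count against
#' accuracy. Conditions with zero trials for a subject are flagged with
#' `NA` accuracy rather than zero.
#'
#' @param trials Window-filtered trial tibble.
#' @return Tibble with columns `subject`, `condition`, `n_trials`,
#'   `n_correct`, `accuracy`, six rows per subject.
#' @export
accuracy_by_condition <- function(trials) {
  trials |>
    dplyr::group_by(.data$subject, .data$condition) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_correct = sum(.data$correct, na.rm = TRUE),
      .groups = "drop"
    ) |>
    tidyr::complete(
      subject = unique(trials$subject),
      condition = ant_condition_codes,
      fill = list(n_trials = 0L, n_correct = 0L)
    ) |>
    dplyr::mutate(
      accuracy = ifelse(.data$n_trials > 0, .data$n_correct / .data$n_trials, NA_real_)
    ) |>
    dplyr::arrange(.data$subject, match(.data$condition, ant_condition_codes))
}

#' Exclude subjects with low accuracy in any condition
#'
#' A subject is excluded when accuracy falls strictly below `threshold` in at
#' least one of the six conditions; a subject sitting exactly at the
#' threshold is retained. The exclusion report (subject, offending condition,
#' accuracy) is attached as the `exclusions` attribute and retrievable with
#' [exclusions()].
#'
#' @param summaries A condition-summary or accuracy tibble with columns
#'   `subject`, `condition`, `accuracy` (all six conditions per subject).
#' @param threshold Accuracy threshold (default 0.75).
#' @return The rows for retained subjects, with attribute `exclusions`.
#' @export
exclude_low_accuracy <- function(summaries, threshold = 0.75) {
  n_cond <- summaries |>
    dplyr::count(.data$subject) |>
    dplyr::filter(.data$n != 6L)
  if (nrow(n_cond) > 0) {
    abort(paste0("All six conditions required per subject; incomplete: ",
                 paste(n_cond$subject, collapse = ", ")))
  }
  offending <- summaries |>
    dplyr::filter(is.na(.data$accuracy) | .data$accuracy < threshold) |>
    dplyr::select("subject", "condition", "accuracy")
  retained <- summaries |>
    dplyr::filter(!.data$subject %in% offending$subject)
  attr(retained, "exclusions") <- offending
  retained
}

#' @rdname exclude_low_accuracy
#' @param x A tibble returned by [exclude_low_accuracy()].
#' @export
exclusions <- function(x) {
  ex <- attr(x, "exclusions", exact = TRUE)
  if (is.null(ex)) abort("No exclusions attribute; was exclude_low_accuracy() applied?")
  ex
}

#' Reduce trials to per-subject condition summaries
#'
#' Computes, for every subject and condition, the median reaction time over
#' correct responses, plus accuracy over all window-filtered trials. Medians
#' of an even number of trials are the midpoint of the two middle order
#' statistics. A condition with zero correct trials for a subject cannot be
#' summarised and raises an error naming the subject.
#'
#' @param trials Window-filtered trial tibble.
#' @return A condition-summary tibble: `subject`, `condition`,
#'   `median_rt_ms`, `accuracy`, `n_trials`, `n_correct`, six rows per
#'   subject in canonical condition order.
#' @examples
#' sim_config(n_subjects = 3, seed = 7) |>
#'   simulate_dataset() |>
#'   filter_rt_window() |>
#'   summarize_conditions()
#' @export
summarize_conditions <- function(trials) {
  acc <- accuracy_by_condition(trials)
  med <- trials |>
    dplyr::filter(!is.na(.data$correct) & .data$correct) |>
    dplyr::group_by(.data$subject, .data$condition) |>
    dplyr::summarise(median_rt_ms = median(.data$rt_ms), .groups = "drop")
  out <- acc |>
    dplyr::left_join(med, by = c("subject", "condition")) |>
    dplyr::select("subject", "condition", "median_rt_ms", "accuracy",
                  "n_trials", "n_correct") |>
    dplyr::arrange(.data$subject, match(.data$condition, ant_condition_codes))
  no_correct <- out |> dplyr::filter(is.na(.data$median_rt_ms))
  if (nrow(no_correct) > 0) {
    abort(paste0(
      "No correct trials to summarise for subject(s) ",
      paste(unique(no_correct$subject), collapse = ", "),
      " in condition(s) ",
      paste(unique(no_correct$condition), collapse = ", ")
    ))
  }
  out
}

#' Full preprocessing pipeline
#'
#' Applies the fixed preprocessing order: reaction-time window filter, then
#' per-condition accuracy over the remaining trials, then subject exclusion
#' by minimum condition accuracy, then per-condition medians over correct
#' trials of the retained subjects.
#'
#' @param trials A validated trial tibble.
#' @param rt_min,rt_max Reaction-time window in ms (defaults 200, 1200).
#' @param accuracy_threshold Minimum per-condition accuracy (default 0.75).
#' @return A list with elements `summary` (condition-summary tibble for
#'   retained subjects), `removed_fraction` (share of responses outside the
#'   RT window), `exclusions` (tibble naming excluded subjects and their
#'   offending conditions), `n_subjects_in`, `n_subjects_retained`.
#' @export
preprocess_trials <- function(trials, rt_min = 200, rt_max = 1200,
                              accuracy_threshold = 0.75) {
  filtered <- filter_rt_window(trials, rt_min, rt_max)
  acc <- accuracy_by_condition(filtered)
  retained <- exclude_low_accuracy(acc, accuracy_threshold)
  kept_trials <- dplyr::filter(filtered, .data$subject %in% unique(retained$subject))
  summaries <- summarize_conditions(kept_trials)
  list(
    summary = summaries,
    removed_fraction = removed_fraction(filtered),
    exclusions = exclusions(retained),
    n_subjects_in = dplyr::n_distinct(trials$subject),
    n_subjects_retained = dplyr::n_distinct(retained$subject)
  )
}
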