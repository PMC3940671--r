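# broom-style tidiers for fitted objects.

#' Tidy a repeated-measures ANOVA
#'
#' @param x An `rm_anova` object.
#' @param ... Unused.
#' @return A tibble with one row per effect: `effect`, `df`, `df_error`,
#'   `statistic`, `p_value`, `partial_eta_sq`, `epsilon`, `df_gg`,
#'   `df_error_gg`, `p_value_gg`.
#' @export
tidy.rm_anova <- function(x, ...) {
  dplyr::select(x$table, -"ss", -"ss_error")
}

#' @rdname tidy.rm_anova
#' @return `glance()` returns a one-row tibble: `n_subjects`, `levels_a`,
#'   `levels_b`.
#' @export
glance.rm_anova <- function(x, ...) {
  tibble::tibble(n_subjects = x$n,
                 levels_a = unname(x$factors[1]),
                 levels_b = unname(x$factors[2]))
}

#' Tidy an intraclass correlation
#'
#' @param x An `icc_oneway` object.
#' @param ... Unused.
#' @return A one-row tibble: `icc`, `ms_between`, `ms_within`, `n`, `k`.
#' @export
tidy.icc_oneway <- function(x, ...) {
  tibble::tibble(icc = x$icc, ms_between = x$ms_between,
                 ms_within = x$ms_within, n = x$n, k = x$k)
}

#' @rdname tidy.icc_oneway
#' @export
glance.icc_oneway <- function(x, ...) tidy.icc_oneway(x)

#' Tidy a split-half result
#'
#' @param x A `split_half` object.
#' @param ... Unused.
#' @return A tibble: `item`, `mean_r`, `sd_r`.
#' @export
tidy.split_half <- function(x, ...) {
  tibble::as_tibble(x)[, c("item", "mean_r", "sd_r")]
}

#' Tidy a reliability report
#'
#' @param x A `reliability_report` object.
#' @param ... Unused.
#' @return A tibble with one row per score item joining the ICC and
#'   split-half columns: `item`, `icc`, `split_half_r`.
#' @export
tidy.reliability_report <- function(x, ...) {
  sh <- dplyr::rename(x$split_half, split_half_r = "mean_r")
  if (is.null(x$icc)) {
    return(dplyr::select(sh, "item", "split_half_r"))
  }
  dplyr::full_join(dplyr::select(x$icc, "item", "icc"),
                   dplyr::select(sh, "item", "split_half_r"),
                   by = "item")
}

#' @rdname tidy.reliability_report
#' @export
glance.reliability_report <- function(x, ...) {
  tibble::tibble(n_runs = x$n_runs, n_perm = x$n_perm,
                 normalization = x$normalization)
}
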