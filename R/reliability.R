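# Test-retest ICC across runs and permutation split-half consistency.

#' One-way random-effects intraclass correlation
#'
#' Decomposes an n-subject by k-run score grid with a one-way random-subject
#' ANOVA into between-subject (`MSb`) and within-subject (`MSw`, residual)
#' mean squares and returns
#' \deqn{ICC = (MSb - MSw) / (MSb + (k - 1) MSw)}
#' where `k` is the number of repeated observations per subject. The ICC is
#' 1 exactly when subjects differ but repeats agree perfectly (`MSw = 0`),
#' and tends to the between-subject share of total variance,
#' \eqn{\sigma_b^2 / (\sigma_b^2 + \sigma_w^2)}, for large samples.
#'
#' @param x Either a numeric matrix (rows = subjects, columns = runs) with
#'   no missing cells, or a long data frame, in which case `subject`, `run`
#'   and `value` name its columns.
#' @param subject,run,value Column names used when `x` is a data frame.
#' @return An object of class `icc_oneway`: list with `icc`, `ms_between`,
#'   `ms_within`, `n`, `k`. Has `tidy()` and `print()` methods.
#' @examples
#' icc_oneway(matrix(c(1, 2, 2, 1), nrow = 2, byrow = TRUE))  # icc = -1
#' @export
icc_oneway <- function(x, subject = "subject", run = "run", value = "value") {
  if (is.data.frame(x)) {
    wide <- x |>
      dplyr::select(subject = dplyr::all_of(subject),
                    run = dplyr::all_of(run),
                    value = dplyr::all_of(value)) |>
      tidyr::pivot_wider(names_from = "run", values_from = "value") |>
      dplyr::arrange(.data$subject)
    x <- as.matrix(wide[, -1, drop = FALSE])
    rownames(x) <- wide$subject
  }
  if (!is.matrix(x)) abort("x must be a matrix or data frame")
  if (anyNA(x)) abort("Missing cells in the subject-by-run grid; no imputation is done")
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) abort("Need at least 2 subjects and 2 runs")
  subj_means <- rowMeans(x)
  grand <- mean(x)
  ms_between <- k * sum((subj_means - grand)^2) / (n - 1)
  ms_within <- sum((x - subj_means)^2) / (n * (k - 1))
  icc <- (ms_between - ms_within) / (ms_between + (k - 1) * ms_within)
  structure(
    list(icc = icc, ms_between = ms_between, ms_within = ms_within,
         n = n, k = k),
    class = "icc_oneway"
  )
}

#' @export
print.icc_oneway <- function(x, ...) {
  cat(sprintf(
    "One-way random-effects ICC: %.3f  (MSb = %.3f, MSw = %.3f, n = %d, k = %d)\n",
    x$icc, x$ms_between, x$ms_within, x$n, x$k))
  invisible(x)
}

#' Per-run cohort scores
#'
#' Computes condition summaries and cohort scores separately within each
#' run (block), the per-run values that feed the test-retest ICC.
#'
#' @param trials Window-filtered trial tibble with a `block` column.
#' @param ... Passed to [score_cohort()] (e.g. `normalization`).
#' @return A tibble of per-subject scores with a leading `run` column.
#' @export
scores_by_run <- function(trials, ...) {
  runs <- sort(unique(trials$block))
  purrr::map_dfr(runs, function(r) {
    trials |>
      dplyr::filter(.data$block == r) |>
      summarize_conditions() |>
      score_cohort(...) |>
      dplyr::mutate(run = r, .before = 1) |>
      tibble::as_tibble()
  })
}

# split one subject-condition RT vector into two random halves; odd counts
# give the extra trial to a random half
split_medians <- function(rts) {
  n <- length(rts)
  idx <- sample.int(n)
  n1 <- n %/% 2L
  if (n %% 2L == 1L && runif(1) < 0.5) n1 <- n1 + 1L
  c(median(rts[idx[seq_len(n1)]]), median(rts[idx[(n1 + 1L):n]]))
}

#' Permutation split-half reliability
#'
#' Estimates internal consistency by randomly splitting, within each subject
#' and condition, the correct window-filtered trials into two halves;
#' summarising each half by its median; scoring both halves; and correlating
#' the two half-scores across subjects (Pearson) for every score item. The
#' split is repeated `n_perm` times (default 1000) and the reliability of an
#' item is the mean of its per-split correlations. No Spearman-Brown
#' step-up is applied by default; set `spearman_brown = TRUE` to report
#' `2r / (1 + r)` per split instead.
#'
#' Subjects with fewer than 2 correct trials in any condition cannot be
#' split and are dropped with a warning.
#'
#' @param trials Window-filtered trial tibble.
#' @param method,normalization,relations Passed to [score_cohort()];
#'   defaults score both methods and the relations in raw (millisecond)
#'   mode, the stable choice when halves contain few trials.
#' @param n_perm Number of random splits (default 1000).
#' @param seed Integer seed making the permutations reproducible.
#' @param spearman_brown Apply the Spearman-Brown correction per split?
#'   Default `FALSE` (report the mean split correlation itself).
#' @return An object of class `split_half`: tibble with one row per score
#'   item (`item`, `mean_r`, `sd_r`) plus attributes `n_perm`, `seed`, and
#'   the full item-by-permutation correlation matrix (`perm_r`).
#' @export
split_half <- function(trials, method = "both", normalization = "raw",
                       relations = TRUE, n_perm = 1000, seed = NULL,
                       spearman_brown = FALSE) {
  correct <- trials |>
    dplyr::filter(!is.na(.data$correct) & .data$correct)
  counts <- correct |>
    dplyr::count(.data$subject, .data$condition) |>
    tidyr::complete(subject = unique(trials$subject),
                    condition = ant_condition_codes,
                    fill = list(n = 0L))
  bad <- counts |> dplyr::filter(.data$n < 2L)
  if (nrow(bad) > 0) {
    warn(paste0("Dropping subject(s) with < 2 correct trials in a condition: ",
                paste(unique(bad$subject), collapse = ", ")))
    correct <- correct |> dplyr::filter(!.data$subject %in% unique(bad$subject))
  }
  subjects <- sort(unique(correct$subject))
  if (length(subjects) < 3) abort("Need at least 3 splittable subjects")

  # list of RT vectors in (subject x condition) order, subject-major
  keys <- tidyr::expand_grid(subject = subjects, condition = ant_condition_codes)
  rt_groups <- purrr::map2(keys$subject, keys$condition, function(s, cc) {
    correct$rt_ms[correct$subject == s & correct$condition == cc]
  })
  n_subj <- length(subjects)

  score_mats <- function(m) {
    parts <- list()
    if (method %in% c("both", "old")) {
      parts$old <- old_scores_mat(m, if (normalization == "raw") "raw" else "baseline")
      colnames(parts$old) <- paste0("old_", colnames(parts$old))
    }
    if (method %in% c("both", "new")) {
      parts$new <- new_scores_mat(m, if (normalization == "raw") "raw" else "baseline")
      colnames(parts$new) <- paste0("new_", colnames(parts$new))
    }
    if (relations) {
      parts$rel <- relation_scores_mat(m, if (normalization == "raw") "raw" else "score")
    }
    do.call(cbind, parts)
  }

  one_perm <- function() {
    halves <- vapply(rt_groups, split_medians, numeric(2))
    m1 <- matrix(halves[1, ], nrow = n_subj, ncol = 6, byrow = TRUE,
                 dimnames = list(subjects, ant_condition_codes))
    m2 <- matrix(halves[2, ], nrow = n_subj, ncol = 6, byrow = TRUE,
                 dimnames = list(subjects, ant_condition_codes))
    s1 <- score_mats(m1); s2 <- score_mats(m2)
    r <- vapply(seq_len(ncol(s1)), function(j) {
      suppressWarnings(cor(s1[, j], s2[, j], use = "complete.obs"))
    }, numeric(1))
    names(r) <- colnames(s1)
    if (spearman_brown) r <- 2 * r / (1 + r)
    r
  }

  item_names <- colnames(score_mats(matrix(
    500 + seq_len(6 * n_subj), n_subj, 6,
    dimnames = list(subjects, ant_condition_codes))))
  perm_r <- with_seed_opt(seed, {
    vapply(seq_len(n_perm), function(i) one_perm(),
           numeric(length(item_names)))
  })
  if (is.null(dim(perm_r))) perm_r <- matrix(perm_r, nrow = length(item_names))
  rownames(perm_r) <- item_names

  out <- tibble::tibble(
    item = item_names,
    mean_r = unname(rowMeans(perm_r, na.rm = TRUE)),
    sd_r = unname(apply(perm_r, 1, sd, na.rm = TRUE))
  )
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "perm_r") <- perm_r
  class(out) <- c("split_half", class(out))
  out
}

#' Full reliability report
#'
#' Computes, for every score item (three traditional scores, three
#' dissection scores, four directed influence scores), the one-way
#' random-effects ICC across runs (scores computed per run, runs as the
#' repeated observations) and the permutation split-half reliability.
#' Deterministic given `seed`.
#'
#' @param trials Window-filtered trial tibble with `block` as the run label.
#' @param n_perm Number of split-half permutations (default 1000).
#' @param seed Integer seed for the permutations.
#' @param normalization Passed to the scorers; default `"raw"`.
#' @return An object of class `reliability_report`: list with elements
#'   `icc` (tibble: item, icc, ms_between, ms_within, k) and `split_half`
#'   (tibble: item, mean_r, sd_r), plus `n_runs`, `n_perm`, `seed`.
#'   `tidy()` merges the two tables.
#' @export
reliability_report <- function(trials, n_perm = 1000, seed = NULL,
                               normalization = "raw") {
  runs <- sort(unique(trials$block))
  icc_tbl <- NULL
  if (length(runs) < 2) {
    warn("Fewer than 2 runs: ICC skipped")
  } else {
    per_run <- scores_by_run(trials, normalization = normalization)
    items <- setdiff(names(per_run), c("run", "subject"))
    icc_tbl <- purrr::map_dfr(items, function(item) {
      fit <- icc_oneway(per_run, subject = "subject", run = "run", value = item)
      tibble::tibble(item = item, icc = fit$icc, ms_between = fit$ms_between,
                     ms_within = fit$ms_within, k = fit$k)
    })
  }
  sh <- split_half(trials, normalization = normalization,
                   n_perm = n_perm, seed = seed)
  structure(
    list(icc = icc_tbl,
         split_half = tibble::as_tibble(sh)[, c("item", "mean_r", "sd_r")],
         n_runs = length(runs), n_perm = n_perm, seed = seed,
         normalization = normalization),
    class = "reliability_report"
  )
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("Reliability report (%d runs, %d split-half permutations)\n",
              x$n_runs, x$n_perm))
  print(tidy(x), ...)
  invisible(x)
}
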