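# ANT scores (condition-dissection and traditional contrasts) and directed
# inter-network influence scores, on per-condition median reaction times.

# --- matrix backends -------------------------------------------------------
# All scoring runs on an n_subjects x 6 matrix of condition medians with
# columns ordered ncc, nci, ccc, cci, scc, sci. The tidy wrappers below
# convert to/from long summary tibbles; reliability code calls the matrix
# functions directly in its permutation loop.

median_matrix <- function(summaries, measure = "median_rt_ms") {
  need <- c("subject", "condition", measure)
  missing_cols <- setdiff(need, names(summaries))
  if (length(missing_cols) > 0) {
    abort(paste0("Summary is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  wide <- summaries |>
    dplyr::select("subject", "condition", dplyr::all_of(measure)) |>
    tidyr::pivot_wider(names_from = "condition", values_from = dplyr::all_of(measure)) |>
    dplyr::arrange(.data$subject)
  missing_cond <- setdiff(ant_condition_codes, names(wide))
  if (length(missing_cond) > 0) {
    abort(paste0("Missing condition(s): ", paste(missing_cond, collapse = ", ")))
  }
  m <- as.matrix(wide[, ant_condition_codes])
  rownames(m) <- wide$subject
  if (anyNA(m)) {
    bad <- rownames(m)[apply(is.na(m), 1, any)]
    abort(paste0("Missing condition median(s) for subject(s): ",
                 paste(bad, collapse = ", ")))
  }
  if (any(m <= 0)) {
    abort(paste0("Condition ", measure, " values must be strictly positive"))
  }
  m
}

new_scores_mat <- function(m, normalization = "baseline") {
  al <- m[, "ncc"] - m[, "ccc"]
  or <- m[, "ccc"] - m[, "scc"]
  ex <- m[, "nci"] - m[, "ncc"]
  if (normalization == "baseline") {
    al <- al / m[, "ncc"]
    or <- or / m[, "ccc"]
    ex <- ex / m[, "ncc"]
  }
  cbind(alerting = al, orienting = or, executive = ex)
}

old_scores_mat <- function(m, normalization = "baseline") {
  no_cue   <- (m[, "ncc"] + m[, "nci"]) / 2
  center   <- (m[, "ccc"] + m[, "cci"]) / 2
  spatial  <- (m[, "scc"] + m[, "sci"]) / 2
  congr    <- (m[, "ncc"] + m[, "ccc"] + m[, "scc"]) / 3
  incongr  <- (m[, "nci"] + m[, "cci"] + m[, "sci"]) / 3
  al <- no_cue - center
  or <- center - spatial
  ex <- incongr - congr
  if (normalization == "baseline") {
    al <- al / no_cue
    or <- or / center
    ex <- ex / incongr
  }
  cbind(alerting = al, orienting = or, executive = ex)
}

relation_scores_mat <- function(m, normalization = "score") {
  al_ex <- (m[, "cci"] - m[, "ccc"]) - (m[, "nci"] - m[, "ncc"])
  or_ex <- (m[, "sci"] - m[, "scc"]) - (m[, "cci"] - m[, "ccc"])
  ex_al <- (m[, "nci"] - m[, "cci"]) - (m[, "ncc"] - m[, "ccc"])
  ex_or <- (m[, "cci"] - m[, "sci"]) - (m[, "ccc"] - m[, "scc"])
  if (normalization == "score") {
    d_al_ex <- m[, "nci"] - m[, "ncc"]   # pure executive score
    d_or_ex <- m[, "cci"] - m[, "ccc"]
    d_ex_al <- m[, "ncc"] - m[, "ccc"]   # pure alerting score
    d_ex_or <- m[, "ccc"] - m[, "scc"]   # pure orienting score
    safe_div <- function(num, den) ifelse(den == 0, NA_real_, num / den)
    al_ex <- safe_div(al_ex, d_al_ex)
    or_ex <- safe_div(or_ex, d_or_ex)
    ex_al <- safe_div(ex_al, d_ex_al)
    ex_or <- safe_div(ex_or, d_ex_or)
  }
  cbind(al_to_ex = al_ex, or_to_ex = or_ex, ex_to_al = ex_al, ex_to_or = ex_or)
}

scores_to_tibble <- function(mat, subjects, prefix = NULL) {
  out <- tibble::as_tibble(as.data.frame(mat))
  if (!is.null(prefix)) names(out) <- paste0(prefix, "_", names(out))
  dplyr::bind_cols(tibble::tibble(subject = subjects), out)
}

# --- tidy interface --------------------------------------------------------

#' Condition-dissection ANT scores
#'
#' Computes per-subject alerting, orienting and executive-control scores from
#' condition medians by dissecting the six cells into additive components,
#' so each score is a difference between two cells that isolates exactly one
#' network:
#' \deqn{alerting = ncc - ccc,\quad orienting = ccc - scc,\quad
#'       executive = nci - ncc}
#' Positive alerting and orienting are reaction-time benefits of the cue;
#' positive executive control is the reaction-time cost of incongruent
#' flankers. With `normalization = "baseline"` (the default) each raw score
#' is divided by the median of its relevant baseline condition (`ncc` for
#' alerting and executive, `ccc` for orienting), giving a dimensionless
#' fraction that controls for baseline speed differences between subjects.
#'
#' @param summaries A condition-summary tibble (see [summarize_conditions()]).
#' @param normalization `"baseline"` (default) or `"raw"` (milliseconds).
#' @return A tibble with one row per subject: `subject`, `method`,
#'   `normalization`, `alerting`, `orienting`, `executive`, ordered by
#'   subject id.
#' @seealso [old_scores()], [relation_scores()], [score_cohort()]
#' @export
new_scores <- function(summaries, normalization = c("baseline", "raw")) {
  normalization <- match.arg(normalization)
  m <- median_matrix(summaries)
  scores_to_tibble(new_scores_mat(m, normalization), rownames(m)) |>
    dplyr::mutate(method = "new", normalization = normalization,
                  .after = "subject")
}

#' Traditional ANT scores
#'
#' The original cell-mean contrasts: alerting is the mean of the no-cue cells
#' minus the mean of the center-cue cells; orienting the mean of the
#' center-cue cells minus the mean of the spatial-cue cells; executive
#' control the mean of the three incongruent cells minus the mean of the
#' three congruent cells. Because each contrast averages over congruent and
#' incongruent (or over cue) cells, these scores absorb any inter-network
#' interaction present in the data. With `normalization = "baseline"` each
#' raw score is divided by its minuend mean (the relevant baseline).
#'
#' @inheritParams new_scores
#' @return A tibble like [new_scores()], with `method = "old"`.
#' @export
old_scores <- function(summaries, normalization = c("baseline", "raw")) {
  normalization <- match.arg(normalization)
  m <- median_matrix(summaries)
  scores_to_tibble(old_scores_mat(m, normalization), rownames(m)) |>
    dplyr::mutate(method = "old", normalization = normalization,
                  .after = "subject")
}

#' Directed inter-network influence scores
#'
#' Interaction contrasts quantifying how engaging one attention network
#' changes the effect of another:
#' \deqn{AL \to EX = (cci - ccc) - (nci - ncc)}
#' \deqn{OR \to EX = (sci - scc) - (cci - ccc)}
#' \deqn{EX \to AL = (nci - cci) - (ncc - ccc)}
#' \deqn{EX \to OR = (cci - sci) - (ccc - scc)}
#' In raw (millisecond) mode the pairs are exact algebraic mirrors:
#' `ex_to_al = -al_to_ex` and `ex_to_or = -or_to_ex`. With
#' `normalization = "score"` (the default) each contrast is divided by the
#' pure dissection score of the target network (`al_to_ex` by the executive
#' score `nci - ncc`, `ex_to_al` by the alerting score `ncc - ccc`, and so
#' on), which breaks the mirror symmetry and expresses the influence as a
#' fraction of the affected effect. A zero denominator makes the normalised
#' score undefined for that subject; such values are returned as `NA` with a
#' warning, since a network relationship cannot be measured against a zero
#' score.
#'
#' @inheritParams new_scores
#' @param normalization `"score"` (default) or `"raw"`.
#' @return A tibble with one row per subject: `subject`, `normalization`,
#'   `al_to_ex`, `or_to_ex`, `ex_to_al`, `ex_to_or`.
#' @export
relation_scores <- function(summaries, normalization = c("score", "raw")) {
  normalization <- match.arg(normalization)
  m <- median_matrix(summaries)
  mat <- relation_scores_mat(m, normalization)
  rownames(mat) <- rownames(m)
  if (anyNA(mat)) {
    bad <- rownames(mat)[apply(is.na(mat), 1, any)]
    warn(paste0("Zero pure-score denominator; undefined normalised relation ",
                "score(s) set to NA for subject(s): ",
                paste(bad, collapse = ", ")))
  }
  scores_to_tibble(mat, rownames(m)) |>
    dplyr::mutate(normalization = normalization, .after = "subject")
}

#' Score a whole cohort
#'
#' Computes any combination of traditional scores, dissection scores and
#' influence scores for every subject in a condition summary, returned as a
#' single wide tibble (one row per subject, deterministic subject order).
#'
#' @inheritParams new_scores
#' @param method Which ANT score families to include: `"both"` (default),
#'   `"new"`, or `"old"`.
#' @param normalization `"normalized"` (default: baseline-normalised ANT
#'   scores, score-normalised relations) or `"raw"` (all in milliseconds).
#' @param relations Include the four influence scores? Default `TRUE`.
#' @param measure Column of the summary to score. The default scores median
#'   reaction times; `"accuracy"` applies the same contrasts to condition
#'   accuracies (an explicit opt-in: between-condition accuracy differences
#'   are often zero, which makes normalised scores undefined, so accuracy
#'   scores are excluded from correlation and reliability analyses unless
#'   requested).
#' @return A tibble of class `ant_scores` with columns `subject`,
#'   `old_alerting` ... `new_executive`, `al_to_ex` ... `ex_to_or`
#'   (as selected).
#' @examples
#' sim_config(n_subjects = 6, seed = 42) |>
#'   simulate_dataset() |>
#'   filter_rt_window() |>
#'   summarize_conditions() |>
#'   score_cohort(normalization = "raw")
#' @export
score_cohort <- function(summaries, method = c("both", "new", "old"),
                         normalization = c("normalized", "raw"),
                         relations = TRUE,
                         measure = c("median_rt_ms", "accuracy")) {
  method <- match.arg(method)
  normalization <- match.arg(normalization)
  measure <- match.arg(measure)
  m <- median_matrix(summaries, measure)
  norm_score <- if (normalization == "raw") "raw" else "baseline"
  norm_rel <- if (normalization == "raw") "raw" else "score"
  out <- tibble::tibble(subject = rownames(m))
  if (method %in% c("both", "old")) {
    out <- dplyr::left_join(out, scores_to_tibble(old_scores_mat(m, norm_score), rownames(m), "old"),
                            by = "subject")
  }
  if (method %in% c("both", "new")) {
    out <- dplyr::left_join(out, scores_to_tibble(new_scores_mat(m, norm_score), rownames(m), "new"),
                            by = "subject")
  }
  if (relations) {
    out <- dplyr::left_join(out, scores_to_tibble(relation_scores_mat(m, norm_rel), rownames(m)),
                            by = "subject")
  }
  out <- dplyr::arrange(out, .data$subject)
  attr(out, "normalization") <- normalization
  attr(out, "measure") <- measure
  class(out) <- c("ant_scores", class(out))
  out
}
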