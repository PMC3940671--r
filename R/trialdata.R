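# Trial-level data model: cue/target enums, condition codes, CSV I/O.

#' Valid cue, target and condition labels
#'
#' The ANT crosses three cue conditions with two flanker target conditions,
#' giving six cells. Each cell has a conventional two- or three-letter code:
#' the first letter(s) name the cue (`n` no cue, `c` center cue, `s` spatial
#' cue) and the last letter the target (`c` congruent, `i` incongruent).
#'
#' @return `ant_conditions()` returns a six-row tibble with columns `cue`,
#'   `target` and `condition`, one row per cell in canonical order
#'   (ncc, nci, ccc, cci, scc, sci).
#' @examples
#' ant_conditions()
#' @export
ant_conditions <- function() {
  tibble::tibble(
    cue       = rep(c("none", "center", "spatial"), each = 2),
    target    = rep(c("congruent", "incongruent"), times = 3),
    condition = c("ncc", "nci", "ccc", "cci", "scc", "sci")
  )
}

ant_cues <- c("none", "center", "spatial")
ant_targets <- c("congruent", "incongruent")
ant_condition_codes <- c("ncc", "nci", "ccc", "cci", "scc", "sci")

#' Map a (cue, target) pair to its condition code
#'
#' Vectorised bijection from the six cue-by-target cells onto the condition
#' codes `ncc, nci, ccc, cci, scc, sci`. For example, a spatial cue with
#' incongruent flankers is `sci`.
#'
#' @param cue Character vector with values in `none`, `center`, `spatial`.
#' @param target Character vector with values in `congruent`, `incongruent`.
#' @return Character vector of condition codes, same length as the inputs.
#' @examples
#' condition_code("none", "congruent")     # "ncc"
#' condition_code("spatial", "incongruent") # "sci"
#' @export
condition_code <- function(cue, target) {
  bad_cue <- setdiff(unique(cue), ant_cues)
  if (length(bad_cue) > 0) {
    abort(paste0("Unknown cue label(s): ", paste(bad_cue, collapse = ", "),
                 ". Expected one of: ", paste(ant_cues, collapse = ", ")))
  }
  bad_tgt <- setdiff(unique(target), ant_targets)
  if (length(bad_tgt) > 0) {
    abort(paste0("Unknown target label(s): ", paste(bad_tgt, collapse = ", "),
                 ". Expected one of: ", paste(ant_targets, collapse = ", ")))
  }
  cue_code <- c(none = "n", center = "c", spatial = "s")[cue]
  tgt_code <- c(congruent = "cc", incongruent = "ci")[target]
  unname(paste0(cue_code, tgt_code))
}

#' Validate a trial table
#'
#' Checks the invariants of trial-level ANT records: known cue/target labels,
#' block index at least 1, cue-target SOA within 200-600 ms, and positive
#' reaction times where a response was made. Non-response trials (misses) are
#' encoded as `NA` reaction time and `NA` correctness. Offending rows are
#' reported by row number together with the offending values.
#'
#' @param trials A data frame with columns `subject`, `block`, `cue`,
#'   `target`, `soa_ms`, `rt_ms`, `correct`.
#' @return The validated trials as a tibble, with a `condition` column added.
#' @export
validate_trials <- function(trials) {
  required <- c("subject", "block", "cue", "target", "soa_ms", "rt_ms", "correct")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required column(s): ", paste(missing_cols, collapse = ", ")))
  }
  trials <- tibble::as_tibble(trials)

  report_rows <- function(bad, what, values) {
    if (any(bad)) {
      rows <- which(bad)
      shown <- head(rows, 5L)
      abort(paste0(
        "Invalid ", what, " in row(s) ", paste(shown, collapse = ", "),
        if (length(rows) > 5L) paste0(" (and ", length(rows) - 5L, " more)") else "",
        ": ", paste(unique(values[shown]), collapse = ", ")
      ))
    }
  }

  report_rows(!trials$cue %in% ant_cues, "cue label", trials$cue)
  report_rows(!trials$target %in% ant_targets, "target label", trials$target)
  report_rows(is.na(trials$block) | trials$block < 1, "block index", trials$block)
  report_rows(!is.na(trials$soa_ms) & (trials$soa_ms < 200 | trials$soa_ms > 600),
              "SOA (must be within 200-600 ms)", trials$soa_ms)
  report_rows(!is.na(trials$rt_ms) & trials$rt_ms <= 0,
              "reaction time (must be > 0 ms)", trials$rt_ms)
  # a recorded response must carry a correctness flag and vice versa
  report_rows(is.na(trials$rt_ms) != is.na(trials$correct),
              "response record (rt_ms and correct must be jointly present or jointly absent)",
              trials$rt_ms)

  trials$subject <- as.character(trials$subject)
  trials$block <- as.integer(trials$block)
  trials$correct <- as.logical(trials$correct)
  trials$condition <- condition_code(trials$cue, trials$target)
  trials
}

#' Read trial-level ANT data from CSV
#'
#' Reads a comma-separated file with one behavioural trial per row and
#' validates it against the trial schema. Column names can be remapped with
#' `col_map` to tolerate exports from stimulus-presentation software whose
#' headers differ from the canonical names.
#'
#' @param path Path to a CSV file with a header row.
#' @param col_map Optional named character vector mapping canonical names to
#'   the file's column names, e.g. `c(subject = "Subject.ID", rt_ms = "RT")`.
#' @return A validated tibble of trials with columns `subject`, `block`,
#'   `cue`, `target`, `condition`, `soa_ms`, `rt_ms`, `correct`, in file
#'   order. Missing reaction times (non-responses) are `NA`.
#' @seealso [write_trials()], [validate_trials()]
#' @export
read_trials <- function(path, col_map = NULL) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(col_map)) {
    missing_src <- setdiff(unname(col_map), names(raw))
    if (length(missing_src) > 0) {
      abort(paste0("Column(s) named in col_map not found in file: ",
                   paste(missing_src, collapse = ", ")))
    }
    for (canonical in names(col_map)) {
      names(raw)[names(raw) == col_map[[canonical]]] <- canonical
    }
  }
  validate_trials(raw)
}

#' Write trial-level ANT data to CSV
#'
#' @param trials A trial tibble (see [validate_trials()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  trials <- validate_trials(trials)
  readr::write_csv(
    dplyr::select(trials, "subject", "block", "cue", "target",
                  "soa_ms", "rt_ms", "correct"),
    path
  )
  invisible(path)
}

#' Write per-subject condition summaries to CSV
#'
#' Serialises a long condition summary (one row per subject by condition; see
#' [summarize_conditions()]) to a wide CSV with one row per subject and, for
#' each of the six condition codes, its median reaction time, accuracy, trial
#' count and correct count. The layout round-trips losslessly through
#' [read_summary()].
#'
#' @param summaries A condition-summary tibble with columns `subject`,
#'   `condition`, `median_rt_ms`, `accuracy`, `n_trials`, `n_correct`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summaries, path) {
  if (nrow(summaries) == 0) abort("Empty summary: nothing to write")
  wide <- summaries |>
    dplyr::select("subject", "condition", "median_rt_ms", "accuracy",
                  "n_trials", "n_correct") |>
    tidyr::pivot_wider(
      names_from = "condition",
      values_from = c("median_rt_ms", "accuracy", "n_trials", "n_correct"),
      names_glue = "{condition}_{.value}"
    ) |>
    dplyr::arrange(.data$subject)
  readr::write_csv(wide, path)
  invisible(path)
}

#' Read per-subject condition summaries from CSV
#'
#' Inverse of [write_summary()].
#'
#' @param path Path to a summary CSV written by [write_summary()].
#' @return A long tibble with columns `subject`, `condition`, `median_rt_ms`,
#'   `accuracy`, `n_trials`, `n_correct`.
#' @export
read_summary <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  wide <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  long <- wide |>
    tidyr::pivot_longer(
      cols = -"subject",
      names_to = c("condition", ".value"),
      names_pattern = "^([a-z]{3})_(.*)$"
    ) |>
    dplyr::mutate(
      subject = as.character(.data$subject),
      n_trials = as.integer(.data$n_trials),
      n_correct = as.integer(.data$n_correct)
    ) |>
    dplyr::arrange(.data$subject,
                   match(.data$condition, ant_condition_codes))
  long
}
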