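# End-to-end pipeline: simulate/read -> preprocess -> score -> analyze ->
# reliability, driven by a YAML config.

pipeline_stages <- c("simulate", "input", "preprocess", "score", "analyze",
                     "reliability")

#' Run the full analysis pipeline
#'
#' Executes the stages named in a YAML (or list) configuration in fixed
#' order: data acquisition (`simulate` a cohort or read an `input` trial
#' CSV), `preprocess` (RT window filter, accuracy screening, condition
#' medians), `score` (both scoring methods plus influence scores),
#' `analyze` (one-sample t-tests per item, score correlations, the
#' cue-by-target ANOVA and the two dissection 2x2 ANOVAs), and
#' `reliability` (ICC across blocks plus permutation split-half). Writes
#' per-stage CSVs and a combined JSON report into `out_dir`, and returns
#' the report invisibly. Identical config and seed give an identical
#' bundle.
#'
#' @param config Path to a YAML file, or an equivalent named list. Allowed
#'   top-level keys: `simulate` (sim_config fields), `input` (trial CSV
#'   path), `preprocess` (`rt_min`, `rt_max`, `accuracy_threshold`),
#'   `score` (`method`, `normalization`), `analyze` (logical), `reliability`
#'   (`n_perm`), `seed`, `out_dir`.
#' @param out_dir Output directory (default from config, else tempdir()).
#' @param seed Overrides the config seed when non-NULL.
#' @return The report, an S3-free nested list, invisibly.
#' @examples
#' cfg <- system.file("extdata", "demo-config.yaml", package = "antscores")
#' report <- run_pipeline(cfg, out_dir = tempfile("ant"))
#' names(report)
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("Config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  unknown <- setdiff(names(config), c(pipeline_stages, "seed", "out_dir"))
  if (length(unknown) > 0) {
    abort(paste0("Unknown stage/key in config: ", paste(unknown, collapse = ", "),
                 ". Allowed: ", paste(c(pipeline_stages, "seed", "out_dir"),
                                      collapse = ", ")))
  }
  if (is.null(seed)) seed <- config$seed
  if (is.null(out_dir)) out_dir <- config$out_dir %||% tempfile("antscores-run")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  report <- list(package_version = as.character(utils::packageVersion("antscores")),
                 seed = seed)

  # --- acquire trials
  if (!is.null(config$input)) {
    trials <- read_trials(config$input)
  } else {
    sim_args <- config$simulate %||% list()
    sim_args$seed <- sim_args$seed %||% seed
    cfg <- do.call(sim_config, sim_args)
    trials <- simulate_dataset(cfg)
    report$simulate <- list(n_subjects = cfg$n_subjects,
                            n_blocks = cfg$n_blocks,
                            n_trials = nrow(trials))
  }
  write_trials(trials, file.path(out_dir, "trials.csv"))

  # --- preprocess
  pp_args <- config$preprocess %||% list()
  pp <- preprocess_trials(
    trials,
    rt_min = pp_args$rt_min %||% 200,
    rt_max = pp_args$rt_max %||% 1200,
    accuracy_threshold = pp_args$accuracy_threshold %||% 0.75
  )
  write_summary(pp$summary, file.path(out_dir, "summary.csv"))
  report$preprocess <- list(
    removed_fraction = pp$removed_fraction,
    n_subjects_in = pp$n_subjects_in,
    n_subjects_retained = pp$n_subjects_retained,
    exclusions = as.data.frame(pp$exclusions)
  )

  # --- score
  sc_args <- config$score %||% list()
  normalization <- sc_args$normalization %||% "normalized"
  scores <- score_cohort(pp$summary,
                         method = sc_args$method %||% "both",
                         normalization = normalization)
  readr::write_csv(scores, file.path(out_dir, "scores.csv"))
  report$score <- list(normalization = normalization,
                       n_subjects = nrow(scores))

  # --- analyze
  if (isTRUE(config$analyze %||% TRUE)) {
    anova_tidy <- function(fit) as.data.frame(tidy(fit))
    report$analyze <- list(
      t_tests = as.data.frame(score_t_tests(scores)),
      correlations = as.data.frame(score_correlations(
        scores, intersect(c("new_alerting", "new_orienting", "new_executive",
                            "old_alerting", "old_orienting", "old_executive"),
                          names(scores)))),
      anova_cue_target = anova_tidy(anova_cue_target(pp$summary)),
      anova_part_I = anova_tidy(anova_dissection(pp$summary, "I")),
      anova_part_II = anova_tidy(anova_dissection(pp$summary, "II"))
    )
  }

  # --- reliability
  rel_args <- config$reliability %||% list()
  if (!isFALSE(config$reliability)) {
    kept_trials <- filter_rt_window(
      trials[trials$subject %in% unique(pp$summary$subject), ],
      pp_args$rt_min %||% 200, pp_args$rt_max %||% 1200)
    rel <- reliability_report(
      kept_trials,
      n_perm = rel_args$n_perm %||% 1000,
      seed = seed,
      normalization = rel_args$normalization %||% "raw"
    )
    report$reliability <- list(
      icc = as.data.frame(rel$icc),
      split_half = as.data.frame(rel$split_half),
      n_runs = rel$n_runs, n_perm = rel$n_perm
    )
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
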