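# One-sample / paired t-tests, Pearson correlation, and two-factor
# repeated-measures ANOVA with Greenhouse-Geisser correction.

#' One-sample t-test
#'
#' Thin tidy wrapper around [stats::t.test()] testing whether the mean of
#' `x` differs from `mu0` (two-tailed).
#'
#' @param x Numeric vector, length at least 2, non-constant.
#' @param mu0 Null-hypothesis mean (default 0).
#' @return One-row tibble: `estimate` (sample mean), `statistic` (t), `df`,
#'   `p_value`, `conf_low`, `conf_high`.
#' @export
one_sample_t <- function(x, mu0 = 0) {
  x <- x[!is.na(x)]
  if (length(x) < 2) abort("Need at least 2 non-missing values")
  if (sd(x) == 0) {
    # constant at mu0 is the well-defined limit t = 0 (e.g. identical paired
    # samples); constant elsewhere has no finite t
    if (x[1] == mu0) {
      return(tibble::tibble(estimate = mu0, statistic = 0,
                            df = length(x) - 1, p_value = 1,
                            conf_low = mu0, conf_high = mu0))
    }
    abort("Degenerate sample: zero variance")
  }
  fit <- t.test(x, mu = mu0)
  tibble::tibble(
    estimate = unname(fit$estimate),
    statistic = unname(fit$statistic),
    df = unname(fit$parameter),
    p_value = fit$p.value,
    conf_low = fit$conf.int[1],
    conf_high = fit$conf.int[2]
  )
}

#' Paired-samples t-test
#'
#' Equivalent to a one-sample t-test on the paired differences `a - b`.
#'
#' @param a,b Numeric vectors of equal length.
#' @return One-row tibble as in [one_sample_t()]; `estimate` is the mean
#'   difference.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) abort("Paired samples must have equal length")
  keep <- !is.na(a) & !is.na(b)
  one_sample_t(a[keep] - b[keep], mu0 = 0)
}

#' Pearson correlation test
#'
#' @param a,b Numeric vectors of equal length, n >= 3, non-constant.
#' @return One-row tibble: `r`, `statistic` (t), `df`, `p_value`.
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) abort("Samples must have equal length")
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 3) abort("Need at least 3 complete pairs")
  if (sd(a) == 0 || sd(b) == 0) abort("Undefined correlation: constant input")
  fit <- cor.test(a, b, method = "pearson")
  tibble::tibble(
    r = unname(fit$estimate),
    statistic = unname(fit$statistic),
    df = unname(fit$parameter),
    p_value = fit$p.value
  )
}

# orthonormal (polynomial-free) contrast matrix: (k-1) x k rows orthonormal,
# each orthogonal to the unit vector
orthonormal_contrasts <- function(k) {
  c_helmert <- stats::contr.helmert(k)          # k x (k-1)
  q <- qr.Q(qr(cbind(1, c_helmert)))[, -1, drop = FALSE]
  t(q)                                          # (k-1) x k
}

gg_epsilon <- function(z) {
  # z: n x d matrix of within-subject contrast scores for one effect
  d <- ncol(z)
  if (d == 1) return(1)
  s <- stats::cov(z)
  tr <- sum(diag(s))
  tr^2 / (d * sum(s * s))
}

#' Two-factor repeated-measures ANOVA
#'
#' Fits the fully within-subject two-way ANOVA for a complete balanced
#' design with one observation per subject and cell (for example, condition
#' median reaction times). Each effect (both main effects and the
#' interaction) is tested against its own subject-by-effect error term. For
#' every effect the table reports the uncorrected F-test, partial
#' eta-squared (SS_effect / (SS_effect + SS_error)), the Greenhouse-Geisser
#' epsilon estimated from the covariance of the orthonormalised
#' within-subject contrasts, and the epsilon-corrected degrees of freedom
#' and p-value. Sphericity cannot be violated for a 2-level factor, so its
#' epsilon is exactly 1 and the corrected test equals the uncorrected one;
#' both are always reported rather than gated on a sphericity test.
#'
#' @param data A data frame in long format.
#' @param subject,factor_a,factor_b,value Column names (tidy-eval) giving
#'   the subject identifier, the two within-subject factors, and the
#'   response.
#' @return An object of class `rm_anova` with a `tidy()` method; printing
#'   shows the effect table (effect, df, df_error, statistic, p_value,
#'   partial_eta_sq, epsilon, p_value_gg).
#' @examples
#' summary <- sim_config(n_subjects = 8, seed = 5) |>
#'   simulate_dataset() |>
#'   filter_rt_window() |>
#'   summarize_conditions()
#' anova_cue_target(summary)
#' @export
rm_anova <- function(data, subject, factor_a, factor_b, value) {
  subject <- rlang::as_name(rlang::enquo(subject))
  factor_a <- rlang::as_name(rlang::enquo(factor_a))
  factor_b <- rlang::as_name(rlang::enquo(factor_b))
  value <- rlang::as_name(rlang::enquo(value))

  df <- tibble::tibble(
    subject = as.character(data[[subject]]),
    a = as.character(data[[factor_a]]),
    b = as.character(data[[factor_b]]),
    y = as.numeric(data[[value]])
  )
  a_lev <- sort(unique(df$a)); b_lev <- sort(unique(df$b))
  na <- length(a_lev); nb <- length(b_lev)
  wide <- df |>
    dplyr::mutate(cell = paste(.data$a, .data$b, sep = ".")) |>
    dplyr::select("subject", "cell", "y") |>
    tidyr::pivot_wider(names_from = "cell", values_from = "y")
  cells <- as.vector(t(outer(a_lev, b_lev, paste, sep = ".")))  # a-major order
  if (!all(cells %in% names(wide)) || anyNA(wide[, cells]) ||
      nrow(df) != nrow(wide) * na * nb) {
    abort("Unbalanced design: every subject must have exactly one value per cell")
  }
  y <- as.matrix(wide[, cells])
  n <- nrow(y)
  if (n < 2) abort("Need at least 2 subjects")

  ca <- orthonormal_contrasts(na)
  cb <- orthonormal_contrasts(nb)
  ja <- matrix(1 / sqrt(na), 1, na)
  jb <- matrix(1 / sqrt(nb), 1, nb)

  effects <- list(
    list(name = factor_a, c = kronecker(ca, jb)),
    list(name = factor_b, c = kronecker(ja, cb)),
    list(name = paste0(factor_a, ":", factor_b), c = kronecker(ca, cb))
  )

  rows <- purrr::map(effects, function(ef) {
    z <- y %*% t(ef$c)                 # n x d contrast scores
    d <- ncol(z)
    m <- colMeans(z)
    ss_effect <- n * sum(m^2)
    ss_error <- sum(sweep(z, 2, m)^2)
    df1 <- d
    df2 <- d * (n - 1)
    ms_effect <- ss_effect / df1
    ms_error <- ss_error / df2
    # an effect with no variance at all (identical cells) has F = 0 by
    # convention rather than a 0/0 ratio of rounding noise
    tot <- sum((y - mean(y))^2)
    degenerate <- (ss_effect + ss_error) <= 1e-12 * max(tot, .Machine$double.xmin)
    f <- if (degenerate) 0 else ms_effect / ms_error
    eps <- if (degenerate) 1 else gg_epsilon(z)
    if (!is.finite(eps)) eps <- 1
    tibble::tibble(
      effect = ef$name,
      df = df1, df_error = df2,
      ss = ss_effect, ss_error = ss_error,
      statistic = f,
      p_value = pf(f, df1, df2, lower.tail = FALSE),
      partial_eta_sq = if (degenerate) 0 else ss_effect / (ss_effect + ss_error),
      epsilon = eps,
      df_gg = df1 * eps, df_error_gg = df2 * eps,
      p_value_gg = pf(f, df1 * eps, df2 * eps, lower.tail = FALSE)
    )
  })

  structure(
    list(table = dplyr::bind_rows(rows), n = n,
         factors = stats::setNames(c(na, nb), c(factor_a, factor_b))),
    class = "rm_anova"
  )
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA: %s (%d) x %s (%d), n = %d subjects\n",
              names(x$factors)[1], x$factors[1],
              names(x$factors)[2], x$factors[2], x$n))
  print(dplyr::select(x$table, -"ss", -"ss_error"), ...)
  invisible(x)
}

#' Cue-by-target ANOVA on condition summaries
#'
#' Runs the 3 (cue: none, center, spatial) by 2 (target: congruent,
#' incongruent) repeated-measures ANOVA on a per-condition measure, the
#' omnibus analysis appropriate for the traditional scoring method.
#'
#' @param summaries A condition-summary tibble.
#' @param measure Column to analyse: `"median_rt_ms"` (default) or
#'   `"accuracy"`.
#' @return An `rm_anova` object.
#' @export
anova_cue_target <- function(summaries, measure = c("median_rt_ms", "accuracy")) {
  measure <- match.arg(measure)
  data <- summaries |>
    dplyr::inner_join(ant_conditions(), by = "condition")
  rm_anova(data, subject, cue, target, !!rlang::sym(measure))
}

#' Dissection-based 2x2 ANOVAs
#'
#' Splits the six conditions into the two 2x2 sub-designs that isolate pairs
#' of networks: part `"I"` (alerting by executive control; cells ncc, nci,
#' ccc, cci) and part `"II"` (orienting by executive control; cells ccc,
#' cci, scc, sci). The interaction term in each part is the omnibus test of
#' the corresponding directed influences.
#'
#' @param summaries A condition-summary tibble.
#' @param part `"I"` or `"II"`.
#' @inheritParams anova_cue_target
#' @return An `rm_anova` object; the first factor is named `alerting`
#'   (part I) or `orienting` (part II), the second `executive`.
#' @export
anova_dissection <- function(summaries, part = c("I", "II"),
                             measure = c("median_rt_ms", "accuracy")) {
  part <- match.arg(part)
  measure <- match.arg(measure)
  if (part == "I") {
    keep <- c("ncc", "nci", "ccc", "cci")
    fac_name <- "alerting"
    fac_level <- c(ncc = "absent", nci = "absent", ccc = "present", cci = "present")
  } else {
    keep <- c("ccc", "cci", "scc", "sci")
    fac_name <- "orienting"
    fac_level <- c(ccc = "absent", cci = "absent", scc = "present", sci = "present")
  }
  data <- summaries |>
    dplyr::filter(.data$condition %in% keep) |>
    dplyr::mutate(
      !!fac_name := fac_level[.data$condition],
      executive = ifelse(substr(.data$condition, 3, 3) == "i",
                         "engaged", "idle")
    )
  rm_anova(data, subject, !!rlang::sym(fac_name), executive,
           !!rlang::sym(measure))
}

#' One-sample t-tests for every score column
#'
#' Tests each score item in a cohort score table against zero, the standard
#' first-pass analysis asking whether each network effect and each directed
#' influence is reliably non-zero across subjects.
#'
#' @param scores A cohort score tibble (see [score_cohort()]).
#' @param mu0 Null mean (default 0).
#' @return A tibble with one row per score item: `item`, `estimate`,
#'   `statistic`, `df`, `p_value`, `conf_low`, `conf_high`.
#' @export
score_t_tests <- function(scores, mu0 = 0) {
  items <- setdiff(names(scores), "subject")
  purrr::map_dfr(items, function(item) {
    dplyr::bind_cols(tibble::tibble(item = item),
                     one_sample_t(scores[[item]], mu0 = mu0))
  })
}

#' Pairwise Pearson correlations between score items
#'
#' @param scores A cohort score tibble.
#' @param items Character vector of column names to correlate; defaults to
#'   all score columns.
#' @return A tibble with one row per unordered pair: `item_a`, `item_b`,
#'   `r`, `statistic`, `df`, `p_value`.
#' @export
score_correlations <- function(scores, items = NULL) {
  if (is.null(items)) items <- setdiff(names(scores), "subject")
  pairs <- utils::combn(items, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(p) {
    dplyr::bind_cols(tibble::tibble(item_a = p[1], item_b = p[2]),
                     pearson_r(scores[[p[1]]], scores[[p[2]]]))
  })
}
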