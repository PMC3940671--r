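test_that("dissection scores match the defining contrasts on toy medians", {
  s <- toy_summary()  # ncc 600, nci 700, ccc 560, cci 680, scc 520, sci 630
  raw <- new_scores(s, "raw")
  expect_equal(raw$alerting, 40)
  expect_equal(raw$orienting, 40)
  expect_equal(raw$executive, 100)

  norm <- new_scores(s, "baseline")
  expect_equal(norm$alerting, 40 / 600)
  expect_equal(norm$orienting, 40 / 560)
  expect_equal(norm$executive, 100 / 600)
})

test_that("traditional scores match the cell-mean contrasts on toy medians", {
  s <- toy_summary()
  raw <- old_scores(s, "raw")
  expect_equal(raw$alerting, 650 - 620)
  expect_equal(raw$orienting, 620 - 575)
  expect_equal(raw$executive, (700 + 680 + 630) / 3 - (600 + 560 + 520) / 3)

  norm <- old_scores(s, "baseline")
  expect_equal(norm$alerting, 30 / 650)
  expect_equal(norm$orienting, 45 / 620)
  expect_equal(norm$executive, 110 / ((700 + 680 + 630) / 3))

  flat <- toy_summary(stats::setNames(rep(600, 6), names(toy_medians)))
  for (mode in c("raw", "baseline")) {
    sc <- old_scores(flat, mode)
    expect_equal(unlist(sc[, c("alerting", "orienting", "executive")]),
                 c(alerting = 0, orienting = 0, executive = 0))
  }
})

test_that("influence scores match the interaction contrasts on toy medians", {
  s <- toy_summary()
  raw <- relation_scores(s, "raw")
  expect_equal(raw$al_to_ex, 20)
  expect_equal(raw$or_to_ex, -10)
  expect_equal(raw$ex_to_al, -20)
  expect_equal(raw$ex_to_or, 10)

  norm <- relation_scores(s, "score")
  expect_equal(norm$al_to_ex, 20 / 100)   # over pure executive nci - ncc
  expect_equal(norm$or_to_ex, -10 / 120)  # over cci - ccc
  expect_equal(norm$ex_to_al, -20 / 40)   # over pure alerting ncc - ccc
  expect_equal(norm$ex_to_or, 10 / 40)    # over pure orienting ccc - scc

  # additive subject: all interaction contrasts vanish
  additive <- toy_summary(c(ncc = 600, nci = 700, ccc = 560, cci = 660,
                            scc = 520, sci = 620))
  r0 <- relation_scores(additive, "raw")
  expect_equal(unlist(r0[, c("al_to_ex", "or_to_ex", "ex_to_al", "ex_to_or")]),
               c(al_to_ex = 0, or_to_ex = 0, ex_to_al = 0, ex_to_or = 0))
})

test_that("zero pure-score denominators yield NA with a warning in score mode", {
  s <- toy_summary(c(ncc = 600, nci = 600, ccc = 560, cci = 680,
                     scc = 520, sci = 630))  # executive score = 0
  expect_warning(r <- relation_scores(s, "score"), "S001")
  expect_true(is.na(r$al_to_ex))
  expect_false(is.na(r$ex_to_al))
})

test_that("raw-mode algebraic identities hold exactly over random sextets", {
  summaries <- random_summaries(1000, seed = 7)
  sc <- score_cohort(summaries, normalization = "raw")
  expect_equal(sc$ex_to_al, -sc$al_to_ex)
  expect_equal(sc$ex_to_or, -sc$or_to_ex)
  # decomposition: old executive - new executive = (2 AL->EX + OR->EX) / 3
  expect_equal(sc$old_executive - sc$new_executive,
               (2 * sc$al_to_ex + sc$or_to_ex) / 3, tolerance = 1e-12)
  # score-normalised mode breaks the mirror symmetry
  scn <- score_cohort(summaries, normalization = "normalized")
  expect_false(isTRUE(all.equal(scn$ex_to_al, -scn$al_to_ex)))
})

test_that("raw scores are translation invariant and scale equivariant", {
  summaries <- random_summaries(50, seed = 8)
  base <- score_cohort(summaries, normalization = "raw")
  shifted <- dplyr::mutate(summaries, median_rt_ms = median_rt_ms + 123.4)
  expect_equal(as.data.frame(score_cohort(shifted, normalization = "raw")),
               as.data.frame(base), tolerance = 1e-10)

  scaled <- dplyr::mutate(summaries, median_rt_ms = median_rt_ms * 1.7)
  sc_scaled <- score_cohort(scaled, normalization = "raw")
  for (col in setdiff(names(base), "subject")) {
    expect_equal(sc_scaled[[col]], 1.7 * base[[col]], tolerance = 1e-10)
  }
  # baseline/score-normalised values are scale invariant
  expect_equal(as.data.frame(score_cohort(scaled, normalization = "normalized")),
               as.data.frame(score_cohort(summaries, normalization = "normalized")),
               tolerance = 1e-10)
})

test_that("score_cohort is deterministic, subject-ordered and complete", {
  summaries <- random_summaries(36, seed = 9)
  sc <- score_cohort(summaries)
  expect_equal(nrow(sc), 36L)
  expect_equal(sc$subject, sort(unique(summaries$subject)))
  expect_false(anyNA(sc))
  expect_identical(as.data.frame(sc), as.data.frame(score_cohort(summaries)))

  one <- score_cohort(toy_summary())
  expect_equal(nrow(one), 1L)
  only_new <- score_cohort(summaries, method = "new", relations = FALSE)
  expect_named(only_new, c("subject", "new_alerting", "new_orienting",
                           "new_executive"))
})

test_that("scoring validates its input summaries", {
  expect_error(new_scores(toy_summary()[-1, ]), "ncc")
  bad <- dplyr::mutate(toy_summary(),
                       median_rt_ms = replace(median_rt_ms, 2, -5))
  expect_error(new_scores(bad), "positive")
})

test_that("cohort means recover generative effects for the new method and show
           the closed-form contamination for the old method", {
  cfg <- sim_config(n_subjects = 150, seed = 71)
  sc <- simulate_dataset(cfg) |>
    filter_rt_window() |>
    summarize_conditions() |>
    score_cohort(normalization = "raw")
  n <- nrow(sc)
  check3 <- function(x, target) {
    expect_lt(abs(mean(x) - target), 3 * sd(x) / sqrt(n))
  }
  check3(sc$new_alerting, cfg$alerting_ms)
  check3(sc$new_orienting, cfg$orienting_ms)
  check3(sc$new_executive, cfg$conflict_ms)
  # old method absorbs the interactions
  check3(sc$old_alerting, cfg$alerting_ms - cfg$gamma_ae_ms / 2)
  check3(sc$old_orienting, cfg$orienting_ms - cfg$gamma_oe_ms / 2)
  check3(sc$old_executive,
         cfg$conflict_ms + (2 * cfg$gamma_ae_ms + cfg$gamma_oe_ms) / 3)
  # mean influence scores track the generative interactions
  check3(sc$al_to_ex, cfg$gamma_ae_ms)
  check3(sc$or_to_ex, cfg$gamma_oe_ms)
})

test_that("accuracy-based scores apply the same contrasts on explicit opt-in", {
  s <- dplyr::mutate(toy_summary(),
                     accuracy = c(0.95, 0.85, 0.96, 0.88, 0.97, 0.90))
  sc <- score_cohort(s, normalization = "raw", measure = "accuracy")
  expect_equal(sc$new_alerting, 0.95 - 0.96)
  expect_equal(sc$new_executive, 0.85 - 0.95)
  expect_equal(sc$al_to_ex, (0.88 - 0.96) - (0.85 - 0.95))
  # rt scoring is unaffected by the accuracy column
  expect_equal(score_cohort(s, normalization = "raw")$new_alerting, 40)
})
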