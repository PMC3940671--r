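test_that("one-sample t matches the closed form and handles edge cases", {
  r <- one_sample_t(c(1, 2, 3, 4, 5))
  # mean 3, sd sqrt(2.5): t = 3 / (sqrt(2.5) / sqrt(5)) = sqrt(18)
  expect_equal(r$statistic, 3 / (sqrt(2.5) / sqrt(5)), tolerance = 1e-12)
  expect_equal(r$df, 4)
  expect_equal(r$p_value, 2 * pt(-r$statistic, 4), tolerance = 1e-12)

  sym <- one_sample_t(c(-2, -1, 1, 2), mu0 = 0)
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p_value, 1)

  expect_equal(one_sample_t(rnorm(36))$df, 35)
  expect_error(one_sample_t(rep(3, 10)), "variance")
  expect_error(one_sample_t(1), "at least 2")
})

test_that("paired t equals one-sample t on the differences", {
  withr::with_seed(13, {
    a <- rnorm(20, 500, 40)
    b <- rnorm(20, 480, 40)
  })
  expect_equal(as.data.frame(paired_t(a, b)),
               as.data.frame(one_sample_t(a - b)), tolerance = 1e-12)
  expect_equal(paired_t(a, a)$statistic, 0)
  expect_error(paired_t(a, b[-1]), "equal length")
})

test_that("pearson_r matches cor.test and hits the degenerate bounds", {
  x <- c(1, 3, 2, 5, 4, 6)
  expect_equal(pearson_r(x, x)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  withr::with_seed(14, y <- x + rnorm(6))
  r <- pearson_r(x, y)
  expect_equal(r$r, unname(cor(x, y)), tolerance = 1e-12)
  expect_equal(r$statistic, r$r * sqrt((6 - 2) / (1 - r$r^2)), tolerance = 1e-10)
  expect_error(pearson_r(x, rep(1, 6)), "constant")
})

test_that("a bivariate-normal correlation is recovered at large n", {
  withr::with_seed(15, {
    n <- 4000; rho <- 0.44
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  })
  r <- pearson_r(x, y)$r
  expect_lt(abs(r - 0.44), 3 * (1 - 0.44^2) / sqrt(4000))
})

test_that("rm-ANOVA degrees of freedom follow the design", {
  withr::with_seed(16, {
    df <- tidyr::expand_grid(subject = sprintf("P%02d", 1:36),
                             cue = c("none", "center", "spatial"),
                             target = c("congruent", "incongruent"))
    df$y <- rnorm(nrow(df), 500, 50)
  })
  out <- tidy(rm_anova(df, subject, cue, target, y))
  expect_equal(out$df_error[out$effect == "cue"], 70)       # (3-1)(36-1)
  expect_equal(out$df[out$effect == "target"], 1)
  expect_equal(out$df_error[out$effect == "target"], 35)
  expect_equal(out$df[out$effect == "cue:target"], 2)
  g <- glance(rm_anova(df, subject, cue, target, y))
  expect_equal(g$n_subjects, 36)
})

test_that("identical factor columns give zero F for that factor and the interaction", {
  withr::with_seed(17, {
    base <- tidyr::expand_grid(subject = sprintf("P%02d", 1:10),
                               a = c("a1", "a2"))
    base$v <- rnorm(20)
  })
  df <- dplyr::bind_rows(dplyr::mutate(base, b = "b1"),
                         dplyr::mutate(base, b = "b2"))
  df$y <- df$v
  out <- tidy(rm_anova(df, subject, a, b, y))
  expect_equal(out$statistic[out$effect == "b"], 0)
  expect_equal(out$statistic[out$effect == "a:b"], 0)
  expect_equal(out$p_value[out$effect == "b"], 1)
})

test_that("2x2 interaction F equals the squared paired t on the double difference", {
  for (seed in c(18, 19, 20)) {
    withr::with_seed(seed, {
      n <- 14
      df <- tidyr::expand_grid(subject = sprintf("P%02d", 1:n),
                               a = c("a1", "a2"), b = c("b1", "b2"))
      df$y <- rnorm(nrow(df), 500, 60)
    })
    fit <- tidy(rm_anova(df, subject, a, b, y))
    wide <- tidyr::pivot_wider(df, names_from = c("a", "b"), values_from = "y")
    dd <- (wide$a1_b1 - wide$a1_b2) - (wide$a2_b1 - wide$a2_b2)
    t_dd <- one_sample_t(dd)$statistic
    expect_equal(fit$statistic[fit$effect == "a:b"], t_dd^2, tolerance = 1e-8)
    # two-level factors cannot violate sphericity
    expect_equal(fit$epsilon, rep(1, 3))
  }
})

test_that("rm-ANOVA agrees with the multivariate-model oracle, including GG epsilon", {
  withr::with_seed(21, {
    n <- 15
    df <- tidyr::expand_grid(subject = sprintf("P%02d", 1:n),
                             a = c("a1", "a2", "a3"), b = c("b1", "b2"))
    # correlated cells so that epsilon < 1
    df$y <- rnorm(nrow(df), 500, 50) +
      rep(rnorm(n, 0, 30), each = 6) +
      as.numeric(df$a == "a2") * rnorm(nrow(df), 0, 40)
  })
  mine <- tidy(rm_anova(df, subject, a, b, y))

  wide <- tidyr::pivot_wider(
    dplyr::mutate(df, cell = paste(a, b, sep = ".")),
    id_cols = "subject", names_from = "cell", values_from = "y")
  mat <- as.matrix(wide[, -1])
  lev <- do.call(rbind, strsplit(colnames(mat), ".", fixed = TRUE))
  idata <- data.frame(a = factor(lev[, 1]), b = factor(lev[, 2]))
  av <- suppressWarnings(  # car warns when its HF epsilon exceeds 1
    summary(car::Anova(stats::lm(mat ~ 1), idata = idata,
                       idesign = ~ a * b, type = 3),
            multivariate = FALSE))
  ut <- av$univariate.tests
  for (ef in c("a", "b", "a:b")) {
    expect_equal(mine$statistic[mine$effect == ef],
                 unname(ut[ef, "F value"]), tolerance = 1e-8)
    expect_equal(mine$p_value[mine$effect == ef],
                 unname(ut[ef, "Pr(>F)"]), tolerance = 1e-8)
  }
  gg <- av$pval.adjustments
  for (ef in c("a", "a:b")) {
    expect_equal(mine$epsilon[mine$effect == ef],
                 unname(gg[ef, "GG eps"]), tolerance = 1e-8)
    expect_equal(mine$p_value_gg[mine$effect == ef],
                 unname(gg[ef, "Pr(>F[GG])"]), tolerance = 1e-8)
  }
})

test_that("epsilon stays within its theoretical bounds on random grids", {
  for (seed in 22:26) {
    withr::with_seed(seed, {
      n <- 10
      df <- tidyr::expand_grid(subject = sprintf("P%02d", 1:n),
                               a = paste0("a", 1:3), b = paste0("b", 1:2))
      df$y <- rnorm(nrow(df), 0, 1) + rep(rnorm(n), each = 6)
    })
    out <- tidy(rm_anova(df, subject, a, b, y))
    k_a <- 3
    eps_a <- out$epsilon[out$effect == "a"]
    expect_gte(eps_a, 1 / (k_a - 1))
    expect_lte(eps_a, 1 + 1e-12)
  }
})

test_that("rm-ANOVA rejects unbalanced designs", {
  df <- tidyr::expand_grid(subject = c("P1", "P2", "P3"),
                           a = c("a1", "a2"), b = c("b1", "b2"))
  df$y <- rnorm(nrow(df))
  expect_error(rm_anova(df[-1, ], subject, a, b, y), "balanced|Unbalanced")
})

test_that("dissection ANOVA parts isolate the corresponding influence contrast", {
  summaries <- random_summaries(20, seed = 27)
  p1 <- tidy(anova_dissection(summaries, "I"))
  sc <- score_cohort(summaries, normalization = "raw")
  t_al_ex <- one_sample_t(sc$al_to_ex)$statistic
  expect_equal(p1$statistic[p1$effect == "alerting:executive"], t_al_ex^2,
               tolerance = 1e-8)
  p2 <- tidy(anova_dissection(summaries, "II"))
  t_or_ex <- one_sample_t(sc$or_to_ex)$statistic
  expect_equal(p2$statistic[p2$effect == "orienting:executive"], t_or_ex^2,
               tolerance = 1e-8)
})

test_that("score_t_tests and score_correlations cover every item/pair", {
  sc <- score_cohort(random_summaries(15, seed = 28), normalization = "raw")
  tt <- score_t_tests(sc)
  expect_equal(nrow(tt), 10L)
  expect_equal(tt$df, rep(14, 10))
  rr <- score_correlations(sc, c("new_alerting", "new_orienting", "new_executive"))
  expect_equal(nrow(rr), 3L)
  expect_true(all(abs(rr$r) <= 1))
})
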