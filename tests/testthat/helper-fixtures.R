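# Fixtures built in code: toy condition summaries and small trial tables.

toy_medians <- c(ncc = 600, nci = 700, ccc = 560, cci = 680,
                 scc = 520, sci = 630)

# one-subject condition summary from a named median sextet
toy_summary <- function(medians = toy_medians, subject = "S001") {
  tibble::tibble(
    subject = subject,
    condition = names(medians),
    median_rt_ms = unname(medians),
    accuracy = 1,
    n_trials = 27L,
    n_correct = 27L
  )
}

# cohort of random positive median sextets (one row per subject x condition)
random_summaries <- function(n_subjects, seed = 1) {
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_subjects), function(i) {
      toy_summary(
        medians = stats::setNames(runif(6, 300, 900),
                                  c("ncc", "nci", "ccc", "cci", "scc", "sci")),
        subject = sprintf("R%03d", i)
      )
    })
  })
}

# minimal hand-built trial table: one row per supplied rt
make_trials <- function(rt_ms, subject = "S001", block = 1L,
                        cue = "none", target = "congruent",
                        correct = TRUE, soa_ms = 400) {
  n <- length(rt_ms)
  validate_trials(tibble::tibble(
    subject = rep_len(subject, n), block = rep_len(block, n),
    cue = rep_len(cue, n), target = rep_len(target, n),
    soa_ms = rep_len(soa_ms, n), rt_ms = rt_ms,
    correct = ifelse(is.na(rt_ms), NA, rep_len(correct, n))
  ))
}

# replicate a one-condition trial set across all six (cue, target) cells,
# keeping each trial's rt/correct pattern
expand_to_all_conditions <- function(trials) {
  conds <- ant_conditions()
  purrr::map_dfr(seq_len(nrow(conds)), function(i) {
    dplyr::mutate(trials, cue = conds$cue[i], target = conds$target[i],
                  condition = conds$condition[i])
  })
}

# balanced trial set covering all six conditions for one subject
all_condition_trials <- function(rts_per_condition, subject = "S001",
                                 block = 1L, correct = TRUE) {
  conds <- ant_conditions()
  purrr::map_dfr(seq_len(nrow(conds)), function(i) {
    make_trials(rts_per_condition[[conds$condition[i]]], subject = subject,
                block = block, cue = conds$cue[i], target = conds$target[i],
                correct = correct)
  })
}
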