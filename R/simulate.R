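# Counterbalanced ANT schedules and synthetic trial data under an additive
# reaction-time model with explicit inter-network interaction terms.

#' Simulation configuration
#'
#' Builds the parameter set for the ANT simulator. Reaction times follow an
#' additive cell-mean model: cue benefits subtract from the no-cue baseline,
#' flanker conflict adds to it, and two interaction terms let alerting and
#' orienting modulate the size of the conflict effect:
#' \deqn{ncc = B,\; nci = B + E,\; ccc = B - A,\; cci = B - A + E + \gamma_{AE},}
#' \deqn{scc = B - A - O,\; sci = B - A - O + E + \gamma_{AE} + \gamma_{OE}.}
#' Each subject draws a baseline offset (SD `subject_sd_ms`) and its own
#' effect sizes around `alerting_ms`, `orienting_ms` and `conflict_ms` (SDs
#' `alerting_sd_ms`, `orienting_sd_ms`, `conflict_sd_ms`), giving the stable
#' individual differences that reliability analyses measure. Trial residuals
#' are ex-Gaussian (normal SD `sigma_ms` plus exponential mean `tau_ms`),
#' the standard right-skewed reaction-time law and the reason condition
#' summaries use medians. Responses slower than `deadline_ms` are recorded
#' as misses; correctness is Bernoulli with a per-target error rate.
#'
#' @param n_subjects Number of subjects (default 36).
#' @param n_blocks Blocks of 54 counterbalanced trials each (default 3).
#' @param baseline_ms Mean no-cue congruent reaction time B (default 600).
#' @param alerting_ms,orienting_ms,conflict_ms Population effect sizes A, O,
#'   E in ms (defaults 40, 35, 90).
#' @param gamma_ae_ms Alerting-by-conflict interaction: extra conflict cost
#'   when a cue is present (default 20).
#' @param gamma_oe_ms Orienting-by-conflict interaction: extra conflict cost
#'   under a spatial cue (default 10).
#' @param subject_sd_ms Between-subject baseline SD (default 50).
#' @param alerting_sd_ms,orienting_sd_ms,conflict_sd_ms Between-subject SDs
#'   of the three effects (defaults 12, 12, 25).
#' @param sigma_ms,tau_ms Ex-Gaussian residual parameters (defaults 50, 100).
#' @param error_rate_congruent,error_rate_incongruent Error probabilities by
#'   target type (defaults 0.02, 0.08).
#' @param deadline_ms Response deadline (default 1700).
#' @param seed Optional integer seed.
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_subjects = 4, seed = 1)
#' expected_cell_means(cfg)
#' @export
sim_config <- function(n_subjects = 36, n_blocks = 3,
                       baseline_ms = 600, alerting_ms = 40, orienting_ms = 35,
                       conflict_ms = 90, gamma_ae_ms = 20, gamma_oe_ms = 10,
                       subject_sd_ms = 50, alerting_sd_ms = 12,
                       orienting_sd_ms = 12, conflict_sd_ms = 25,
                       sigma_ms = 50, tau_ms = 100,
                       error_rate_congruent = 0.02,
                       error_rate_incongruent = 0.08,
                       deadline_ms = 1700, seed = NULL) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_blocks = as.integer(n_blocks),
    baseline_ms = baseline_ms, alerting_ms = alerting_ms,
    orienting_ms = orienting_ms, conflict_ms = conflict_ms,
    gamma_ae_ms = gamma_ae_ms, gamma_oe_ms = gamma_oe_ms,
    subject_sd_ms = subject_sd_ms, alerting_sd_ms = alerting_sd_ms,
    orienting_sd_ms = orienting_sd_ms, conflict_sd_ms = conflict_sd_ms,
    sigma_ms = sigma_ms, tau_ms = tau_ms,
    error_rate_congruent = error_rate_congruent,
    error_rate_incongruent = error_rate_incongruent,
    deadline_ms = deadline_ms, seed = seed
  )
  if (cfg$n_subjects < 1) abort("n_subjects must be >= 1")
  if (cfg$n_blocks < 1) abort("n_blocks must be >= 1")
  sds <- c("subject_sd_ms", "alerting_sd_ms", "orienting_sd_ms",
           "conflict_sd_ms", "sigma_ms", "tau_ms")
  for (p in sds) if (cfg[[p]] < 0) abort(paste0(p, " must be >= 0"))
  for (p in c("error_rate_congruent", "error_rate_incongruent")) {
    if (cfg[[p]] < 0 || cfg[[p]] >= 1) abort(paste0(p, " must be in [0, 1)"))
  }
  if (cfg$baseline_ms <= 0) abort("baseline_ms must be > 0")
  if (cfg$deadline_ms <= 0) abort("deadline_ms must be > 0")
  class(cfg) <- "sim_config"
  cfg
}

#' Expected condition means under a simulation configuration
#'
#' Closed-form cell means of the additive model (see [sim_config()]),
#' averaged over subjects and residual noise.
#'
#' @param config A `sim_config`.
#' @return A six-row tibble: `condition`, `mean_ms`, in canonical order.
#' @export
expected_cell_means <- function(config) {
  B <- config$baseline_ms; A <- config$alerting_ms; O <- config$orienting_ms
  E <- config$conflict_ms; gae <- config$gamma_ae_ms; goe <- config$gamma_oe_ms
  tibble::tibble(
    condition = ant_condition_codes,
    mean_ms = c(B, B + E, B - A, B - A + E + gae,
                B - A - O, B - A - O + E + gae + goe)
  )
}

soa_grid <- seq(200, 600, by = 50)  # 9 equally spaced cue-target intervals

#' Counterbalanced trial schedule
#'
#' Builds the within-block design: each block contains exactly one trial per
#' (cue, target, SOA) cell — 3 cues x 2 targets x 9 SOAs = 54 trials — with
#' the 9 SOAs equally spaced from 200 to 600 ms and trial order randomised
#' within block.
#'
#' @param n_blocks Number of blocks (default 3).
#' @param seed Optional integer seed for the within-block shuffle.
#' @return A tibble with columns `block`, `trial` (position within block),
#'   `cue`, `target`, `condition`, `soa_ms`.
#' @export
make_schedule <- function(n_blocks = 3, seed = NULL) {
  if (n_blocks < 1) abort("n_blocks must be >= 1")
  cells <- tidyr::expand_grid(ant_conditions(), soa_ms = soa_grid)
  with_seed_opt(seed, {
    purrr::map_dfr(seq_len(n_blocks), function(b) {
      cells[sample.int(nrow(cells)), ] |>
        dplyr::mutate(block = as.integer(b), trial = dplyr::row_number(),
                      .before = 1)
    })
  })
}

#' Simulate an ANT dataset
#'
#' Draws trial-level reaction times and correctness for a cohort under the
#' additive model of [sim_config()]. Every subject gets an independently
#' shuffled counterbalanced schedule. Reaction time = subject's cell mean +
#' ex-Gaussian residual; draws exceeding the deadline are recorded as misses
#' (`NA` reaction time and correctness). Errors still have latencies:
#' correctness is drawn independently of the reaction time.
#'
#' @param config A `sim_config`.
#' @return A validated trial tibble (see [validate_trials()]).
#' @examples
#' trials <- simulate_dataset(sim_config(n_subjects = 2, seed = 11))
#' nrow(trials)  # 2 subjects x 3 blocks x 54 trials = 324
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  with_seed_opt(config$seed, {
    subjects <- sprintf("S%03d", seq_len(config$n_subjects))
    schedule <- purrr::map_dfr(subjects, function(s) {
      dplyr::mutate(make_schedule(config$n_blocks), subject = s, .before = 1)
    })
    n <- nrow(schedule)

    # per-subject stable parameters
    offs <- tibble::tibble(
      subject = subjects,
      b_s = rnorm(config$n_subjects, 0, config$subject_sd_ms),
      a_s = rnorm(config$n_subjects, config$alerting_ms, config$alerting_sd_ms),
      o_s = rnorm(config$n_subjects, config$orienting_ms, config$orienting_sd_ms),
      e_s = rnorm(config$n_subjects, config$conflict_ms, config$conflict_sd_ms)
    )
    df <- dplyr::left_join(schedule, offs, by = "subject")

    cued <- df$cue != "none"
    spatial <- df$cue == "spatial"
    incong <- df$target == "incongruent"
    mu <- config$baseline_ms + df$b_s -
      ifelse(cued, df$a_s, 0) -
      ifelse(spatial, df$o_s, 0) +
      ifelse(incong, df$e_s, 0) +
      ifelse(cued & incong, config$gamma_ae_ms, 0) +
      ifelse(spatial & incong, config$gamma_oe_ms, 0)

    noise <- rnorm(n, 0, config$sigma_ms)
    if (config$tau_ms > 0) noise <- noise + rexp(n, rate = 1 / config$tau_ms)
    rt <- mu + noise
    err_p <- ifelse(incong, config$error_rate_incongruent,
                    config$error_rate_congruent)
    correct <- rbinom(n, 1, 1 - err_p) == 1

    miss <- rt > config$deadline_ms
    rt[miss] <- NA_real_
    correct[miss] <- NA

    validate_trials(tibble::tibble(
      subject = df$subject, block = df$block, cue = df$cue,
      target = df$target, soa_ms = df$soa_ms,
      rt_ms = rt, correct = correct
    ))
  })
}

#' Inject out-of-window artifacts
#'
#' Replaces a random fraction of response reaction times with fast guesses
#' (uniform on 80-199 ms) and attentional lapses (uniform on 1201-1690 ms)
#' so the reaction-time window filter has known ground truth.
#'
#' @param trials A trial tibble.
#' @param fast_guess_rate,lapse_rate Replacement probabilities, each in
#'   \[0, 0.2\].
#' @param seed Optional integer seed.
#' @return The trials with contaminated reaction times.
#' @export
inject_artifacts <- function(trials, fast_guess_rate = 0.01,
                             lapse_rate = 0.005, seed = NULL) {
  for (r in c(fast_guess_rate, lapse_rate)) {
    if (r < 0 || r > 0.2) abort("Artifact rates must be in [0, 0.2]")
  }
  with_seed_opt(seed, {
    has_rt <- !is.na(trials$rt_ms)
    u <- runif(nrow(trials))
    fast <- has_rt & u < fast_guess_rate
    lapse <- has_rt & u >= fast_guess_rate & u < fast_guess_rate + lapse_rate
    trials$rt_ms[fast] <- runif(sum(fast), 80, 199)
    trials$rt_ms[lapse] <- runif(sum(lapse), 1201, 1690)
    trials
  })
}
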