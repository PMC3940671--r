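---
title: "Condition-dissection scoring for the Attention Network Test: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Condition-dissection scoring for the Attention Network Test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antscores)
```

## The measurement model

The ANT yields six cue-by-target cells. The package's central assumption is
an *additive decomposition* of the expected reaction time in each cell into
a baseline plus network effects, with two explicit interaction terms:

| condition | decomposition |
|---|---|
| `ncc` | B |
| `nci` | B + E |
| `ccc` | B − A |
| `cci` | B − A + E + γ~AE~ |
| `scc` | B − A − O |
| `sci` | B − A − O + E + γ~AE~ + γ~OE~ |

Here A (alerting) and O (orienting) are reaction-time *benefits* of the cue
and therefore subtract, E (executive control / flanker conflict) is a *cost*
and adds, γ~AE~ is the extra conflict cost whenever a warning cue has raised
alertness, and γ~OE~ the further change under a spatially informative cue.
All quantities are in milliseconds; per-subject values are always computed
on the *median* reaction time of correct trials in each cell, because
reaction times are right-skewed and the median is the conventional robust
summary.

Under this model the two scoring systems behave differently:

* **Dissection ("new") scores** — `alerting = ncc − ccc`,
  `orienting = ccc − scc`, `executive = nci − ncc` — are each a difference
  of two cells in which only the scored network changes, so their
  expectations are exactly (A, O, E) regardless of the γ terms.
* **Traditional ("old") scores** — cell-mean contrasts over rows/columns —
  absorb the interactions: E[alerting] = A − γ~AE~/2,
  E[orienting] = O − γ~OE~/2, E[executive] = E + (2γ~AE~ + γ~OE~)/3.
  With γ~AE~, γ~OE~ > 0 the traditional method under-states alerting and
  over-states executive control, which is precisely the direction of the
  method difference the dissection approach was designed to expose.
* **Influence scores** are the four directed interaction contrasts
  (AL→EX, OR→EX, EX→AL, EX→OR). In raw milliseconds
  E[AL→EX] = γ~AE~, E[OR→EX] = γ~OE~, and the pairs are exact algebraic
  mirrors (EX→AL ≡ −AL→EX). The package treats this identity as a test
  invariant, and it also implies the exact decomposition
  `old_executive − new_executive = (2·AL→EX + OR→EX)/3` for every subject.

## Normalisation

Baseline speed differs substantially between subjects, so both score
families support a normalised mode, which is the default for the tidy
scoring functions:

* ANT scores: divide each raw score by its *relevant baseline* median —
  `ncc` for alerting and executive, `ccc` for orienting (dissection), and
  the minuend cell mean for the traditional contrasts.
* Influence scores: divide each contrast by the *pure dissection score of
  the target network* (AL→EX by `nci − ncc`, EX→AL by `ncc − ccc`, and so
  on). This choice is forced by two observations: the raw contrasts are
  exact negatives of each other, while empirically reported influence pairs
  are not mirrored, so the two members of a pair must carry different
  denominators; and an influence is most interpretable as a fraction of the
  effect it modifies. A zero denominator makes the normalised value
  undefined — a network relationship cannot be measured against a zero
  score — and the package returns `NA` for that subject with a warning
  rather than imputing.

Because the printed forms of the original equations are not available in
machine-readable form, the exact algebra above is a reconstruction from the
dissection table, the reported effect directions, and the non-mirrored
influence statistics; normalisation is therefore exposed as configuration
(`raw` versus `baseline`/`score`) rather than silently fixed, and every
report records which mode produced it. Reliability analyses default to raw
(millisecond) scores: half-sample medians rest on very few trials, and
score-normalised influence values can explode when a pure-score denominator
from a half-sample is near zero.

## Preprocessing

The pipeline order is fixed: (1) remove responses with reaction time
strictly below 200 ms or strictly above 1200 ms (responses exactly at a
bound are kept — the removal rule is a literal "< 200" / "> 1200");
(2) compute per-condition accuracy on the remaining trials, counting misses
(no response before the 1700 ms deadline) in the denominator; (3) exclude
any subject whose accuracy falls strictly below 0.75 in *any* of the six
conditions (exactly 0.75 is retained); (4) summarise correct trials by the
per-condition median, using the midpoint rule for even counts. Non-response
trials carry no reaction time, pass through the window filter untouched,
and count as errors — a miss is not a correct response. The removed
fraction is reported over responses, not trials, since misses have no
reaction time to filter.

## Inference

`rm_anova()` fits the fully within-subject two-factor ANOVA (one
observation per subject and cell) by projecting each subject's cell vector
onto orthonormal contrast bases — main effects, interaction — and testing
each effect against its own subject-by-effect error term. Greenhouse–
Geisser ε is estimated for every effect from the covariance of the contrast
scores, ε = tr(Σ)²/(d·tr(Σ²)), and both the uncorrected and ε-corrected
tests are always reported; the correction is never gated on a sphericity
test, since the gating criterion used in practice varies between analysts
and a two-level factor has ε = 1 identically. Partial η² is
SS~effect~/(SS~effect~ + SS~error~). For a 2×2 design the interaction F is
algebraically the square of the paired t on the per-subject double
difference, which the test suite checks at machine precision, and the full
table is cross-checked against an independent multivariate-model
implementation. The dissection 2×2 ANOVAs split the six cells into part I
(alerting × executive: `ncc, nci, ccc, cci`) and part II (orienting ×
executive: `ccc, cci, scc, sci`), whose interaction terms are the omnibus
tests of the corresponding influence pairs. All p-values are two-tailed.

A degenerate numerical case is handled explicitly: when an effect's
contrast scores are identically zero (e.g. two factor levels with byte-equal
data), both SS terms are rounding noise and their ratio is meaningless; the
package reports F = 0, p = 1, ε = 1 for such effects.

## Reliability

*Test–retest*: scores are computed separately within each block (run) from
run-level medians — the only granularity at which "one value per item per
run" is defined — and the one-way random-effects ICC,
(MSb − MSw)/(MSb + (k − 1)·MSw) with k runs, is computed per item: three
traditional scores, three dissection scores, four influence scores, ten
items in all. Missing cells are an error; no imputation.

*Split-half*: the only way to split a per-subject *score* is to split its
constituent trials, so within every subject × condition the correct,
window-filtered trials are randomly partitioned into two halves (an odd
trial joins a random half), each half is summarised and scored, the two
half-score vectors are correlated across subjects, and the procedure is
repeated 1000 times (configurable); reliability is the mean of the split
correlations. No Spearman–Brown step-up is applied by default — the mean
split correlation itself is reported — but the correction is available as
an option. A single seed controls all permutations, and identical seeds
give byte-identical reports. Subjects with fewer than two correct trials in
any condition cannot be split and are dropped with a warning.

## The simulator

`simulate_dataset()` exists so that every claim above is testable by
parameter recovery. It reproduces the experimental design — 3 blocks × 54
trials, each block a full counterbalance of 3 cues × 2 targets × 9 SOAs —
and draws reaction times from the additive model plus noise:

* **Schedule.** The 9 cue–target SOAs are equally spaced 200–600 ms (the
  design states the range and the count but not the grid; equal spacing is
  the recorded assumption). SOA has no effect on simulated reaction time,
  matching analyses that collapse over it; trial order is shuffled within
  block.
* **Individual differences.** Each subject draws a baseline offset
  (SD 50 ms) and subject-level effect sizes around A = 40, O = 35,
  E = 90 ms (SDs 12, 12, 25 ms). The effect SDs are not part of the
  six-cell decomposition itself but are required for any reliability
  analysis to have signal to detect; the chosen values give single-session
  reliabilities in the range typically reported for cued flanker tasks.
  The interaction parameters default to γ~AE~ = 20, γ~OE~ = 10 ms and are
  fixed across subjects, so influence scores have near-zero between-subject
  variance — which is why their reliability is expected, and observed, to
  be lowest.
* **Noise.** Residuals are ex-Gaussian (normal SD 50 ms + exponential mean
  100 ms), the standard right-skewed reaction-time law and the reason the
  summaries use medians. Draws beyond the 1700 ms deadline become misses.
  Correctness is Bernoulli per target type (error rates 0.02 congruent,
  0.08 incongruent — typical for healthy adults and consistent with an
  exclusion rate of a few subjects per forty at the 75% rule); correctness
  is independent of the drawn latency, a documented simplification (real
  errors tend to be fast).
* **Artifacts.** `inject_artifacts()` replaces a known fraction of
  responses with fast guesses (< 200 ms) and lapses (> 1200 ms) so the
  window filter has ground truth.

What the simulator deliberately omits: sequential effects, practice or
fatigue drift, inhibition of return, SOA-dependent alerting decay (a hook
exists in the design but is off by default), and any coupling between speed
and accuracy. Passing recovery tests therefore show that the estimators are
correct *under the additive model*, not that real ANT data satisfy that
model.

## Problem sizes used in the test suite

The package's checks run at sizes chosen to make Monte-Carlo error small
relative to the effects being verified: algebraic identities on 1000 random
median sextets (they are exact, so size only adds coverage); oracle
equivalence on 100 random ICC grids and 20 random 2×2 designs; parameter
recovery on one 200-subject cohort at 27 trials per condition, asserted
within 3 standard errors; null calibration of the influence-score t-test
and the 2×2 interaction F on 2000 simulated 24-subject single-block cohorts
against a 3-standard-error binomial band around 0.05; and the reliability
ordering on a 36-subject cohort with 300–1000 split-half permutations.

## Known limitations

* The influence scores are double differences of medians and are intrinsically
  noisy at realistic trial counts; single-session estimates should be
  interpreted at the group level, not per subject.
* The ICC implemented is the one-way random-effects form only; two-way
  forms (fixed raters, absolute agreement) are out of scope.
* Accuracy-based scores can be computed through the same contrasts, but the
  correlation and reliability machinery excludes them by default because
  between-condition accuracy differences are frequently zero, producing
  undefined normalised scores.
* The double-cue ANT variant and multi-modality designs are not modelled.
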