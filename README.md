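# antscores

Scoring, inference and reliability tools for the **Attention Network Test
(ANT)**, the cued flanker paradigm that measures three attentional networks —
alerting, orienting and executive control — in a single session.

## The problem

The ANT crosses three cue conditions (no cue, center cue, spatial cue) with
two flanker target conditions (congruent, incongruent), giving six cells with
condition codes `ncc, nci, ccc, cci, scc, sci`. The traditional scores are
cell-mean contrasts on per-subject median reaction times:

    alerting  = mean(ncc, nci) - mean(ccc, cci)
    orienting = mean(ccc, cci) - mean(scc, sci)
    executive = mean(nci, cci, sci) - mean(ncc, ccc, scc)

Because each contrast averages over cells in which *other* networks are also
engaged, any interaction between networks (for example, a warning cue
enlarging the flanker-conflict cost) leaks into all three scores and into
their reliabilities. `antscores` implements an alternative **condition
dissection**: each cell is decomposed additively (`ncc` = baseline, `nci` =
baseline + executive, `ccc` = baseline + alerting, ... ), so that each score
is a difference of exactly two cells that isolates one network:

    alerting  = ncc - ccc        orienting = ccc - scc
    executive = nci - ncc

and the inter-network interactions become **directed influence scores**, the
four interaction contrasts

    AL->EX = (cci - ccc) - (nci - ncc)    OR->EX = (sci - scc) - (cci - ccc)
    EX->AL = (nci - cci) - (ncc - ccc)    EX->OR = (cci - sci) - (ccc - scc)

In milliseconds these pairs are exact mirrors (`EX->AL = -AL->EX`); the
default normalisation divides each contrast by the pure score of the target
network, which breaks the symmetry and expresses influence as a fraction of
the affected effect. Under the additive generative model with interaction
parameters γ<sub>AE</sub>, γ<sub>OE</sub>, the traditional scores are biased
(`E[alerting] = A - γ_AE/2`, `E[executive] = E + (2γ_AE + γ_OE)/3`) while the
dissection scores are unbiased — the package's simulator makes this testable
by parameter recovery.

Around the scores, the package provides the full analysis stack: trial-level
preprocessing (200–1200 ms reaction-time window, accuracy-based subject
exclusion at 75%, per-condition medians over correct trials), one-sample /
paired t-tests and Pearson correlations, two-factor repeated-measures ANOVA
with Greenhouse–Geisser correction and partial η², one-way random-effects
intraclass correlation across runs, ICC = (MSb − MSw)/(MSb + (k − 1) MSw),
and permutation split-half reliability (trials split within subject ×
condition, 1000 random splits, reliability = mean split correlation).

## Worked example

```r
library(antscores)

trials <- simulate_dataset(sim_config(n_subjects = 36, seed = 42))
pp <- preprocess_trials(trials)
pp$removed_fraction
#> [1] 0.004115932
pp$n_subjects_retained
#> [1] 34
```

0.4% of responses fell outside the 200–1200 ms window, and two simulated
subjects dropped below 75% accuracy in at least one condition and were
excluded. Scoring the retained cohort in milliseconds and testing each item
against zero:

```r
scores <- score_cohort(pp$summary, normalization = "raw")
score_t_tests(scores)[c(1, 4, 7), ]
#> # A tibble: 3 × 7
#>   item         estimate statistic    df       p_value conf_low conf_high
#>   <chr>           <dbl>     <dbl> <dbl>         <dbl>    <dbl>     <dbl>
#> 1 old_alerting     36.0      7.90    33 0.00000000414    26.7       45.2
#> 2 new_alerting     43.1      7.45    33 0.0000000147     31.3       54.8
#> 3 al_to_ex         14.2      2.64    33 0.0124            3.28      25.2
```

The dissection method recovers a larger alerting effect (43 ms vs 36 ms) —
the traditional contrast absorbs half of the alerting-by-conflict
interaction — and the AL→EX influence score (14 ms, p = .012) picks up the
interaction that the generator injected (γ<sub>AE</sub> = 20 ms). The
omnibus cue-by-target ANOVA tells the same story:

```r
tidy(anova_cue_target(pp$summary))[, 1:7]
#> # A tibble: 3 × 7
#>   effect        df df_error statistic  p_value partial_eta_sq epsilon
#>   <chr>      <int>    <dbl>     <dbl>    <dbl>          <dbl>   <dbl>
#> 1 cue            2       66     90.3  1.28e-19          0.732   0.888
#> 2 target         1       33    374.   1.42e-19          0.919   1
#> 3 cue:target     2       66      8.23 6.42e- 4          0.200   0.856
```

Reliability per score item — ICC across the three blocks and split-half over
200 random trial splits:

```r
rel <- reliability_report(filter_rt_window(trials), n_perm = 200, seed = 7)
tidy(rel)
#> # A tibble: 10 × 3
#>    item              icc split_half_r
#>  1 old_alerting   0.105       0.235
#>  2 old_orienting  0.0492      0.0455
#>  3 old_executive  0.533       0.549
#>  ...
#>  7 al_to_ex      -0.121      -0.220
```

Difference scores built from few trials are noisy, so at 27 trials per
condition single-session reliabilities are modest, and the influence scores
(double differences) are the least reliable — the ordering the method
predicts.

An end-to-end pipeline (simulate → preprocess → score → analyze →
reliability) is driven by a YAML config:

```r
run_pipeline(system.file("extdata", "demo-config.yaml", package = "antscores"),
             out_dir = "ant-results")
```

or from the shell via `Rscript inst/scripts/ant-pipeline.R --config
demo-config.yaml --out-dir ant-results`.

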