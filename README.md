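# stagescreen

Data-driven screening for Alzheimer's disease clinical trials: fit a
kernel-density **event-based model** (KDE-EBM) of cognitive decline on a
reference cohort, assign each trial participant a baseline **model stage**
(disease progression score), stratify the trial at a stage threshold, and run
the trial's primary and secondary analyses per stratum.

## Who this is for

Trial statisticians and disease-progression modellers who suspect that a
null trial hides a responder subgroup. Clinical labels like "amnestic MCI"
pool people at very different points of the disease cascade; a treatment that
helps only the more severely affected is **washed out** when everyone is
analyzed together. `stagescreen` detects and quantifies exactly this
situation — and, because the real datasets of this kind are controlled-access,
it ships a synthetic-cohort generator with known ground truth so the whole
pipeline is testable end to end.

## The model

K cognitive "events" (instruments crossing from their normal to their
abnormal distribution) accumulate in an unknown order S; a subject at stage k
has experienced the first k events. With per-feature event/no-event densities
`p_E`, `p_N` (two-component kernel-density mixtures, robust to the
floor/ceiling pile-up of bounded scales, constrained monotone in a known
disease direction) the likelihood of S is

    P(X | S) = prod_j 1/(K_j+1) * sum_{k=0..K_j}
               prod_{i<=k} p_E(x_{S(i)j}) * prod_{i>k} p_N(x_{S(i)j})

Sequence inference: greedy ascent + Metropolis MCMC over orderings, with
uncertainty summarized as a cross-validated positional density (5-fold x 10
repeats, 50 pooled posterior sample sets). Staging: argmax of the per-subject
stage posterior under the maximum-likelihood sequence. Trial analysis:
Kaplan-Meier curves, Cox proportional-hazards models (Efron ties; baseline
age, MMSE, APOE-e4 covariates), Hochberg step-up correction across **all**
arm-by-stratum comparisons, and per-visit two-sided Mann-Whitney tests on the
cognitive outcome.

See `vignettes/stagescreen-methods.Rmd` for the full methods account.

## Worked example

```r
library(stagescreen)

specs <- ad_cognitive_battery()                       # 10 bounded instruments
feats <- vapply(specs, `[[`, character(1), "name")
ref   <- generate_reference_cohort(specs, seed = 42)  # 229 CN / 181 AD / 400 MCI
adj   <- fit_covariate_adjustment(ref$cohort, feats)
fit   <- cross_validated_fit(apply_covariate_adjustment(adj, ref$cohort),
                             specs, folds = 2, repeats = 1, n_iter = 2000,
                             seed = 42, adjustment = adj)
fit
#> <ebm_fit> 10 events; 2 x 1 cross-validation pooled over 2 sample sets
#>   ML sequence: clock_drawing > lm_delayed > dsst > animals > cdr_global >
#>     lm_immediate > mmse > digit_span_bwd > boston_naming > cdr_sob

trial  <- generate_trial_cohort(specs, ref$truth$true_sequence, seed = 43)
stages <- stage_cohort(trial$cohort, fit)     # baseline disease progression scores
lab    <- stratify_by_stage(stages, threshold = 8)
attr(lab, "counts")
#>     Others Late-stage
#>        644        125

primary_outcome_analysis(trial$cohort, lab, arms = "donepezil")
#> <primary_outcome> Cox treatment effects by stratum:
#>     stratum       arm   n n_events    hr ci_low ci_high p_raw p_adj
#>         All donepezil 512      114 0.740  0.510    1.07 0.113 0.226
#>      Others donepezil 425       85 0.858  0.558    1.32 0.484 0.484
#>  Late-stage donepezil  87       29 0.510  0.224    1.16 0.109 0.226
```

The recovered maximum-likelihood sequence equals the generator's ground
truth, and the stage-based split (644/125) recovers the configured late
fraction. The trial was simulated with a true donepezil hazard ratio of 0.55
in the late-stage subgroup and 1.0 elsewhere: pooled over all subjects the
estimated effect is a diluted HR 0.74, the unaffected "Others" stratum shows
HR 0.86, and the late-stage stratum isolates HR 0.51 — the wash-out pattern
the screening tool exists to reveal. (`autoplot()` on the fit's positional
density, on the mixtures, and on the primary outcome object draws the
standard diagrams.)

A file-based pipeline with the same steps: `run_simulate()`, `run_fit()`,
`run_stage_analyze()` (see also the thin CLI wrapper in
`inst/cli/stagescreen.R` with `simulate` / `fit` / `stage-analyze`
subcommands).

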