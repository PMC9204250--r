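---
title: "Event-based staging as a clinical-trial screening tool: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-based staging as a clinical-trial screening tool: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagescreen)
```

## The problem

Disease-modifying trials in Alzheimer's disease routinely enrol
heterogeneous cohorts: participants who all carry the same clinical label
(amnestic MCI) can sit at very different points of the underlying
pathophysiological cascade. If a treatment only helps a subgroup — say, the
more severely affected — pooling everyone in one analysis dilutes ("washes
out") the effect, and the trial reads null. `stagescreen` implements a
computational screening workflow for this situation:

1. fit a data-driven model of cumulative cognitive decline (an event-based
   model, EBM) on a reference observational cohort;
2. assign each trial participant a baseline *model stage* — the number of
   decline events their screening measurements most likely reflect;
3. stratify the trial at a stage threshold and run the trial's own primary
   (time-to-conversion) and secondary (cognition) analyses per stratum, with
   familywise multiplicity control across all strata.

Because real reference and trial data of this kind are controlled-access,
the package ships a synthetic-data module that generates both cohorts with
known ground truth (event sequence, per-subject stages, subgroup hazard
ratios), so every stage of the pipeline can be validated against truth.

## The event-based model

The model assumes K measurable "events" — here, cognitive instruments
transitioning from their normal to their abnormal distribution — accumulate
in a fixed order $S$ across the disease course. A subject at stage $k$ has
experienced exactly the first $k$ events of $S$. With $p_E(x_{ij})$ and
$p_N(x_{ij})$ the densities of subject $j$'s value on feature $i$ under the
event/no-event components, and a uniform prior over stages, the data
likelihood of an ordering $S$ is

$$ P(X \mid S) = \prod_j \frac{1}{K_j + 1} \sum_{k=0}^{K_j}
   \prod_{i \le k} p_E\!\left(x_{S(i)j}\right)
   \prod_{i > k} p_N\!\left(x_{S(i)j}\right), $$

where missing features are dropped from the products and $K_j$ counts the
subject's observed features. This is the form shared by the EBM literature;
the package treats it as the contract and verifies it against brute-force
stage-sum enumeration in the test suite.

Sequence inference combines greedy ascent (best-improving pairwise swaps
from random restarts; default 10) with a Metropolis sampler over orderings
(pairwise-swap proposals, acceptance $\min(1, e^{\Delta \log L})$; default
10,000 iterations, 10% burn-in). Uncertainty is summarized as a *positional
density*: a row-stochastic K×K matrix of posterior event-position
frequencies, pooled with equal weight across the sample sets of repeated
stratified cross-validation (default 5 folds × 10 repeats = 50 sets).
Pooling averages each set's empirical distribution rather than concatenating
raw samples, so short and long chains count equally.

Staging evaluates the same stage-sum terms for one subject under the
full-data maximum-likelihood sequence and assigns the argmax stage, ties
broken toward the lower stage — the conservative choice for screening, since
it produces fewer false "late-stage" labels.

## KDE mixtures and the disease-direction prior

Cognitive instruments are bounded, with heavy floor/ceiling pile-up, so the
per-feature two-component mixtures use weighted Gaussian-kernel densities
rather than parametric components. The fit is an alternating refit:
responsibilities start at the diagnosis labels (reference controls = normal,
dementia cases = abnormal, everyone else 0.5), each iteration re-estimates
the two weighted KDEs, sets the mixture weight to the mean abnormal
responsibility, and updates free responsibilities to the posterior,
until the largest change falls below 1e-4 (cap 200 iterations). The fit is
fully deterministic.

Two design points deserve explanation because the obvious alternatives fail:

**Label noise and the release rule.** Diagnosis labels are noisy proxies for
per-feature event status: an *early* event has already occurred in many
control-labeled subjects, and a *late* event has not yet occurred in many
dementia-labeled subjects, so either class can carry ~50% label
contamination on some feature. Letting labeled points float freely with the
posterior is unstable: when the two classes do not actually separate, half
of each class sits "beyond the opposite median" and label-flip feedback
polarizes the posterior to a spurious 0-to-1 sigmoid. `stagescreen`
therefore anchors each class at the quartile of its values on its *own* side
of the disease direction (robust to contamination, which always pulls toward
the other side) and releases a labeled point only when (i) the class medians
separate by more than two pooled bandwidths and (ii) the value sits on the
wrong side of the midpoint between the anchors by at least one bandwidth;
after each convergence, labeled points whose posterior contradicts their
label by more than 0.75 are additionally released and the fit re-converges
(at most three rounds). Under no class separation nothing is released and
the posterior stays flat, which the tests check explicitly.

**Bandwidths.** Silverman's rule assumes a unimodal sample. Applied to the
pooled two-class data it oversmooths the components, which measurably
degrades downstream staging. The pooled-sample Silverman bandwidth (floored
at 1e-3 of the data range) therefore only sets the working scale for the
release rule; once the classes separate, each component receives its own
Silverman bandwidth estimated from its labeled values on its own side of the
midpoint. Without separation both components share the pooled bandwidth —
per-class bandwidths estimated from identical distributions differ by
sampling noise alone, and that mismatch would itself polarize the posterior
tails.

The disease-direction prior is enforced after fitting: the event posterior
$P(E \mid x) = w f_E / (w f_E + (1-w) f_N)$ is projected onto the monotone
functions (isotonic regression, pool-adjacent-violators) over a 512-point
grid spanning the kernel range, oriented by the known direction of decline.
When the raw posterior is already monotone the model keeps evaluating it
exactly, so the projection is an identity there. Downstream likelihood work
uses the component-density pair implied by the constrained posterior with
the overall mixture density preserved; where the constraint is inactive this
is exactly the raw KDE pair. Queries beyond all kernel support take the
limiting probability implied by the direction (1 on the disease side, 0
otherwise) and are flagged.

## Preprocessing

Features are residualized against age and education by OLS fitted on the
reference-label (control) group only and applied identically to every
subject: adjusted = raw − (predicted − control mean). Trial cohorts are
adjusted with the *reference-fitted* coefficients — a trial has no control
arm to refit on. Adjusted values are deliberately not re-clipped to
instrument bounds: boundary mass is a property of the raw measurement
process and re-clipping would distort the control/case separation the
mixtures rely on. Complete-case filtering on the model features precedes
fitting, matching the reference analysis's complete-data rule; no imputation
is attempted.

## The synthetic cohorts

The generator is the package's definition of the study conditions, not a
tuning knob.

* **Reference cohort** — default 229 controls / 181 dementia / 400 MCI
  (total 810). A uniformly random true sequence is drawn; stages are
  truncated-geometric from stage 0 for controls, truncated-geometric from
  stage K for dementia cases (decay 0.5), and uniform over 0..K for MCI —
  parametric stand-ins for the qualitative shape seen in real staged
  cohorts (controls low, dementia high, MCI spread). A subject at stage k
  draws features at sequence positions ≤ k from their abnormal distribution
  and the rest from the normal one, clipped to instrument bounds. Age ~
  N(73, 7.3) and education ~ N(14.6, 3.1) (truncated positive) enter
  features through per-feature linear coefficients so the adjustment step
  has real work to do.
* **Trial cohort** — default 259 placebo / 257 vitamin E / 253 donepezil
  (total 769), all labeled MCI. Baseline stages come from a bimodal mixture:
  weight 0.16 on a late component (uniform over stages > 8), the rest
  uniform over stages 0–8; the late weight matches the late-subgroup
  fraction reported for the trial this design emulates (121/769) and is a
  free parameter, not a modeled mechanism. Conversion times are exponential
  with log-hazard $\log h_0 + b\,\mathrm{stage} + \log \mathrm{HR}(\text{arm},
  \text{subgroup})$ — the simplest generative model satisfying proportional
  hazards, so Cox recovery is well defined. Defaults $h_0 = 0.004$/month and
  $b = 0.15$ give roughly 45% three-year conversion for untreated late-stage
  subjects and ~13% at stage 0. Administrative censoring at 36 months;
  per-visit dropout censors at the last attended visit (never before the
  first follow-up, so event times stay positive). The cognitive outcome
  (0–85, higher = worse) is linear per month with a stage-dependent slope,
  attenuated multiplicatively in treated subgroups, plus Gaussian noise —
  enough structure for the per-visit rank tests to have power, no more.
* The default treatment-effect configuration is HR 0.55 for donepezil in the
  late-stage subgroup and 1.0 everywhere else: the configuration whose
  wash-out under pooled analysis the screening pipeline exists to detect.

What the generator does *not* emulate: imaging/fluid biomarkers, visit-level
measurement error models, practice effects, non-proportional hazards,
informative dropout, or any vitamin-E-specific biology. Passing tests on
these cohorts show the pipeline recovers the structure it assumes; they do
not certify performance on real data, where none of the generative
assumptions hold exactly.

## Trial analyses

The primary outcome uses Kaplan-Meier product-limit curves (Greenwood
variance, log–log 95% intervals) and Cox proportional-hazards models with
Efron tie handling and Wald intervals, comparing each treatment arm against
placebo with baseline age, MMSE and APOE-e4 carriage as covariates,
intention-to-treat (dropouts censored at last visit). One Hochberg step-up
family covers *all* arm-by-stratum treatment p-values — the correction spans
every subgroup analyzed, not only the subgroup of interest, the most
conservative reading of extending the original trial's two-arm correction.
Non-estimable strata (e.g. no events) are reported as missing but still
count toward the family size. The secondary outcome applies two-sided
Mann-Whitney U tests (midranks; exact enumeration when $n_x n_y \le 400$
with no ties, otherwise normal approximation with tie and continuity
corrections) to the cognitive score at each 6-month visit within each
subgroup, on observed values only, with a single Hochberg family across all
subgroup-by-visit tests.

"Late-stage" means stage strictly greater than the threshold (default 8,
configurable, with `suggest_stage_threshold()` offering a histogram-valley
alternative); the strict inequality mirrors delineating the subgroup
*beyond* a stage on the histogram.

## Numerical choices

* Stage posterior and sequence likelihood evaluate stage terms by cumulative
  products; component densities are floored at 1e-300 to keep logs finite.
* Stage ties break toward the lower stage; subjects with no observed
  features get a uniform posterior and a flag.
* Positional-density rows and stage posteriors sum to 1 within 1e-12
  (asserted in the tests).
* Fold assignment is stratified by diagnosis; a diagnosis group smaller than
  the fold count is an error, not a silent degradation.
* All randomness (generators, greedy restarts, MCMC, folds) is governed by
  explicit integer seeds; identical seeds give byte-identical outputs, and
  the RNG state of the calling session is left untouched.

## Validation studies and the sizes they run at

The package ships three study functions used by the test suite and the
acceptance script:

* `evaluate_sequence_recovery()` — 10 cohorts of 810 (229/181/400), K = 10
  events at 2 SD separation; reports the normalized Kendall tau distance
  between the recovered maximum-likelihood sequence and the truth.
* `evaluate_staging_accuracy()` — one training cohort of 810 at 3 SD
  separation; 500 held-out subjects drawn from the same population (same
  diagnosis mix, stage distributions and true sequence — "held out" means
  same-distribution, not a different design); reports exact and within-±1
  stage accuracy.
* `evaluate_screening_power()` — one reference model, then 100 independent
  trials of 769 with the late-stage-only HR 0.55; each trial is staged,
  stratified and analyzed; reports how often the stratum hazard ratios order
  as Late < All < Others (the wash-out signature), and the Wald-CI coverage
  of the true late-stage hazard ratio.

These sizes keep each study to a few minutes on one CPU while leaving the
acceptance margins interpretable; they are the package's chosen experiment
sizes, stated here so results are reproducible as printed.

## Known limitations

* Cross-sectional EBM only: no longitudinal consistency, no subtype
  inference, one ordering for the whole cohort.
* The KDE mixtures assume a single abnormality direction per feature and at
  least ~10 labeled subjects per class.
* Stage is an integer summary; borderline subjects near the stratification
  threshold carry real uncertainty that a hard Late/Others split discards
  (the stage posterior is exported for users who want soft handling).
* The Cox analyses assume proportional hazards within strata, which the
  synthetic generator satisfies by construction but real trials need not.
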