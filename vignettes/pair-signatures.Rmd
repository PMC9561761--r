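---
title: "Rank-pair prognostic signatures: model, estimators, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-pair prognostic signatures: model, estimators, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairsig)
```

## The model

`pairsig` builds prognostic signatures whose features are binary
within-sample gene comparisons. For a gene pair $(a, b)$ and a sample $s$
with expression profile $x_s$,

$$v_{ab}(s) = \mathbf{1}\{x_s[a] > x_s[b]\},$$

and the risk score of a signature with pairs $i = 1, \dots, n$ and Cox
coefficients $\beta_i$ is

$$\mathrm{risk}(s) = \sum_{i=1}^{n} \beta_i \, v_i(s),$$

with $s$ called high-risk when $\mathrm{risk}(s)$ strictly exceeds a fixed
cutoff. Because $v_{ab}$ depends only on the ordering of two values inside
one sample, the entire model is invariant to any strictly increasing
per-sample transformation of the expression values. That is the method's
batch strategy: no quantile normalization or location/scale correction is
applied anywhere, and a single profile on any monotone scale (TPM,
microarray intensity, qPCR expression relative to a housekeeping gene) can
be scored in isolation. The invariance is exact and is asserted
bit-for-bit in the test suite; it is a theorem about the transform, not an
empirical observation.

The survival side assumes proportional hazards: pairs are screened and fit
with Cox models on overall-survival time (months) and an event indicator
(1 = death, 0 = censored). Censoring is assumed independent of the risk
score given the covariates, the usual Cox assumption.

## The selection pipeline

1. **Enumeration.** All $n(n-1)/2$ unordered pairs of the gene universe, in
   a canonical orientation (`gene_a` before `gene_b` in C-locale order) so
   pair identity is stable across files and platforms.
2. **Prevalence filter.** A pair whose indicator is nearly constant across
   the cohort carries no between-sample contrast; the default band keeps
   pairs with mean indicator in $[0.2, 0.8]$, the convention in the
   rank-pair signature literature. The band is configurable; the filter is
   computed on the full cohort before the train/validation split by
   default, with `filter_on_training = TRUE` available for a strictly
   leakage-free variant (prevalence filtering uses no survival
   information, so the leakage in question is marginal distribution only).
3. **Univariate Cox screen.** One single-covariate Cox fit per pair;
   retained iff the Wald $p <$ `alpha` (default $0.001$, no
   multiple-testing correction — the screen is deliberately a raw
   threshold and the penalized fit downstream does the real selection).
   Constant and non-converging (monotone-likelihood) pairs are skipped and
   counted.
4. **LASSO Cox.** `glmnet` over a descending lambda path; lambda chosen at
   the minimum cross-validated partial-likelihood deviance (10 folds by
   default; the one-standard-error rule is available as
   `lambda_rule = "1se"` for a sparser, more conservative signature). Fold
   assignment is stratified by event status with a seeded shuffle so no
   fold is event-free; with the seed fixed the whole fit is reproducible
   bit-for-bit.
5. **Cutoff.** The risk cutoff maximizes Youden's index
   ($\mathrm{sens} + \mathrm{spec} - 1$) on the time-dependent ROC curve
   at a 12-month horizon.

## The time-dependent ROC estimator

`td_roc()` implements the Kaplan–Meier cumulative/dynamic estimator:
cases at horizon $t$ are subjects with an event by $t$, controls are
subjects event-free at $t$, and censoring before $t$ is handled through
product-limit estimates. With $S$ the KM survival function and $X$ the
score,

$$\mathrm{TPR}(c) = \frac{\big(1 - S(t \mid X > c)\big)\,P(X > c)}{1 - S(t)},
\qquad
\mathrm{TNR}(c) = \frac{S(t \mid X \le c)\,P(X \le c)}{S(t)}.$$

Numerical conventions, all fixed deliberately:

* candidate thresholds are the midpoints between adjacent distinct score
  values, so the chosen cutoff always separates two observed score levels;
* KM-plug-in estimates can fall marginally outside $[0,1]$ under heavy
  censoring and are clamped;
* ties in the Youden index break toward the **lower** threshold (larger
  high-risk group);
* the AUC is the trapezoidal area under the empirical (FPR, TPR) curve
  closed at $(0,0)$ and $(1,1)$;
* ties in expression scores to 0 in the pair indicator, and scores exactly
  at the cutoff are low-risk (strict inequality) — boundary behavior has
  to be fixed somewhere and is asserted in tests.

The tests verify the estimator pointwise against `survival::survfit`
computations and the Youden optimum against brute-force midpoint search.

## Evaluation toolbox

* `km_logrank()` — product-limit curves and the $k$-group log-rank test
  (`survival::survdiff`), validated against a hand-computed 6-subject
  worked table.
* `cox_model()` — uni-/multivariate Cox with Wald 95% CIs. Covariate
  coding follows the clinical convention used throughout: gender female =
  0 / male = 1, MGMT promoter methylated = 0 / unmethylated = 1, age in
  years, risk group low = 0 / high = 1, all entered as continuous
  covariates. Missing covariates are handled complete-case per model
  (Kaplan–Meier analyses keep all samples); no imputation.
* `c_index()` — Harrell's concordance (via `survival::concordance`,
  `reverse = TRUE`): higher score should precede shorter survival, tied
  scores credit 1/2, incomparable pairs under censoring are excluded. The
  estimator choice (Harrell rather than Uno) is the standard reading when
  a C-index is reported without further qualification. Tested against
  exhaustive comparable-pair enumeration.
* `compare_signatures()` — paired C-indices plus a seeded bootstrap
  percentile CI (default 1000 resamples) of the difference. A published
  comparator signature enters as its score vector; the package does not
  re-derive third-party signatures.
* `quartile_analysis()` — extreme-quartile contrast; boundaries at ranks
  $\lfloor 0.25 n \rfloor$ and $\lceil 0.75 n \rceil$ with deterministic
  (input-order) tie resolution; degenerate all-equal scores are an error.
* `score_external_profile()` — the single-sample path: indicators, score
  and group from one profile with no cohort context.

## The robustness test

`robustness_test()` asks whether the selected signature is more stable
than what outcome randomization produces. Two symmetric arms run the same
reduced-resolution screen + LASSO:

* **observed arm** — event-stratified subsamples (80% by default) of the
  real data; each run counts how many of the observed signature's pairs
  are re-selected;
* **null arm** — per randomization, `(os_time, os_event)` rows are jointly
  permuted across samples (preserving the survival marginal and the pair
  matrix), a *null signature* is derived from the permuted data, and one
  subsample re-run on the same permuted data counts how many of that null
  signature's pairs are re-selected.

The empirical p-value is the add-one estimator
$(1 + \#\{\mathrm{null} \ge \mathrm{observed}\}) / (1 + n_\mathrm{valid})$.
The design point is symmetry: a naive null that only permutes and re-runs
would be compared against an observed statistic conditioned on the very
labels that selected the signature, and would reject even on pure noise.
Conditioning both arms on their own selection step makes the statistic
exchangeable under the null — on simulated outcome-independent cohorts the
empirical p is non-extreme in essentially all runs, while planted-signal
cohorts reject at $p \approx 1/(n+1)$. Runs where a fit fails are logged,
excluded, and counted in `n_failed`.

## The synthetic-data generator

`simulate_cohort()` emulates the statistical structure the pipeline
assumes, not any particular tumor biology:

* latent log-normal expression (gene log-means $\sim N(3, 1)$, per-sample
  log-SD 1, plus measurement noise of log-SD 0.2);
* planted pairs drawn between genes that are **given equal log-means**, so
  each planted indicator is approximately Bernoulli(1/2) — the maximal
  variance, hence estimable effect, configuration; decoy genes keep
  independent means;
* proportional-hazards event times: exponential with rate
  $\lambda_0 \exp(\sum_k \beta_k v_k)$. The default baseline
  $\lambda_0 = 0.05$/month gives a median survival near 14 months, the
  scale typical of IDH wild-type glioblastoma cohorts;
* independent exponential censoring whose rate is calibrated by bisection
  so the realized censored fraction matches the target (default 30%,
  tolerance 0.5 points at the calibration sample);
* batch structure in two flavors: `monotone_per_sample` applies
  $x \mapsto s_b\, x^{p_b}$ with batch-dependent scale and power (strictly
  increasing, so pair indicators are provably untouched — this flavor
  demonstrates the method's core claim exactly), and `gene_shift` applies
  per-gene per-batch multiplicative shifts on the log scale (a realistic
  partial violation that the transform does **not** neutralize exactly and
  which is therefore only evaluated empirically, never asserted).

Defaults (400 samples, 50 genes, 3 planted pairs with log hazard ratios
1.0, 0.8, −0.8, two batches) are the conditions used by the package's own
validation. What the generator does *not* emulate: gene–gene correlation
structure, tumor purity and immune-cell mixtures, non-proportional
hazards, informative censoring. Passing recovery tests on these cohorts
therefore show correctness of the estimators under the model's own
assumptions — not performance on real tumors.

A note on the discrimination ceiling: with three binary features at these
effect sizes the concordance of the *true* linear predictor is only about
0.69 (the expected value of $1/(1 + e^{-|\Delta\eta|})$ over random sample
pairs), and the fitted signature attains that oracle almost exactly in the
held-out experiments. Larger planted effects would raise the ceiling;
the defaults were fixed once and kept.

## Problem sizes and reproducibility

The validation suite works at deliberately modest scales — cohorts of
40–1000 samples, universes of 10–50 genes (up to 1225 candidate pairs),
10–20 seeds per stochastic claim, 30–50 permutations per robustness run —
chosen so the full suite and the acceptance script each complete in about
a minute while keeping every stochastic acceptance margin comfortable.
Every stochastic step (simulation, fold assignment, subsampling,
bootstrap, permutation) consumes an explicit seed and restores the
caller's RNG state, so identical inputs reproduce identical outputs
bit-for-bit, including serialized signature files.

## Known limitations

* The prevalence-filter band and screen threshold are conventions, not
  optimized values; both are exposed as parameters.
* Harrell's C is biased upward under heavy censoring; no IPCW (Uno)
  variant is provided.
* The bootstrap CI for C-index differences is a percentile interval; it is
  a pragmatic uncertainty summary, not an exact test.
* The rank-pair transform is invariant to *per-sample monotone*
  distortions only; per-gene batch effects (probe affinity differences)
  can flip indicators and are not corrected, only measurable via
  `evaluate_batch_mixing()`.
* Gene identifiers are assumed pre-harmonized across cohorts; no
  probe-to-gene or cross-annotation mapping is attempted.
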