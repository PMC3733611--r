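---
title: "Testing the added value of new biomarkers: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing the added value of new biomarkers: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rocnest)
```

## Scope

`rocnest` answers two distinct questions that are often conflated:

* **Paradigm 1 — training-data tests of the ideal model.** Do `q` new
  biomarkers improve the *ideal* (infinite-training-data) performance of a
  model nested inside a larger one? The LR test, the Wald test, and the
  exact F test of ideal AUC all test this hypothesis, using only training
  data.
* **Paradigm 2 — test-data comparison of fixed models.** Do two *already
  trained and frozen* models differ in their true AUC on the population,
  judged from scores on a common independent test set? This is the
  correlated-AUC z test (DeLong or U-statistics variance).

The null hypotheses differ: Paradigm 1 concerns the ideal AUC `A`,
Paradigm 2 the conditional AUC `A_r` of a model trained on one finite
sample. They coincide only as the training sample grows without bound. The
learning-curve study (`run_learning_curve()`) makes the distinction
concrete.

## Paradigm 1: the three training-data tests

### The exact F test of ideal AUC

Assume the `d` biomarkers follow multivariate normal distributions in both
classes with means `μ0`, `μ1` and a **common** covariance `V`. The optimal
linear model is Fisher's discriminant, and its ideal AUC is
`A = Φ(√D²/√2)` with `D² = (μ1−μ0)ᵀV⁻¹(μ1−μ0)` the squared Mahalanobis
distance (`mahalanobis_to_auc()`). Since the map is strictly increasing,
"the new markers do not raise the ideal AUC" is equivalent to "they do not
raise `D²`", and that hypothesis has an exact test: with sample distances
`D̂²` computed from pooled-covariance estimates (denominator `N0+N1−2`),
Rao's statistic

$$U = \frac{N_0+N_1-p-q-1}{q}\left(\frac{1+c\hat D^2_{p+q}}{1+c\hat D^2_{p}}-1\right),
\qquad c=\frac{N_0N_1}{(N_0+N_1)(N_0+N_1-2)}$$

is exactly `F(q, N0+N1−p−q−1)` under the null. Exactness at *any* sample
size is the point: the test's type I error equals the nominal level even
when `N0+N1` barely exceeds `p+q`, where the asymptotic tests inflate.

Numerical choices:

* The pooled covariance uses the `N0+N1−2` denominator, consistent with the
  `(N0+N1−2)` factor inside `c`. The test suite's null-distribution check
  (a Kolmogorov–Smirnov test of simulated `U` values against the exact F
  reference) pins this convention empirically.
* A reciprocal-condition-number guard (`rcond < 1e-12`) rejects singular
  pooled covariances rather than silently switching to a pseudo-inverse:
  the statistic presumes a proper Mahalanobis distance.
* `p = 0` is allowed with `D̂²(0) := 0`, reducing to a one-sample
  separation test of the new panel alone.
* Nestedness guarantees `D̂²_full ≥ D̂²_partial` in exact arithmetic;
  violations beyond `1e-8` raise an error (they indicate non-nested inputs),
  while sub-tolerance rounding is snapped to equality.
* The p-value is one-sided (upper tail): added variables can only increase
  the population distance.

The mapping direction `A = Φ(√D²/√2)` (rather than `Φ(D²/2)`) is the one
under which the 15-marker reference panel (`D² = 2.00`) has ideal AUC
0.8413 and the alternative 16-marker panel (`D² = 2.36`) has 0.8613; both
anchors are asserted in the tests.

### LR and Wald tests for nested logistic regression

`fit_logistic()` fits by iteratively reweighted least squares (tolerance
`1e-10` on the relative deviance change, at most 100 iterations), always
including an intercept. The LR statistic is `2(ℓ_full − ℓ_partial)` against
`χ²(q)`; the Wald statistic for `q = 1` is the coefficient over its
standard error (inverse Fisher information, which equals the observed
information for the canonical logit link) against the standard normal, and
for `q > 1` the quadratic form of the new-coefficient block against
`χ²(q)`.

Design choices where standard practice had to be pinned down:

* **Intercept included.** The ideal discriminant needs no intercept when
  classes are balanced, but the simulated designs are mostly unbalanced and
  applied logistic modelling always carries an intercept. The Monte Carlo
  reproduction of the LR/Wald operating characteristics supports this
  choice.
* **Separation.** With 16 predictors and as few as 90 training subjects,
  quasi-complete separation occurs in a small fraction of draws
  (diagnosed as nonconvergence or any |slope| > 15). Such fits are *kept*,
  with their achieved statistics, and counted in the `flagged` column of
  Monte Carlo summaries; discarding them would bias rejection fractions.
* **Rank deficiency.** Aliased columns (e.g. a constant biomarker) get
  zero coefficients; the LR test then correctly degenerates to zero
  statistic, and the Wald test reports a degenerate result rather than
  dividing by a singular covariance block.
* Tiny negative LR statistics from finite convergence tolerance are
  clamped at zero.

## Paradigm 2: comparing correlated AUCs

The nonparametric AUC is `Â = (1/N0N1) Σ ψ(Xi, Yj)` with the win/tie/loss
kernel (`ψ = 1, 0.5, 0`); ties count half everywhere, including file-loaded
scores. `estimate_auc()` evaluates it via midranks in `O(n log n)`, exactly
equal to the all-pairs average.

Its sampling variance decomposes (Hoeffding) as

$$\mathrm{Var}(\hat A) = \tfrac{N_0-1}{N_0N_1}\xi_{01}
 + \tfrac{N_1-1}{N_0N_1}\xi_{10} + \tfrac{1}{N_0N_1}\xi_{11},$$

with `ξ01`, `ξ10` the one-subject covariance components and `ξ11` the
single-pair term. Two estimators are provided:

* **DeLong (structural components).** Per-subject averages of the kernel
  (`structural_components()`) estimate `ξ01` and `ξ10` through their sample
  variances ((n−1) denominators); `ξ11` is dropped. Always nonnegative,
  slightly biased.
* **Unbiased U-statistics.** Each expectation of a kernel product is
  averaged over index tuples with the required indices *distinct*, and `A²`
  is estimated unbiasedly by the average of `ψ(Xi,Yj)ψ(Xi',Yj')` over
  `i≠i', j≠j'`. These averages reduce algebraically to kernel row/column
  sums, giving an `O(N0N1)` implementation that the test suite proves equal
  (to 1e-12) to the literal four-index enumeration. The estimator is exactly
  unbiased for `Var(Â)` — also verified by simulation — but can go negative
  in tiny samples.

For two models on a common test set, `compare_auc()` builds
`SE² = Var(Â1) + Var(Â2) − 2Cov(Â1, Â2)` with the covariance from
cross-model structural components (DeLong) or cross-model U-statistic
analogues of the ξ terms (which the tests likewise verify against literal
enumeration), and refers `z = (Â1−Â2)/SE` two-sided to the standard normal.
Degenerate cases — `SE² ≤ 0` after clamping, e.g. identical score columns —
return `p = 1` with a `degenerate` flag: such data carry no usable evidence
of a difference, and the total function keeps Monte Carlo loops well
defined.

Kernel matrices are processed in column blocks (≤ 10⁶ entries at a time) so
memory stays bounded on large test sets.

**Scope warning.** Both variance estimators account only for test-set
sampling around *fixed* models. Applying the z test to resubstitution
scores of models retrained per dataset tests nothing meaningful — the
difference of resubstitution AUCs is not even asymptotically normal under
the null — and is precisely the misuse the harness here avoids by drawing
only test scores in the comparison study.

## The Monte Carlo harness and its study conditions

### Data generators

`reference_panel_spec()` defines the 16-biomarker panel used by the
added-value studies: identity covariance in both classes, negative-class
means zero, positive-class mean shifts
`(0.7, 0.6, 0.6, 0.5, 0.5, 0.3, 0.3, 0.2, 0.2, 0.1, 0.1, 0.1, 0, 0, 0, 0)`,
with the 16th entry raised to 0.6 under the alternative scenario. The panel
deliberately mixes informative and useless "existing" markers (false
positives from earlier studies) around a medium overall performance
(ideal AUC 0.8413 on the first 15). It emulates the *distributional
assumptions of the F test exactly* — multivariate normal, common covariance
— which is what makes the F test's exactness checkable; it does not emulate
skewed, heavy-tailed, correlated-measurement, or missing-data features of
real biomarker panels, so passing tests certify the statistics under their
stated assumptions, not robustness beyond them.

`binormal_pair_spec(rho, mu)` models paired test scores of two fixed
models: within-class bivariate normal, unit variances, correlation `rho`,
class means `(0,0)` and `(mu,mu)`. Both models share the true AUC
`Φ(mu/√2)`, so the comparison null holds for every `(rho, mu)`; `rho`
controls how much the common test set correlates the two AUC estimates.

All generators consume the global RNG stream; every experiment function
takes a `seed` and is bit-reproducible from `(arguments, seed)`. Summaries
carry the seed, the binomial Monte Carlo standard error
`√(f(1−f)/n_trials)`, and flagged-trial counts.

### Experiments

* `run_added_value_experiment(n0, n1, scenario, ...)`: per trial, draw one
  training sample and apply any of LR/Wald/F to the 16th marker given the
  first 15 (all tests see the identical draw, so their errors are
  correlated within a trial but each marginal rejection fraction is
  unaffected). 20,000 trials by default; the bundled test suite runs
  5,000-trial checks against three binomial standard errors.
* `run_auc_comparison_experiment(n0, n1, rho, mu, ...)`: per trial, draw
  paired test scores only (the models are fixed by construction) and apply
  both z tests. Degenerate trials count as non-rejections and are flagged.
* `run_learning_curve()`: the antler study. Training sizes 60–480 (total,
  split equally between classes — the natural reading for a curve indexed
  by one size axis; configurable), 1,000 independent retrainings per size
  on the 15 existing markers, and three AUC estimates per fit:
  resubstitution, a small independent test set (60 per class), and a large
  one (10,000 per class, making test noise negligible so the estimate
  approximates the conditional AUC itself). Expected geometry: the
  resubstitution mean sits above the ideal AUC 0.8413, the independent-test
  means below it, both converging toward it as training size grows, with
  the small-test branch noisier than the large-test branch at every size.
  At size 60 with 15 predictors a minority of fits separate; they are kept
  and counted.

### Problem sizes in the bundled tests

The test suite keeps the full protocol for the learning-curve study (1,000
repetitions) and uses 5,000-trial runs for the rejection-fraction checks,
10,000 replicates for the unbiasedness check of the U-statistics variance
(designs (10,10) and (30,15)), 5,000 draws for the exact-distribution KS
check, and ≤ 12×12 instances for the literal index-enumeration equalities —
sizes at which every comparison has well-defined Monte Carlo tolerances
(three binomial standard errors, or four standard errors of a difference of
means) while the whole suite completes in a few minutes.

## Known limitations

* The F test's exactness rests on multivariate normality with a *common*
  covariance; it is undefined for unequal class covariances and only
  applies to linear discriminants.
* The LR/Wald implementations target ML logistic regression; no penalized,
  exact, or score-test variants.
* The AUC comparison offers no partial-AUC, ROC-curve confidence bands, or
  bootstrap variance.
* The unbiased variance estimator can be negative for very small test sets;
  the z test then degenerates (flagged, `p = 1`) rather than reporting an
  imaginary standard error.
* Single-threaded by design; the default 20,000-trial studies take minutes
  on one core.
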