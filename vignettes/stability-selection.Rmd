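---
title: "Bootstrap-stable edge selection for connectome-based prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bootstrap-stable edge selection for connectome-based prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Predicting a continuous phenotype (say, a cognitive test score) from
resting-state functional connectivity is a many-features/few-subjects
problem: a 300-node parcellation yields 44,850 edges per subject, while
cohorts rarely exceed a thousand subjects. The standard first step is mass
univariate screening — keep every edge whose Spearman correlation with the
trait is significant at p < .05 — followed by a regression model on the
surviving edges. At these sample sizes the screen is noisy twice over: it
admits roughly `alpha` times the number of null edges by chance, and the
set it selects changes substantially under small perturbations of the
cohort (outlier subjects, heteroscedastic noise, sampling variability).

`stableconn` implements a stability-filtered version of that screen. The
screen is repeated over `NB` resampled subject sets and an edge survives
only if it is significant — with a consistent sign — in at least a fraction
`FP` (frequency percentage) of the resamples. Two resampling schemes are
supported:

* **without replacement**: each resample draws `floor(BP * n)` distinct
  subjects (`BP`, the bootstrap percentage, is a third tunable);
* **with replacement**: classic bootstrap resamples of size `n`;
  duplicated subjects enter the Spearman screen as genuine repeated
  observations (midranks absorb the induced ties).

The surviving edges are split by correlation sign into positive, negative
and combined sets, which feed four predictors: CPM-P and CPM-N
(connectome-based predictive modelling on the positive and negative sets:
sum the selected edge weights per subject, then univariate least squares of
the trait on that network-strength score), and linear epsilon-SVR, LASSO
and ridge regression on the combined set.

## Evaluation protocol

Everything is evaluated inside a nested cross-validation designed so that
all selection methods are compared on identical partitions:

* **Sorted round-robin outer folds.** Subjects are sorted by trait value
  and dealt into k = 10 folds cyclically (1st, 11th, 21st, ... subject to
  fold 1, and so on). The partition is deterministic, every fold spans the
  trait range, and fold sizes differ by at most one. Ties in the trait are
  broken by input order.
* **Per-fold selection.** Feature selection (baseline screen or
  bootstrap-stability filter) sees only the nine training folds. The
  held-out fold's labels influence nothing upstream of prediction; the test
  suite verifies this by permuting held-out labels and asserting
  bit-identical selections and hyperparameters.
* **Inner tuning.** C (SVR) is tuned over 2^-5 ... 2^10 and lambda
  (LASSO/ridge) over 2^-10 ... 2^5 by an inner 5-fold CV on the training
  folds, built with the same sorted round-robin scheme. The selection
  criterion is the mean inner-fold Pearson R, consistent with the outer
  criterion; ties prefer the simpler model (smaller C, larger lambda). CPM
  has no hyperparameters.
* **Metrics.** Per fold, Pearson R and MSE between predicted and observed
  trait values, averaged over folds. A fold whose needed feature set is
  empty (or whose CPM summary is constant) is excluded from the averages
  and reported as failed rather than imputed. A constant prediction vector
  scores R = 0 and is flagged.
* **Grid search.** The full parameter grid is NB in {10, 20, 50, 100, 500,
  1000} and FP in {50, ..., 100%}, plus BP in {25, 50, 60, 70, 80%} without
  replacement: 180 + 36 = 216 configurations. The configuration with the
  largest fold-averaged R wins; exact ties break toward smallest NB, then
  largest FP, then smallest BP (cheapest, most stringent). Within a fold,
  resample b is shared across the whole grid — per-resample RNG streams are
  derived from (seed, fold, b) — so frequencies are counted once per BP and
  snapshot at every NB, and identical feature sets reuse cached model fits.
* **External validation.** For discovery-to-validation transfer, features
  are selected and hyperparameters tuned on the whole discovery cohort
  (inner 5-fold on all discovery subjects — the natural extension of the
  in-sample protocol), the model is fitted once, and applied to the held-out
  cohort; a predefined shortlist of eight configurations (NB {50, 100} x BP
  {0.7, 0.8} x FP {0.8, 0.9}) is evaluated and averaged.

## Statistical and numerical choices

**Spearman p-values.** Two-sided, from t = rho * sqrt((n-2)/(1-rho^2)) on
n - 2 degrees of freedom. At screening sample sizes (n over a hundred) the
approximation is indistinguishable from a permutation test at the coarse
.05 threshold; the test suite keeps a 10^6-shuffle permutation oracle that
agrees within 0.005 at n = 30. Significance is strict (p < alpha), and no
multiplicity correction is applied at the screen — the stability filter,
not a stringent threshold, is the guard against false edges. Zero-variance
edges are kept (rho defined as 0, p = 1) so feature indices remain stable
across folds and files.

**Frequency thresholding.** The FP comparison is inclusive (frequency >=
FP): the grid contains FP = 100%, which would be unsatisfiable under a
strict inequality. Sign-specific counters are kept separately; an edge that
flips sign across resamples accrues to both counters and neither may reach
a high FP, preserving the CPM positive/negative semantics. Resample size is
floor(BP * n) — deterministic and never exceeding n.

**Edge ranks inside resamples.** Each training matrix's columns are sorted
once; a resample's midranks are then obtained by a linear scan of the
sorted order with subject multiplicities, and significance is tested as
|rho| > r_crit(alpha, m), the exact critical value of the two-sided t
screen. This is algebraically identical to re-running the full screen on
the resampled rows (a test asserts exact agreement) at a fraction of the
cost.

**Ridge.** Solved exactly by the penalized normal equations (Cholesky) on
training-standardized features with an unpenalized intercept, minimizing
RSS + lambda * sum(beta^2). The test suite checks agreement to 1e-8 with an
independent augmented-QR oracle, and at lambda = 0 with OLS. (Path solvers
converge only to ~1e-4 relative accuracy here, so the closed form is both
faster and exact.)

**LASSO.** glmnet, with the objective mapped exactly: minimizing
RSS + lambda * sum|beta| corresponds to glmnet's lambda of
lambda / (2n). Single-edge feature sets use the univariate soft-threshold
closed form. The large-lambda limit (all coefficients zero, intercept =
mean(y)) and sparsity monotonicity over the grid are asserted in tests.

**Linear SVR.** The epsilon-insensitive objective
0.5 * ||beta||^2 + C * sum(xi + xi') is solved by dual coordinate descent
(the liblinear algorithm for L1-loss SVR) with a deterministically shuffled
update order, so fits are bit-reproducible. The intercept rides on an
appended constant feature; because the target is centered and standardized
before fitting, its ridge term is negligible. epsilon is fixed at 0.1 on
the standardized target (configurable); only C is tuned. During inner
tuning the whole ascending C path is solved with warm starts at tolerance
0.05 (150 epochs cap); chosen models are refit at tolerance 1e-3 (1000
epochs). On representative folds the looser tuning solve leaves the chosen
C and the inner R-curves unchanged to about 3e-3 while cutting tuning time
about six-fold. Agreement with libsvm (e1071) at moderate C, where libsvm
converges, is asserted in tests.

**Standardization.** SVR/LASSO/ridge operate on features standardized with
training-fold statistics (penalized objectives are scale-sensitive); CPM
uses raw edge weights, and its summary is the sum (not the mean — the two
differ by a factor the regression slope absorbs). Stored coefficients are
always mapped back to the raw edge scale, so prediction is plainly affine.

**Reproducibility.** Every stochastic step draws from a stream derived
from (seed, fold, resample-index). Identical inputs and seeds give
bit-identical selections, frequencies and predictions; growing NB extends
rather than reshuffles the resample sequence; and a single-configuration
run reproduces the matching grid-search cell exactly.

## The synthetic generator

Real HCP-style connectome data are access-restricted, so the package ships
a generator that emulates their statistical shape with known ground truth:
subjects-by-edges matrices of iid Normal(0, 0.3) Fisher-z-like weights
(optionally with equicorrelated blocks of 10 edges at rho 0.3, for studying
LASSO's behavior under correlated features), a trait that is a sparse
linear function of a small planted edge set plus Gaussian noise, and two
contamination mechanisms that are on by default: 5% outlier subjects whose
edge weights are heavy-tailed (t with 2 df, scaled 3x), and trait noise
whose standard deviation grows with the subject's standardized signal
level, noise_sd * (1 + |z|).

The default effect structure was set by a power analysis, not by fitting to
any test outcome, and is worth spelling out because it is constrained in a
non-obvious way. With k independent planted edges of equal strength, no
single edge's marginal correlation with the trait can exceed 1/sqrt(k)
regardless of the noise level — the other signal edges act as noise for the
marginal screen. A generator with many weak planted edges therefore forces
a choice between an unrecoverable planted set and a nearly noise-free
trait; in the latter regime penalized baseline models saturate and
stability filtering has nothing to offer, which does not resemble the weak
signal regime of real connectome-trait data. The defaults — 300 subjects,
60 nodes (1770 edges), 10 planted edges at |beta| = 0.15 (half positive,
half negative), noise_sd = 0.12 — give each planted edge a marginal
correlation near 0.24: screen power ~0.99 at the full sample but only
~0.6-0.8 at the subsample sizes the stability filter uses, so single-screen
selections fluctuate while resampling frequencies separate planted from
null edges; the planted set explains ~58% of trait variance before
contamination, less after.

What the generator does *not* emulate: realistic network covariance among
edges (beyond the optional block knob), site or motion artifacts,
non-Gaussian marginals of real Fisher-z weights, and any spatial structure
over nodes. Passing tests demonstrate the machinery and the direction of
the stability-selection effect under controlled contamination — not effect
sizes on real cohorts.

## Problem sizes in the test suite

The suite exercises the full default generator (300 x 1770) for screening
and selection properties, and a reduced grid ({NB 50, 100} x {BP 0.5, 0.7}
x {FP 0.7, 0.8}, 10 seeds) for the headline comparison of best-bootstrap
versus baseline across all five models — sizes chosen so the whole suite
runs on a single CPU in well under half an hour while keeping every
qualitative property at realistic dimensionality.

## Known limitations

* The bootstrap advantage is a statistical tendency, not a guarantee; on
  individual draws (especially clean, strong-signal ones) the baseline
  screen with a well-regularized model can match or beat it. The effect is
  weakest for LASSO, which embeds its own L1 selection and therefore
  tolerates false screen survivors while losing usable edges to an external
  stability filter — in the package's contaminated synthetic experiments
  LASSO is the one model where the baseline screen often remains
  competitive, and the original application likewise reports its smallest
  relative gain for LASSO.
* p-values use the t approximation throughout; for n below ~20 with heavy
  ties an exact method would differ.
* CPM is implemented in the paper-faithful two-model form (CPM-P, CPM-N);
  the two-term combined CPM variant found elsewhere in the literature is
  out of scope.
* Covariate adjustment (age, motion), alternative screens (Pearson,
  partial correlation) and stability-selection error-control bounds are
  not implemented.
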