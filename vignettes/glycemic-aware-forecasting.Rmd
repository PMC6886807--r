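---
title: "Glycemic-aware evaluation and oversampling for blood glucose forecasting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glycemic-aware evaluation and oversampling for blood glucose forecasting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoregress)
```

## The problem

A continuous glucose monitor (CGM) reports interstitial glucose roughly
every five minutes. Short-horizon forecasting — predicting the glucose
level 30 minutes ahead from the recent trace — is the computational core
of hypoglycemia alarms and artificial-pancreas controllers. Two
properties of real CGM data shape everything this package does:

1. **Range imbalance.** People with type 1 diabetes spend most of their
   time in the normal range (70–180 mg/dl), a substantial fraction in
   hyperglycemia (> 180 mg/dl) and only a few percent in hypoglycemia
   (< 70 mg/dl). A model selected on overall accuracy can therefore be
   arbitrarily poor exactly where alerts matter most.
2. **Gaps.** Sensor replacement and missed scans leave holes in the
   trace. Imputing across them (smoothing, last-value-carried-forward)
   risks leaking future information or inventing dynamics, so this
   package discards any prediction window that spans a gap instead of
   imputing.

## The prediction task

`build_windows()` slides a window of 24 consecutive readings (120
minutes) along a trace; the regression target is the reading 6 steps
(30 minutes) after the window end. A window is emitted only when all 30
readings are consecutive within the spacing tolerance — a gap inside
the window *or* between window end and target discards the candidate,
because an unverifiable target timestamp is as bad as a missing
feature. The stride is one reading, which maximizes training data; the
window and horizon lengths are parameters, but their defaults are the
task definition.

Two readings are "consecutive" when their spacing is within the nominal
interval ± a 60 s jitter tolerance. Real CGM clocks drift; the
tolerance is configurable per trace and 60 s is a deliberately
permissive default for 5-minute hardware.

## Metrics: MARD by range and the Clarke grid

The headline metric is the mean absolute relative difference,

$$\mathrm{MARD} = \frac{100}{N}\sum_{t=1}^{N}
  \frac{|\hat{y}_t - y_t|}{y_t},$$

with the observed value in the denominator, so equal absolute errors
cost more in the hypoglycemic range. `mard_by_range()` partitions the
pairs by the *ground truth*: hypo (< 70), normal (70–180 inclusive) and
hyper (> 180). The boundary values 70 and 180 count as normal —
"hypoglycemic" means strictly below 70 throughout. The per-range values
recompose exactly: $N \cdot \mathrm{MARD}_{all} = \sum_C N_C \cdot
\mathrm{MARD}_C$. A range with no test pairs is reported as `NA`, never
as zero: a model that was never evaluated somewhere has no accuracy
there, and treating it as perfect would resurrect exactly the
trivial-baseline artifact the range-partitioned analysis exists to
expose.

`ega_zone()` implements Clarke error grid analysis. The grid is
published as a figure, not as formulas, so this package fixes the
widely used inequality form and evaluates it with precedence
A, E, C, D, else B:

* **A**: both values below 70, or prediction within 20% of truth;
* **E**: actual ≤ 70 predicted ≥ 180, or actual ≥ 180 predicted ≤ 70;
* **C**: (70 ≤ actual ≤ 290 and predicted ≥ actual + 110) or
  (130 ≤ actual ≤ 180 and predicted ≤ 7/5·actual − 182);
* **D**: (actual ≥ 240 and 70 ≤ predicted ≤ 180) or
  (actual ≤ 175/3 and 70 ≤ predicted ≤ 180) or
  (175/3 ≤ actual ≤ 70 and predicted ≥ 6/5·actual);
* **B**: everything else.

The precedence resolves boundary ties deterministically; the test suite
verifies on the exhaustive 361×361 integer grid that the rules assign
exactly one zone per point and agree with an independently coded
oracle. Note the A-rule's asymmetry: actual 60 / predicted 65 is A, but
actual 65 / predicted 100 is not (it lands in D) — the hypo/hypo clause
applies only when *both* values are below 70.

## Oversampling for regression via pseudolabels

Classification oversamplers need class labels; regression has none. The
bridge is a *pseudolabel*: the target discretized into
hypo / normal / hyper. `oversample()` balances the two minority classes
up to the majority-class size and then the pseudolabels are discarded —
the regressor never sees them.

The key point of the synthetic variants is that they synthesize the
**target along with the features**. For a seed example $x_i$ and a
same-class neighbor $x_j$,

$$x_{new} = x_i + \lambda (x_j - x_i), \qquad \lambda \sim U[0,1],$$

and the target uses the *same* $\lambda$. Because each glycemic class
is an interval and a convex combination of two targets in an interval
stays inside it, the synthetic pseudolabel provably equals its
parents' — the package still asserts this on every synthetic row, and
every row carries provenance (parent indices and $\lambda$) so the
construction is auditable after the fact.

Design choices where the method descriptions are qualitative, following
the original algorithms:

* SMOTE draws the interpolation neighbor from the seed's $k = 5$
  nearest *same-class* neighbors (Euclidean distance on the 24 raw
  mg/dl features, before any scaling); $k$ is reduced to class size − 1
  for very small classes, and a single-member class falls back to
  duplication with a warning.
* ADASYN computes each minority row's difficulty as the fraction of its
  $k$ nearest neighbors *in the full dataset* that carry a different
  pseudolabel, allocates the class deficit proportionally with
  largest-remainder rounding (so allocations sum exactly to the
  deficit; all-zero difficulties fall back to a uniform split), and
  then synthesizes exactly as SMOTE does.
* Oversampling is applied to training data only; the benchmark pipeline
  never touches test windows.

Undersampling the majority class is deliberately not offered: throwing
away most of the normal-range data degrades the regressor everywhere.

## The model registry

`model_registry()` holds ten regressor configurations under one
train/predict contract: a constant-mean dummy baseline, Lasso, linear
SVR, a regression tree, k-NN, an RBF-kernel SVR, one- and
two-hidden-layer perceptrons, a random forest and gradient boosting.
Pinned settings: 5-fold cross-validated L1 penalty for the Lasso;
100,000-iteration caps for the first-order optimizers; 500 trees for
the ensembles; hidden layers of five tanh units trained with ADAM.
Everything else uses conventional defaults recorded in the spec
objects, so a run is reproducible from its seed and registry alone.

Each trained model bundles its own preprocessing: degree-2 polynomial
expansion (`expand_polynomial()`; linear + squares + pairwise products,
324 features from 24) for the two sparse linear models only, then
feature-wise standardization fitted on the training data (population
SD; zero-variance columns divide by 1). The pipeline order —
oversample, then expand, then standardize — is a documented choice:
interpolation is defined on the raw 24 readings, and standardizing last
puts all expanded features on a comparable scale for the L1 penalty.
`glyco_train(standardize_first = TRUE)` flips the expansion/scaling
order for sensitivity checks.

Implementation notes, since the target environment ships no tree, MLP
or SVM regression packages for R: the trees are a compiled
least-squares CART (memorizing distinct rows when grown unpruned, as a
default regression tree should); the forest bags unpruned trees with
per-node feature subsampling (mtry = p/3, following the description of
per-tree random feature subsets rather than the all-features default
some libraries use); boosting fits depth-3 trees to residuals with
shrinkage 0.1; the MLPs are exact tanh networks trained with minibatch
ADAM and early stopping; the linear SVR minimizes the L1-penalized
epsilon-insensitive primal by proximal subgradient descent (the L1
choice is the point of that model — it prunes most of the 324
polynomial features); and the RBF SVR is a reduced-set kernel machine
(random centers, gamma = 1/(p·var), smoothed epsilon-insensitive loss,
L2 penalty) standing in for a full nu-SVR solver — the one deliberate
algorithmic approximation in the registry, acceptable because the model
serves as a benchmark baseline, not as the object of study. k-NN uses
FNN and the Lasso uses glmnet.

## The benchmark harness

`run_grid()` evaluates every model × oversampler × patient cell (10 × 4
× patients; 240 cells for a six-patient cohort). One master seed fans
out to per-cell sub-seeds through a counter scheme, so any cell can be
re-run in isolation and results do not depend on grid iteration order;
per-cell failures are recorded without aborting the grid.

On top of the result table: `rank_combinations()` averages a metric
across patients (lower-better for all MARD variants and EGA zones B–E,
higher-better for zone A; undefined values excluded pairwise with
counts reported; ties ordered stably by name), `rank_matrix()` builds
the within-patient rank matrix, `friedman_rank_test()` applies the
tie-corrected chi-square approximation, `nemenyi_posthoc()` the
studentized-range post-hoc, and `paired_t_metric()` a two-sided paired
t-test with a zero-variance guard (degenerate differences report p = 1
with a warning rather than NaN). Zones C and E are computed but make
poor selection criteria: a constant predictor trivially scores zero in
both, which is why rankings here should lean on MARD by range and zones
A/B/D.

## The synthetic cohort generator

Real benchmark CGM datasets are distribution-restricted, so
`simulate_cohort()` generates traces that reproduce the *statistical
shape* the pipeline assumes: 5-minute sampling, the 40–400 mg/dl sensor
range (values are clipped, mirroring a sensor that saturates rather
than errors), gaps, and the three-regime occupancy histogram. Glucose
is a mean-reverting random walk plus gamma-shaped meal excursions at
Poisson times; a fraction of meal responses is followed by a Gaussian
"overcorrection" dip into hypoglycemia, which is what gives the traces
a realistic hypoglycemic tail. Gaps delete readings outright, with
log-uniform durations between 15 minutes and 8 hours (short
missed-scan holes are common, day-long sensor failures rare).

The defaults (baseline 160 mg/dl, reversion 0.01/min, noise
1.0 mg/dl/√min, 4 meals/day with peaks of 55–175 mg/dl at 60 min,
overcorrection probability 0.40 with 105–140 mg/dl dips at 240 min, 1
gap/day) were calibrated **once** against the published occupancy of
the standard six-patient benchmark — about 3.4% hypoglycemic and 34%
hyperglycemic readings — and then frozen; measured occupancy over ten
seeds is ~3.5% / ~32%. The generator is a stated world, not a tuning
dial: tests assert against it as it is.

What the generator does *not* emulate: sensor error models, insulin and
meal covariates, circadian structure, inter-patient parameter
heterogeneity, or autocorrelated sensor dropout. A green test on
synthetic data therefore establishes that the pipeline's *mechanics*
(windowing, balancing, metric bookkeeping, statistics) behave as
specified and that the imbalance-correction effect has the expected
direction; it does not establish clinical accuracy numbers, which
require real traces.

## Numerical and degenerate-input policy

* Predictions are floored at 1 mg/dl before scoring (relative error
  needs a positive denominator and MARD a positive prediction).
* Empty metric subranges are `NA` and propagate as "undefined", exclude
  themselves from means and tests pairwise, and are counted.
* Rank ties get average ranks; the Friedman statistic uses the standard
  tie correction; an all-tied matrix reports statistic 0, p = 1 with a
  warning.
* Early stopping: the first-order learners stop when their objective
  stops improving (relative tolerances in the registry), so the
  100,000-iteration caps are ceilings, not running times.
* `benchmark_control()` exposes computational caps (iterations, trees,
  kernel centers, training windows per cell) for time-boxed runs. The
  test suite's end-to-end blocks use reduced caps; scale, not
  structure, is what they change.

## Known limitations

* The Clarke grid inequalities are one published formulation of a
  figure-defined standard; boundary pixels differ between published
  implementations, which is why the precedence order is fixed and
  tested rather than assumed.
* The RBF SVR is an approximation (see above), and the exact SVR
  loss/penalty configuration used in the original benchmark is not
  recoverable; the registry documents the interpretation chosen.
* Whether real benchmark preprocessing standardized before or after
  polynomial expansion is unstated; both orders are available, one is
  the default.
* With six patients the Nemenyi post-hoc has very little power at 40
  combinations; an omnibus-significant, post-hoc-inconclusive outcome
  is expected behavior, not a bug.
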