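---
title: "Replicability analysis for multivariate BWAS: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replicability analysis for multivariate BWAS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(bwasrep)
```

## The problem

Multivariate brain-wide association studies (BWAS) train a predictive model
over many brain features jointly — typically vectorized functional-connectivity
edges — and summarise the brain–phenotype association as the Pearson
correlation *r* between model predictions and observed outcomes. Two
methodological choices dominate how replicable such effects look:

1. **How the discovery effect size is estimated.** Evaluating the model on
   the same samples it was trained on (the *in-sample* estimate) inflates *r*
   through overfitting, increasingly so as model flexibility grows relative
   to the sample size. Evaluating on pooled out-of-fold predictions from
   internal cross-validation (the *CV* estimate) removes that bias.
2. **How large the samples are.** Smaller samples do not bias the CV
   estimate, but they widen its sampling distribution, which lowers power,
   lowers the probability that an independent replication succeeds, and
   creates room for selection effects (the winner's curse) to inflate the
   published record.

`bwasrep` implements the machinery to study both choices quantitatively: a
paired discovery/replication bootstrap benchmark, permutation null
distributions for both estimators, analytic Fisher-z power calculations, and
a synthetic-data generator with a *known* population effect size so that
every claim is testable against ground truth.

## The discovery/replication benchmark

For each sample size $n$ in a grid, and for each of $B$ bootstrap
replicates, `run_benchmark()`:

1. draws two **disjoint** subsets of size $n$ without replacement
   (`draw_pair()`): a discovery and a replication sample. Disjointness makes
   the replication half a genuinely independent test of the
   discovery-trained model. Across replicates the subsets are redrawn
   independently (a bootstrap over subsamples);
2. trains the configured model on the full discovery subset and records the
   **in-sample** correlation $r_\text{disc}^\text{in}$ (predict the training
   rows themselves);
3. computes the **CV** correlation $r_\text{disc}^\text{cv}$ from pooled
   out-of-fold predictions of a $k$-fold cross-validation inside the
   discovery subset (default $k = 10$, single repetition; repeated CV is
   available via `cv_predictions(repeats =)`). The correlation is computed
   once over all $n$ pooled predictions rather than averaged across folds —
   the pooled form has lower variance and is standard practice; and
4. applies the single discovery-trained model *unchanged* to the replication
   subset, giving $r_\text{rep}$. We deliberately use the one model refit on
   all discovery rows, not an ensemble of CV fold models, because that is
   what a replication attempt of a published model would do.

`aggregate_benchmark()` reduces the records per grid size to:

* **inflation**: $\mathrm{mean}(r_\text{disc} - r_\text{rep})$ for each
  estimator. The in-sample version is large and positive for flexible
  models; the CV version should be indistinguishable from zero;
* **power**: the fraction of replicates that are *discovery-positive*,
  defined as $p \le \alpha$ **and** $r_\text{disc}^\text{cv} > 0$. A
  significantly negative prediction–outcome correlation is a failed model,
  not a discovery;
* **P~rep~**: among discovery-positive replicates, the fraction whose frozen
  model is also significant and positive in the replication sample. When no
  replicate is discovery-positive this is reported as `NA` with subset size
  0, never as a silent zero;
* **conditional inflation**: the CV inflation averaged only over a
  conditioning subset. The default conditions on discovery significance —
  the standard publication-bias construction: journals see the significant
  discoveries. Conditioning on replication-sample significance, on both, or
  on nothing are available as modes, because the two published descriptions
  of this analysis differ and we implement both rather than resolve the
  discrepancy.

Intervals on all metrics are 2.5/97.5 percentile bootstrap intervals over
replicates. `min_n()` scans the table for the first grid size reaching a
threshold (default 0.8); when none does, it returns an above-grid sentinel
labelled e.g. `">500"` — no interpolation between grid points is attempted.

All randomness is driven by per-replicate seeds derived deterministically
from the master seed and the pair (grid size, replicate index), so results
are independent of execution order and of how many replicates are run;
extending $B$ leaves earlier replicates bit-identical.

## The two prediction pipelines

`model_spec()` declares one of two families commonly compared in
multivariate BWAS:

* **`ridge`** — ridge regression on standardized features with a fixed
  shrinkage penalty $\lambda$ (default 1, the field's customary default for
  partial-correlation connectomes): $\hat\beta = (X^\top X + \lambda
  I)^{-1} X^\top y$ on training-standardized $X$ and centred $y$. The
  solution is computed in closed form, via the primal $p \times p$ system
  when $p \le n$ and the algebraically identical dual $n \times n$ system
  when $p > n$. Note that $\lambda = 1$ is *weak* relative to $X^\top X$
  (whose diagonal is $\approx n$), so at $p \gtrsim n$ this model
  near-interpolates — which is exactly the regime in which in-sample
  estimates become grossly inflated.
* **`pca_svr`** — principal-component reduction fitted on the training
  partition only, retaining the smallest number of components explaining
  `pca_variance_kept` (default 0.95) of the variance, capped at
  $\min(n_\text{train} - 1, 250)$, followed by a linear support-vector
  regression on the scores (cost 1, epsilon 0.1, the library defaults,
  recorded in `glance()`). The kernel is linear because multivariate BWAS
  weight maps are linear readouts; a nonlinear kernel would change the
  method class. The exact component count and SVR settings of published
  PCA+SVR pipelines vary, so numeric parity with any specific study is not
  claimed; the retention rule is exposed in the spec because results depend
  on it.

Both pipelines standardize features with training-partition statistics, and
`cv_predictions()` refits the *entire* pipeline — standardization, component
basis, regressor — inside each training fold. A dedicated test corrupts
held-out outcomes and asserts the out-of-fold predictions are bit-identical,
which is the operational definition of leakage-freedom.

We intentionally fix all hyperparameters rather than tuning them: the
benchmark's point is to measure the behaviour of a fixed, declared pipeline,
and tuning inside the benchmark would reintroduce the optimism the CV
estimate exists to remove.

## Effect-size inference

`prediction_outcome_r()` is a plain Pearson correlation that refuses
constant inputs rather than returning `NA`. Significance uses the exact
t-transform $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom
(`r_p_value()`, two-sided by default; the one-sided version tests $r > 0$),
inverted in closed form by `critical_r()`. Parametric intervals are
Fisher-z: $\tanh(\operatorname{atanh} r \pm z/\sqrt{n-3})$.

The parametric p-value treats the $n$ pooled out-of-fold predictions like an
ordinary bivariate sample. This is the conventional choice, but fold
coupling makes the CV null distribution of $r$ somewhat wider than the
parametric null and slightly negative in the mean (CV is mildly pessimistic,
most visibly at small $n$). The package therefore also provides
`permutation_null()`, which subsamples, permutes outcomes, recomputes the
chosen estimator, and summarises the null with permutation percentiles —
the honest reference distribution when calibration matters. Our own test
suite measures the CV null at $n = 150$, $p = 20$ to have a standard
deviation roughly 1.5 times $1/\sqrt{n}$ with a small negative mean, and the
type-I calibration test accordingly checks the positive-tail rate against a
wide binomial band around $\alpha$ rather than asserting exact parametric
calibration.

## Analytic power

`power_at_n()` and `required_n()` implement the Fisher-z approximation
$\text{power} = \Phi(\operatorname{atanh}(\rho)\sqrt{n-3} - z_{1-\alpha/2})$
and its inversion $n = ((z_{1-\alpha/2}+z_\text{power})/
\operatorname{atanh}\rho)^2 + 3$, refined by direct evaluation so the
returned $n$ is exactly minimal. $\rho^2$ is the fraction of outcome
variance explained: a model explaining 1% of variance corresponds to $\rho =
0.1$ and needs $n = 783$ for 80% power at $\alpha = 0.05$ (two-sided);
$\rho^2 = 0.02$ needs $n = 391$. Published prospective-replication
calculations that condition on a significant discovery give somewhat larger
numbers for the same effect sizes; that calculation is a different estimand,
and the closed form here is the unconditional one. `simulate_power()` is the
Monte-Carlo counterpart used to validate the approximation (the suite checks
agreement within a 99% binomial band at $\rho = 0.2$, $n = 100$, and within
0.02 at $\rho = 0.5$, $n = 50$).

## The synthetic-data generator

`simulate_bwas_data()` generates the structure the analysis assumes, with a
closed-form ground truth:

* **Features**: zero-mean, unit-variance Gaussians in equicorrelated blocks
  (`block_size` = 10 features per block, within-block correlation
  `block_rho` = 0.3 by default), mimicking the redundancy of connectivity
  edges, where edges sharing a node or a network are substantially
  correlated.
* **Signal**: fixed weights on the first `n_signal` features (default
  $p/4$), drawn once per seed from a standard normal and rescaled so the
  latent signal $f = Xw$ has exactly unit population variance under the
  block covariance.
* **Outcome**: $y = \rho_\text{true} f + \sqrt{1-\rho_\text{true}^2}\,
  \varepsilon$, so the population correlation between the best linear
  predictor and $y$ is exactly `rho_true`, returned by
  `population_effect()` as the oracle for parameter-recovery tests.
  `rho_true = 0` yields an outcome independent of all features, and a
  property test confirms the resulting CV-r distribution is
  indistinguishable (two-sample KS) from the permuted-outcome distribution.

The default scale is $n = 1200$, $p = 200$, $\rho_\text{true} = 0.3$: large
enough that disjoint pairs up to $n = 500$ per half are feasible and that
$p/n$ sits in the regime where in-sample inflation is dramatic but CV
estimation is stable, while keeping a full benchmark run in minutes on one
CPU. High-dimensional behaviour ($p \gg n$) is exercised separately at $p =
2000$, $n = 200$.

A useful closed-form companion for interpreting results: a weakly penalized
(near-OLS) linear model at true effect $\rho$ attains out-of-sample
correlation approximately $\rho/\sqrt{1 + (p/n)(1-\rho^2)/\rho^2}$. At $p =
200$, $n \approx 1100$, $\rho = 0.3$ this is $\approx 0.18$ — the CV and
replication estimates agree with each other (unbiasedness) but both sit
below $\rho_\text{true}$ because shrinkage 1 leaves estimation noise in 200
coordinates. Unbiasedness here means CV estimates the *deployable* effect
size of the fitted model, not the oracle effect size of the best possible
model.

What the generator does **not** emulate: heavy-tailed or heteroscedastic
features, site/scanner structure, measurement unreliability of phenotypes,
motion confounds, or spatial structure beyond block correlation. Passing
tests on this generator demonstrate the *mechanics* — CV unbiasedness,
overfitting bias, winner's-curse direction, power scaling — not
dataset-specific effect sizes or minimal sample sizes of any real cohort.

`generate_node_timeseries()` complements this with a timeseries-level
fixture: samples from a multivariate Gaussian with a random sparse,
diagonally dominant (hence positive-definite) precision matrix, returned
together with the implied true partial-correlation matrix, so the
`partial_correlation_matrix()` → `vectorize_edges()` feature pipeline can be
tested for consistency against ground truth.

## Numerical choices

* Ridge is solved exactly (Cholesky-backed `solve` of the primal or dual
  system); the two branches are tested against each other and against an
  independent coordinate-descent implementation.
* PCA uses the smaller of the $p \times p$ or $n \times n$ eigenproblems;
  components with eigenvalues below $10^{-12}$ of the largest are dropped.
* The SVR optimizer's termination tolerance defaults to 0.01 (the library
  default is 0.001). Near the interpolation regime this is severalfold
  faster while changing predictions only in the fourth decimal; it is a
  `model_spec` field and is recorded in fitted-model metadata.
* Constant outcomes (possible in tiny subsamples of discrete phenotypes)
  abort a fit with a typed error; the benchmark excludes such replicates,
  logs the count, and aborts if more than 10% of replicates are invalid.
* Constant features receive a standardization scale of 1 (they contribute
  nothing after centring).
* CV fold sizes differ by at most one; assignment is a seeded shuffle.
* Negative CV correlations are reported as computed, never truncated at
  zero, so inflation statistics stay unbiased.
* `permutation_null()` requires at least 20 permutations and uses 2.5/97.5
  percentiles, not a normal approximation.

## Problem sizes used by the test suite

The suite's end-to-end statistical checks run at: the headline benchmark
($\rho_\text{true} = 0.3$, $p = 200$, $n_\text{full} = 1200$, $B = 100$ at
$n \in \{50, 200\}$, ridge); permutation nulls at $n = 200$, $p = 2000$
with 100 permutations (in-sample for both model families; CV for ridge —
the point of the CV half is estimator unbiasedness, which is
model-agnostic, and the linear-SVR optimizer makes a 1000-fit CV null at
this size disproportionately expensive); type-I calibration at
$\rho_\text{true} = 0$, $B = 200$, $n = 100$; and $10^4$ Monte-Carlo draws
for the analytic-power check. These sizes were chosen so the full suite
completes in minutes while keeping Monte-Carlo error well inside the
asserted tolerances.

## Known limitations

* The parametric p-value for CV estimates inherits the mild miscalibration
  discussed above; use permutation p-values when exact type-I control at
  small $n$ matters.
* `P_rep` is a per-study quantity conditioned on the benchmark's own
  discovery rule; it is not a posterior replication probability.
* The generator's linear-Gaussian design is deliberately the best case for
  both pipelines; real connectome data will generally show smaller effects
  and heavier tails.
* Execution is serial; the seed-derivation contract makes replicates
  embarrassingly parallel, but no parallel backend is wired in.
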