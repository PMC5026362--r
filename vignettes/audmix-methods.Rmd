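---
title: "Latent-cluster regression for longitudinal audiogram prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-cluster regression for longitudinal audiogram prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Audiograms record the softest stimulus level (the *threshold*, in dB) a
patient detects at a test frequency; higher thresholds mean worse hearing.
In longitudinal hearing-loss data each ear of each patient at each test
frequency — a *patient-ear-frequency* unit, PEF — forms its own short series
of tests (here 4–21 tests, typically about 6), because hearing can change
independently across ears and frequencies.

Predicting a threshold is not one task but three, and they stress a model
differently:

1. **Imputation** — fill in randomly missing tests of series the model has
   already seen;
2. **Forecasting** — extrapolate a known series one test into its future;
3. **New-patient generalization** — predict every test of a series the
   model has *never* seen, without retraining.

The further a task moves from "predict more of the same", the more it is
exposed to *concept drift*: between individuals (different PEFs follow
different threshold-age relationships) and within an individual (a PEF's
own pattern changes over the forecast horizon). `audmix` implements three
regression predictors spanning the classic bias–flexibility range for this
setting and the simulation machinery to compare them per task.

## The three predictors

All three share one regression form for the threshold $t_{ij}$ of PEF $i$
at test $j$, with covariate row
$x_{ij} = (1,\ \log \mathrm{age}_{ij},\ \mathrm{gender}_i,\ \log(\mathrm{diag}_{ij}+1))$:

**Pooled OLS.**  $t_{ij} \sim N(\beta^\top x_{ij}, \sigma^2)$: a single
population pattern; every PEF is predicted by the same coefficients.

**Linear mixed effects.**
$t_{ij} \sim N((\beta + b_i)^\top x_{ij}, \sigma^2)$ with PEF-level
deviations $b_i \sim N(0, \Sigma)$ — a random intercept and random slopes
for all predictors, estimated by REML (`lme4`).  Predictions for a PEF seen
in training add its estimated deviation (BLUP); for an unseen PEF the model
can only fall back to the fixed effects $\beta^\top x$, which is the crux
of the new-patient task.

**Grouped mixture of regressions.**  $K$ latent clusters share the
regression form but differ in coefficients and noise:
$t_{ij} \mid z_i = k \sim N(\beta_k^\top x_{ij}, \sigma_k^2)$, with
$z_i \sim \mathrm{Multinomial}(\pi)$ and the *grouping constraint* that all
tests of one PEF share one cluster $z_i$.  Prediction weights each
cluster's line by the PEF's posterior membership
$\hat t = \sum_k p(z_i = k \mid \text{PEF } i)\, \beta_k^\top x$, and for a
*new* PEF the posterior comes from Bayes rule on whatever observations are
supplied, $p(z_i = k \mid y_{i1..in}) \propto \pi_k \prod_j
N(y_{ij};\, \beta_k^\top x_{ij}, \sigma_k^2)$ — no parameter is updated, so
generalization needs no retraining.

The scientific intuition: the mixed model adapts to *each* individual but
owns no mechanism for individuals it has not seen; the mixture compresses
between-individual variation into a small set of shared patterns that a
new individual can be matched against.  On cohorts whose variation really
is cluster-shaped, the mixture should hold its accuracy in the new-patient
task while the mixed model collapses to OLS-level error; on cohorts with
continuous individual variation the mixed model leads and the mixture
approaches it from below as $K$ grows.

## EM estimation under the grouping constraint

`fit_mixture()` maximizes the observed-data likelihood by EM at the PEF
level:

* **E-step**: responsibilities
  $r_{ik} \propto \pi_k \exp(\ell_{ik})$ with
  $\ell_{ik} = \sum_j \log N(y_{ij};\, \beta_k^\top x_{ij}, \sigma_k^2)$ —
  a PEF's rows enter jointly, never individually.  Normalization is done
  in log space (log-sum-exp), so long series with tiny joint densities
  never underflow to a division by zero.
* **M-step**: each $\beta_k$ solves a weighted least squares in which
  every row of PEF $i$ carries weight $r_{ik}$;
  $\sigma_k^2$ is the responsibility-weighted mean squared residual;
  $\pi_k$ is the PEF-level mean responsibility (one multinomial draw per
  PEF, not per row — mixing proportions describe PEFs, not tests).

**Initialization.**  One informed start hard-assigns PEFs by k-means on
two per-PEF trajectory summaries (mean residual from the pooled fit and a
crude threshold-vs-log-age slope), followed by `n_starts - 1` random
PEF-level responsibility draws from a symmetric Dirichlet(1); the start
with the best final log-likelihood wins.  The informed start matters:
with purely random soft starts the first M-step makes every cluster
nearly the pooled fit, and EM then breaks symmetry along whichever axis
fluctuates first — on cluster-structured cohorts it regularly settled on
a gender-split solution whose log-likelihood is strictly below the
trajectory-split optimum.  Seeding along the trajectory axes (the same
practice used when initializing latent growth mixtures) removes that
failure mode while the random starts still probe alternative basins.

**Convergence and safeguards.**  Absolute log-likelihood change below
`tol = 1e-6` (cap `max_iter = 500`); the trace is returned and is
non-decreasing up to 1e-8 slack, which the tests assert on random
cohorts.  Cluster variances are floored at `1e-4` dB² to block degenerate
spikes (clamping is recorded).  A cluster whose weighted design becomes
singular mid-run (e.g. it collapses onto single-gender PEFs) abandons
that start's refinement but keeps its last valid state; a singular
initial M-step discards the start and redraws.  Non-convergence is
reported in the trace, never thrown.

**Pruning and labels.**  At convergence, clusters holding fewer than 1%
of PEFs by modal assignment (`prune_threshold = 0.01`) are removed and the
E-step re-run — vanishing clusters are an overfitting signature, not
signal.  Clusters are reported sorted by descending log-age coefficient,
so "cluster 1" is always the fastest-progressing pattern and labels are
comparable across fits.  `k = 1` bypasses EM and returns the pooled OLS
solution exactly, which the task harness relies on (the mixture's MSE
curve starts exactly at the OLS level).

**Choosing K.**  `select_k()` grows $k$ until held-out MSE improvement
over $k-1$ drops below `improvement_tol = 0.01` (relative) or pruning
fires, and returns the previous $k$ plus the whole MSE-vs-k table.  This
is deliberately a prediction-accuracy criterion, not BIC: the models are
compared as predictors, and the plateau of the held-out curve is the
quantity of interest.

**Coefficient standard errors** come from the weighted-least-squares
information matrix per cluster.  They ignore membership uncertainty and
are therefore mildly optimistic; they are reporting aids, not inference
machinery.

## Prediction protocols

* **Known PEF** (imputation, forecasting): the posterior is the PEF's
  training responsibility vector, taken at convergence — the model
  "retrieves" what it already inferred.  It is not re-evaluated on
  train+test rows.
* **New PEF** (generalization): the posterior comes from
  `infer_membership()` on conditioning rows of the same PEF.  Which rows
  may condition the prediction of row $j$ is a genuinely open protocol
  choice, so all three options are shipped in `predict_for_task()`:
  `"loo"` (default) conditions on the PEF's *other* rows, never the
  target itself; `"all"` uses all rows including the target; `"prefix"`
  uses only rows earlier in age, the strictly sequential reading.  The
  default avoids predicting an observation from itself while still using
  the full series, which is the fairest reading of "the new patient's
  data is supplied as input but never updates the coefficients".  With
  zero conditioning rows the posterior is the mixing prior and the
  prediction is flagged.
* The no-retraining contract is concrete: serialized model bytes are
  asserted identical before and after any prediction pass.

## Task construction and scoring

* **Imputation**: each PEF's rows are randomly split into 4 bins with
  sizes differing by at most one (larger bins first in permutation
  order); each bin is the "missing" set exactly once, models are retrained
  per rotation, and the score is the unweighted mean of the per-fold MSEs.
  The ≥4-tests inclusion rule exists precisely so every bin is non-empty.
* **Forecasting**: each PEF's maximal-age row is withheld (age ties:
  last stable position); the horizon — years since the previous test —
  is kept per PEF.  The *error-gap regression*
  $|e^{\text{mixed}}_i| - |e^{\text{mixture}}_i| \sim \text{horizon}_i +
  t^{\text{obs}}_i$ then asks whether the mixed model's error grows
  faster with forecast distance; a positive horizon coefficient is the
  within-individual-drift signature.
* **New patient**: whole PEFs are sampled without replacement until their
  rows reach the target test fraction (default 0.22); the split is at PEF
  level, and the tests assert zero leakage into any training structure
  (responsibilities, BLUPs).
* MSE follows the per-fold-then-average definition; its square root is
  the average dB margin of error.

## Cohort filtering

Six criteria: documented ear; bone conduction only (air conduction mixes
in middle-ear pathology); frequencies 500/1000/2000/4000 Hz; zero
thresholds dropped as failed test attempts; PEFs with fewer than 4
surviving tests removed whole; ages restricted to the pediatric 0–21
range with a one-week lower floor because a zero age has no log
transform.  Application order is 1, 2, 3, 4, 6, 5: the minimum-test-count
rule runs last so it counts tests that survive every record-level
criterion — otherwise an age-filtered row could leave a "kept" PEF with
three tests and break the fold construction.  Removal counts are reported
per criterion regardless of order, and filtering is idempotent.

`log(diagnoses)` is implemented as `log(count + 1)`: zero cumulative
diagnoses are common, and the shifted transform keeps zero mapped to zero
while preserving monotonicity.  Natural logs throughout; any other base
would only rescale slopes.

## The synthetic cohort generator

Real audiogram extracts of this kind come from clinical databases that
cannot be redistributed, so every experiment here runs on synthetic
cohorts with known ground truth.  The generator emulates the *statistical
skeleton* of such data:

| parameter | default | meaning |
|---|---|---|
| `n_pefs` | 1000 | PEF series (the study-scale cohort is order 10³) |
| `tests_per_pef` | 4–21 | per-series test count, `4 + Poisson(2)` truncated — mean ≈ 6 |
| `age_range` | 0.5–21 y | test ages: sorted uniform draws per PEF |
| `k_true`, `cluster_betas` | 3 clusters | intercepts 60/35/12 dB, log-age slopes 3/1/−1.5, gender offsets −18/8/0, diag slopes 0.4/0.5/0.2 |
| `cluster_sigmas` | 5 dB | residual SD per cluster |
| `random_effect_sd` | 0 | per-coefficient SD of PEF-level deviations |
| `drift_rate` | 0 | dB per horizon-year added to the final observation's mean |
| `contamination_rate` | 0 | fraction of records violating one inclusion criterion each |

Cluster magnitudes sit where fitted pediatric audiogram clusters land
(intercepts roughly 10–65 dB, log-age slopes roughly ±3, mixed-sign
gender offsets, small positive diagnosis effects).  Gender is
Bernoulli(0.5) per patient and shared across the patient's PEFs; the
cumulative diagnosis count is a non-decreasing Poisson(0.5)-increment
path from zero; patients own 1–4 PEFs drawn from the 2-ear × 4-frequency
grid.  Drift is applied to the final observation only, matching the
forecast design that withholds exactly that observation — with
between-individual spread present, drift makes the individual-tracking
model's error grow faster in the horizon, which is what the error-gap
regression detects.  Identical configuration and seed give byte-identical
output.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: audiometric quantization (real thresholds come
in 5 dB steps), floor/ceiling effects of the audiometer range,
informative visit timing (sick children are tested more often),
measurement error correlated across frequencies of one session, cochlear
implants, or any causal structure linking diagnoses to thresholds.
Conclusions here are about the *mechanics* of the three predictors under
known cluster/random-effect/drift structure, not about clinical hearing
trajectories.

## Numerical and design choices, collected

* Log-space posterior arithmetic everywhere a product of densities
  appears (E-step, membership inference).
* EM: `tol = 1e-6` on absolute log-likelihood change, `max_iter = 500`,
  `n_starts = 5` (one k-means-informed + four Dirichlet random),
  variance floor `1e-4` dB², pruning threshold 1% of PEFs.
* Mixed model: unstructured 4×4 random-effect covariance first (the
  "slopes for all predictors" reading); singular or failed fits fall back
  to a random intercept only, flagged.  Singularity is routine here since
  gender is constant within a PEF, making its random slope collinear with
  the intercept.
* Age ties within a PEF keep input order (stable sorts), so fold
  construction is deterministic under a seed.
* Shared mixing prior $\pi$ with PEF-specific posteriors: the membership
  prior is a population quantity; per-PEF information enters through the
  likelihood.
* Cluster predictions condition on the full covariate row (age, gender,
  diagnoses), not age alone.
* Test problem sizes are the package's own choices: recovery and
  mechanics checks run at 40–500 PEFs; the error-gap power analysis runs
  at 800 PEFs, the study-scale order of magnitude at which the horizon
  effect is reliably detectable.

## Known limitations

* $K$ is fixed after selection; a genuinely novel hearing pattern in a
  new patient is forced into an existing cluster (no novel-cluster
  discovery at prediction time).  Infinite-mixture extensions are out of
  scope.
* Cluster coefficient standard errors ignore membership uncertainty.
* The membership posterior for known PEFs is frozen at training
  convergence; a deployment that accumulates new tests for known patients
  would want to re-run Bayes-rule inference on the extended series.
* The per-cluster coefficient estimates carry the ordinary sampling
  variability of weighted least squares; with 5 dB residual noise and a
  few hundred PEFs per cluster, intercept-scale entries are only
  estimable to a few tenths of a dB, and no estimator can do better than
  the per-cluster information limit.
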