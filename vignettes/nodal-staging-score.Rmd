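---
title: "Methods: a beta-binomial nodal staging score for GSRCC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a beta-binomial nodal staging score for GSRCC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodalstaging)
```

## The problem

Pathological nodal staging in gastric signet ring cell carcinoma classifies
a patient pN0 when every examined lymph node is negative.  With few nodes
examined that classification is unreliable: a truly diseased patient can
show an all-negative exam.  This package models that failure mode and
quantifies, per T stage and examined-node count, the confidence one may
place in a negative nodal exam.

## Model and assumptions

For a truly node-diseased patient of stage $T$, each examined node is
positive with a patient-specific propensity $p \sim \mathrm{Beta}(\alpha_T,
\beta_T)$, and the count of positive nodes among $n$ examined is
$\mathrm{Binomial}(n, p)$.  Marginally the count is beta-binomial.  Three
working assumptions underpin everything: no false-positive nodes (a
pathologically positive node is trusted); examined nodes are exchangeable
(no station or sequence structure); and sensitivity is identical for
detected and missed disease.  Under these,

$$\Pr(\mathrm{FN} \mid n, T) \;=\;
  \frac{B(\alpha_T, \beta_T + n)}{B(\alpha_T, \beta_T)}$$

is the probability that a diseased patient shows zero positive nodes.  It
equals 1 at $n = 0$, decreases strictly in $n$, and decays like
$n^{-\alpha_T}$ — so small $\alpha_T$ (as in early T stages) means the miss
probability falls off very slowly.

### Fitting

$(\alpha_T, \beta_T)$ are estimated per stage, independently (no shrinkage
across stages), from the node-positive patients.  Because the fitting
sample is *defined* by $k \ge 1$, the default likelihood conditions on it —
the zero-truncated beta-binomial likelihood.  An untruncated variant
(`truncated = FALSE`) is available for sensitivity analysis; fitting
untruncated on a $k \ge 1$ sample overstates $\alpha$.  Optimization is
Nelder–Mead on $(\log\alpha, \log\beta)$ (unconstrained, positivity by
construction), started at method-of-moments values plus four jittered
restarts under a fixed internal seed; observations are aggregated to unique
$(n, k)$ pairs first.  Estimates drifting past $10^6$ or below $10^{-8}$
are flagged degenerate — in particular, a sample in which every patient has
$k = n$ pushes $\alpha \to \infty$ and is reported as a boundary case
rather than a number.

All beta-function ratios are computed as log-gamma differences; the
equivalent running product $\prod_{k=0}^{n-1} (\beta+k)/(\alpha+\beta+k)$
and direct numerical integration of $\int (1-p)^n \,
\mathrm{dBeta}(p;\alpha,\beta)$ serve as independent cross-checks in the
test suite, never as the production path.

### Prevalence adjustment

Within each (stage, examined-count) stratum, with $\#TP$ observed
node-positive patients and miss probability $q$, the expected number of
diseased patients hiding among the observed negatives is $q \cdot \#TP /
(1 - q)$.  Two interpretation choices are deliberate:

* **Re-labelling, not creation.**  Imputed false negatives are moved from
  the observed-negative pool into the diseased pool; the stage denominator
  stays the total patient count.  The alternative reading — adding FN as
  new patients to the denominator — would make "all patients" inconsistent
  with the data and is rejected.
* **Capping.**  The imputed $\#FN$ is capped at the stratum's observed
  negative count (imputed patients must physically exist), with one
  summarized warning per stage when the cap binds.  The cap binds routinely
  in sparse strata (one node-positive patient, zero negatives) and keeps
  the adjusted prevalence inside $[\text{apparent}, 1]$.

Strata are distinct observed values of the examined-node count — no
binning.

### The score

$$\mathrm{NSS}(n, T) \;=\; \frac{1 - \mathrm{Prev}_T}
  {(1 - \mathrm{Prev}_T) + \mathrm{Prev}_T \cdot \Pr(\mathrm{FN} \mid n, T)}$$

is the posterior probability that an all-negative exam of $n$ nodes
reflects true absence of disease.  When $\Pr(\mathrm{FN}) = 0$ the score is
defined as 1 for every prevalence, which also resolves the $0/0$ corner at
$\mathrm{Prev} = 1$.  The prevalence entering the score is a parameter
(`prevalence_source`): the FN-adjusted value by default, the apparent value
as an option — reported analyses should state which is used, since the two
differ materially in advanced stages.

Every patient of a stage receives a score as a function of
$(T, n)$ — including node-positive patients, for whom the score is a
counterfactual "had the exam been negative" quantity; restricting scoring
to node-negative patients is a documented alternative the quantile grouping
supports by subsetting beforehand.

### Quantile groups

Within each stage, patients are split at the stage's empirical 25/50/75
percentiles of the score (type-7 linear interpolation between order
statistics), with half-open intervals $[\text{low}, \text{high})$ and the
top group closed above.  A fixed 0.25/0.5/0.75 grid is available
(`quantile_mode = "fixed"`).  Empirical cutoffs are the default because
stage-specific score distributions concentrate in narrow ranges (a T1
cohort may lie entirely above 0.8, where a fixed grid would put everyone in
one group).  Fully tied scores yield degenerate cutoffs: all patients land
in the top group and a warning is emitted.

### Uncertainty

Bootstrap resampling is at the patient level, with replacement, stratified
within T stage (all estimands are stage-specific; preserving stage sample
sizes avoids mixing stage mixes into the interval).  Intervals are
percentile at 95%, with endpoints taken as explicit order statistics
$x_{(\lceil pm \rceil)}$ — a small fuzz guards exact multiples of $1/m$
against floating-point promotion to the next index.  The study default is
1000 replicates; the point fit uses the multi-start optimizer while
bootstrap refits start once from the method-of-moments values, which is
accurate and keeps 1000 refits cheap.  Replicates whose refit fails or is
degenerate are dropped; more than 20% failures aborts the interval.

### Survival

Kaplan–Meier estimation and the $k$-group log-rank test go through the
`survival` package; deaths precede censorings at tied times; survival time
is in months and zero times are kept at zero.  The four per-stage tests are
reported without multiplicity correction, matching common practice for
per-stratum exploratory comparisons.

## The synthetic-cohort generator

`simulate_cohort()` emulates a registry-scale GSRCC cohort with the exact
statistical structure the analysis assumes: stage mix 116/60/176/209 (out
of 561), stage prevalences 0.155/0.583/0.727/0.895, beta-binomial
parameters on the scale of published stage-specific fits, and
examined-node counts $1 + \mathrm{NB}(\mu = 14, \text{size} = 1.2)$ capped
at 90 — a realistic right-skewed lymphadenectomy yield (median ≈ 10,
long upper tail) chosen once; registry sources do not publish the
examined-node distribution, so recovery tolerances are always defined
against the generator's own truth.  Survival is exponential with monthly
base hazard 0.010, hazard ratio 2 for truly diseased patients, independent
exponential censoring at rate 0.006 and an administrative cutoff at 120
months (≈30% censoring) — used only to exercise the survival module, not
to emulate GSRCC survival.  Ground-truth labels (disease indicator, latent
propensity, FN flag) are returned alongside the cohort.

Each patient draws from a private RNG substream derived from the seed and
the patient index, so enlarging a cohort extends it without reshuffling
earlier patients.  `expected_observed_prevalence()` gives the closed-form
expected node-positive fraction, the analytic oracle the generator is
tested against.

What passing tests on synthetic data do **not** show: real cohorts violate
node exchangeability (station structure), have non-exponential survival
with stage-dependent hazards, and their examined-node distribution differs
from the stand-in; results on real data inherit none of the generator's
guarantees.

## Identifiability and problem sizes

A practical warning that falls directly out of the model: **the
zero-truncated likelihood is nearly flat in $\alpha$ when $\alpha$ is
small.**  Truncation removes the $k = 0$ class, which is where a small
$\alpha$ carries almost all of its information.  For T1-scale truth
($\alpha \approx 0.07$) the maximum-likelihood estimate remains unstable
even with tens of thousands of node-positive observations, and at
realistic T1 sample sizes the fit can drift to the $\alpha \to 0$ boundary
(reported as degenerate, and the stage is skipped by the pipeline rather
than silently misreported).  For stages with $\alpha$ near 0.5–0.8 (T3/T4
scale) a few hundred node-positive patients identify the parameters well.
Consumers of T1-type fits should rely on the bootstrap interval, not the
point estimate.

Test and validation problem sizes were chosen as the smallest that make
each property sharp: MLE recovery at 5,000 node-positive observations,
end-to-end recovery on a 20,000-patient cohort, bootstrap coverage with
200 replicates over 50 outer simulations at a 561-patient single-stage
cohort, and null log-rank calibration over 50 replicates.

## Numerical choices

* Beta ratios via `lbeta` (log-gamma) only; products and quadrature are
  test oracles.
* Truncated log-likelihood uses `log1p(-exp(lp0))` for the conditioning
  term.
* Optimizer tolerance `reltol = 1e-10`, max 2000 iterations per start.
* Score curves are evaluated to `n_max = 90` by default (registry
  examined-node field ceiling); `min_nodes_for_score()` returns
  `NA_integer_` when the target is not reached by `n_max`.
* Percentages in the characteristics table round half-up to one decimal;
  prevalences export at 3 decimals; parameters at 7 significant digits.

## Known limitations

* No covariate adjustment in the beta-binomial (no regression on tumor
  size, site, age) and no Bayesian fitting.
* The FN adjustment treats the fitted $(\hat\alpha, \hat\beta)$ as known
  when imputing; the bootstrap is the only propagation of that
  uncertainty.
* Quantile groups from near-tied score distributions are fragile; the
  empirical-cutoff default mitigates but cannot remove this.
* The survival component is descriptive (KM + log-rank); no Cox models,
  competing risks or landmarking.
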