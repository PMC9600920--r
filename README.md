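# nodalstaging

Adequacy of pathological lymph-node staging in gastric signet ring cell
carcinoma (GSRCC).  A patient staged pN0 may still harbour nodal disease:
when few nodes are examined, metastatic nodes are easily missed.  This
package quantifies that risk and turns it into a per-patient **nodal staging
score (NSS)** — the probability that an all-negative nodal exam reflects
true absence of nodal disease — as a function of T stage and the number of
examined nodes.  It is aimed at biostatisticians and clinical researchers
working with registry-style cohorts (SEER-like patient tables).

## Model

Node positivity for a truly diseased patient is beta-binomial: the
per-node positivity propensity is `p ~ Beta(α_T, β_T)` (stage-specific),
and the number of positive nodes among `n` examined is `Binomial(n, p)`.
Three working assumptions: no false-positive nodes; examined nodes are
exchangeable; sensitivity is identical for detected and missed disease.

1. **Miss probability.**  For a diseased patient with `n` examined nodes,

       Prob(FN | n, T) = B(α_T, β_T + n) / B(α_T, β_T)

   the zero class of the beta-binomial (computed via log-gamma
   differences).  `(α_T, β_T)` are fitted by maximum likelihood on the
   node-positive patients of the stage, using the **zero-truncated**
   likelihood (the fitting sample is defined by `k ≥ 1`).

2. **Prevalence adjustment.**  Per (stage, `n`) stratum, the expected
   number of false negatives hiding among the observed negatives is

       #FN = Prob(FN) · #TP / (1 − Prob(FN)),

   capped at the stratum's observed negative count.  The adjusted stage
   prevalence is `Σ(#TP + #FN) / Σ(#TP + #TN + #FN)` (false negatives are
   re-labelled, not added).

3. **Nodal staging score.**

       NSS(n, T) = (1 − Prev_T) / ((1 − Prev_T) + Prev_T · Prob(FN | n, T))

   NSS rises with `n`; within each stage, patients are split into quartile
   groups of NSS and compared by Kaplan–Meier / log-rank.

Bootstrap (patient-level, stratified by stage; percentile method) supplies
95% CIs for parameters, prevalence and curves.  A synthetic-cohort
generator with ground-truth disease labels makes the full pipeline testable
without registry access.

## Worked example

Reference stage-specific parameters and stage counts from a published SEER
GSRCC cohort (n = 561) ship with the package:

```r
library(nodalstaging)
params <- read_bb_params(system.file("extdata", "gsrcc_reference_params.json",
                                     package = "nodalstaging"))
counts <- read.csv(system.file("extdata", "gsrcc_stage_counts.csv",
                               package = "nodalstaging"))
strata <- data.frame(t_stage = counts$t_stage, nodes_examined = 10,
                     n_positive = counts$ln_positive,
                     n_negative = counts$ln_negative)
round(apparent_prevalence(strata), 3)
#>    T1    T2    T3    T4
#> 0.155 0.583 0.727 0.895

round(fn_probability(params$T2$alpha, params$T2$beta, c(1, 5, 10, 20)), 4)
#> [1] 0.8390 0.5823 0.4622 0.3567
```

A T2 patient with 10 examined nodes still has a 46% chance of missed nodal
disease; the corresponding staging score,

```r
curve <- nss_curve(params$T2, 0.583, n_max = 90)
round(curve$score[c(1, 5, 10, 20)], 4)
#> [1] 0.4599 0.5509 0.6071 0.6669
min_nodes_for_score(curve, 0.75)
#> [1] 55
```

so an all-negative T2 exam with 10 nodes carries only 61% confidence of
true node negativity, and 55 examined nodes would be needed to reach 0.75.

End-to-end on a synthetic cohort:

```r
sim <- simulate_cohort(sim_config(n_patients = 2000), seed = 42)
res <- run_pipeline(sim$cohort, pipeline_config(n_boot = 200, seed = 42))
res$params$T4
#> Beta-binomial fit [T4]: alpha = 0.7515257, beta = 0.8501303 (n = 564, logLik = -1372.7522)
#>   95% CI alpha: (0.6010077, 0.9442982)  beta: (0.7300727, 0.9819078)
res$prevalence
#>   t_stage apparent adjusted fn_total n_patients
#> 1      T1   0.0184   0.0348     7.14        435
#> 2      T2   0.2750   0.4425    33.49        200
#> 3      T3   0.5135   0.6967   115.64        631
#> 4      T4   0.7684   0.9070   101.76        734
res$survival$T4$test[c("statistic", "df", "p_value")]
#> $statistic
#> [1] 0.1228723
#> $df
#> [1] 3
#> $p_value
#> [1] 0.988958
```

The adjusted prevalences move from the observed positive fractions toward
the generator's truths (0.155/0.583/0.727/0.895); T1's tiny α makes its
parameters — and hence its adjustment — very weakly identified at this
cohort size (see the methods vignette).  The flat log-rank test reflects
the generator's survival model, which ties hazard to true disease status,
not to the examined-node count.

## Layout

- `R/` — cohort ingestion and validation; beta-binomial core and truncated
  MLE; FN imputation and prevalence adjustment; NSS curves, minimal-node
  lookup, quantile groups; bootstrap; survival; synthetic-cohort generator;
  pipeline orchestration with manifest.
- `vignettes/nodal-staging-score.Rmd` — methods: model, assumptions,
  numerical choices, generator design, limitations.
- `inst/extdata/` — reference parameter and stage-count fixtures.
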