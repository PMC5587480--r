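# acmove

Movement ecologists tracking burrowing, central-place animals (desert
tortoises being the motivating case) face a recurring two-part problem:
weekly radio-telemetry encounters yield burrow-to-burrow displacement
distances whose distribution is strongly bimodal — short shuffles *within*
an activity center versus rare, long forays *among* activity centers — and
the scientific questions concern the second kind only. `acmove` is an R
package for that workflow: it classifies movements into the two behavioural
modes and models the probability of among-activity-center movement against
temporal, individual, landscape, vegetation, and weather covariates.

## What it computes

**Mode discrimination.** For each sex class, the distribution of
displacement distances (on the `log(d + 1)` scale) is tested for
multimodality with Silverman's critical-bandwidth test: `h_crit(k)` is the
smallest Gaussian-KDE bandwidth with at most `k` modes, and the p-value is
the fraction of variance-rescaled smoothed-bootstrap resamples whose
critical bandwidth exceeds the observed one. The classification threshold is
the intermodal density minimum between the two most prominent modes,
bandwidth-extrapolated to remove smoothing bias. A distance at or above the
threshold is an among-center movement (`is_acm = 1`).

**The movement model.** A binomial GLMM on the logit scale,

    logit(p) = x'beta + b_individual + c_area + log(interval)

with nested random intercepts (individual within monitoring area) and the
log of the 5–8-day encounter interval as an offset, fitted by Laplace
approximation (lme4). Candidate models always share a temporal core (year ×
cubic date polynomial). Model support uses `BIC = -2 LL + K ln n`
(`K` = fixed effects + 2 variance components); two-stage selection picks the
best model per covariate group by BIC, then ranks a 17-model final set
(constant, temporal, four group winners, all multi-group unions) by BIC
weight `w_i = exp(-dBIC_i / 2) / sum_j exp(-dBIC_j / 2)`. Unless a single
model holds ≥ 0.95 of the weight, coefficients are model-averaged with
unconditional standard errors, and covariates whose 95 % CI excludes zero
are flagged predictive. Discrimination is summarized by the Mann–Whitney
AUC.

**Synthetic data.** `sim_config()` / `simulate_dataset()` generate encounter
histories with known truth — bimodal log-normal step lengths per sex class,
covariate-driven among-center probability, nested random intercepts, daily
weather series — so the whole chain is testable without field data. The
generator's defaults are the package's study conditions; see the methods
vignette (`vignettes/activity-center-movement.Rmd`) for every parameter and
the reasoning behind it.

## A worked example

```r
library(acmove)

cfg <- pipeline_config(
  sim = sim_config(n_individuals_per_area = c(release = 14, control_west = 9,
                                              control_east = 5),
                   years = 2013:2014),
  n_boot = 50, nAGQ_stage1 = 0, nAGQ_stage2 = 0,
  compute_density_indices = FALSE, seed = 3)
res <- run_pipeline(cfg, "run-tiny")
summarize_run("run-tiny")
```

```
Run run-tiny (seed 3)
Movements: 992 among 28 individuals (1211 encounters retained of 1517)
Median distance 6.9 m; among-center fraction 0.335
Thresholds (m):
  female: 39.6 (Silverman p = 0)
  male: 27.4 (Silverman p = 0)
  subadult: 13.1 (Silverman p = 0.56)
Second-stage ranking (top 5):
  Weather                                       BIC 1230.6  dBIC   0.0  w 0.456
  Landscape + weather                           BIC 1231.8  dBIC   1.2  w 0.253
  Year and date                                 BIC 1233.3  dBIC   2.7  w 0.118
  Landscape                                     BIC 1234.0  dBIC   3.4  w 0.083
  Vegetation                                    BIC 1236.4  dBIC   5.8  w 0.025
Coefficients were model-averaged across the second-stage set.
Best model: Weather (AUC 0.74)
```

Reading the report: the thresholds are the estimated intermodal density
minima in metres — the classification boundaries between within- and
among-center movements — and the Silverman p-values quantify the evidence
for bimodality (males and females reject unimodality decisively; the ~60
subadult movements cannot, and their threshold is correspondingly
uncertain). The ranking lists the final candidate models by BIC with their
weights; no model reaches the 0.95 single-model weight rule, so
coefficients are model-averaged. At this toy sample size BIC keeps only a
weather effect — the remaining generating effects are too small to justify
their parameters at n ≈ 1,000, which is itself a correct selection outcome.
At the default scale (~5,600 movements among 102 individuals) the winner is
the individual + landscape + weather combination that generated the data,
with a positive fence effect and a negative minor-road effect among the
predictive covariates.

The individual stages are exported if you want the pieces:
`filter_encounters()`, `build_movements()`, `silverman_test()`,
`estimate_thresholds()`, `classify_movements()`, `build_covariate_table()`,
`fit_glmm()`, `stage1_select()`, `stage2_set()`, `rank_and_weight()`,
`model_average()`, `predict_scenarios()`.

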