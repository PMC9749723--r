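# landmarkvar

Two-stage "super landmark" dynamic prediction of 10-year cardiovascular
disease (CVD) risk from longitudinal primary-care records of people with
type 2 diabetes, with particular attention to whether **within-person
variability** of routinely measured risk factors — systolic blood
pressure (SBP), total cholesterol (TC), HDL cholesterol (HDL), HbA1c —
carries prognostic information beyond their level. A seeded synthetic
cohort generator with known ground truth makes every stage testable
without access to licensed health records.

## The model

Prediction is anchored at landmark ages `s = 40, 41, ..., 85`. A subject
contributes a record at `s` when under follow-up, event-free, diagnosed
with diabetes by `s`, and (complete-case) with every factor measured in
the half-open window `[30, s)`. The outcome is the first CVD event in
`(s, s + 10]`, follow-up truncated at `s + 10`.

**Stage 1** summarises each factor's pre-landmark history four ways:
last observed value; cumulative mean; within-person standard deviation
(defined for ≥ 2 measurements); and the best linear unbiased predictions
(BLUPs) of current value and slope at `s` from a multivariate linear
mixed model

&nbsp;&nbsp;&nbsp;&nbsp;*y<sub>ik</sub>(a) = β<sub>k0</sub> + β<sub>k1</sub>(a−50) + β<sub>k2</sub>(a−50)² + b<sub>0ik</sub> + b<sub>1ik</sub>(a−50) + ε<sub>ik</sub>(a)*

with an unstructured 8-dimensional cross-factor random-effect covariance
and factor-specific residual variances, fitted sex-specifically by a
deterministic ECM maximum-likelihood algorithm.

**Stage 2** stacks the records of all 46 landmark ages into one dataset
(a subject appears up to 46 times) and fits sex-specific Cox models on
the time scale *years since landmark*:

&nbsp;&nbsp;&nbsp;&nbsp;*λ(t | x) = λ<sub>0</sub>(t) exp{β′x}*,&nbsp;&nbsp;
*P̂(event by 10 yr) = 1 − exp{−Λ̂<sub>0</sub>(10) e<sup>β̂′(x−x̄)</sup>}*

where `x` holds landmark age (`s − 60`, `(s − 60)²`), ethnicity,
diabetes duration, smoking, antihypertensive and atrial-fibrillation
history, the four factor summaries with landmark-age interactions, and
optionally the within-person SDs. Standard errors are cluster-robust on
subject (up to 46 correlated records each); ties use Efron's
approximation; the baseline cumulative hazard is a Breslow step function
that reduces exactly to Nelson–Aalen at a zero linear predictor.

Models are compared on held-out practices (2:1 practice-level split) by
Harrell's C (strict comparability convention), 10-year IPCW Brier score,
calibration slope by landmark-age bin, and continuous NRI, with
cluster-bootstrap confidence intervals resampling subjects with all
their records. See the methods vignette
(`vignettes/landmark-variability-methods.Rmd`, source only) for full
conventions.

## Worked example

```r
library(landmarkvar)

cohort <- generate_cohort(sim_config(n_subjects = 4000, seed = 1))
split  <- split_by_practice(cohort, seed = 1)
der <- build_landmark_dataset(split$derivation, landmark_grid())
val <- build_landmark_dataset(split$validation, landmark_grid())
mixed <- list(M = fit_mixed(split$derivation, "M"),
              F = fit_mixed(split$derivation, "F"))
der <- add_mixed_summaries(der, mixed, split$derivation)
val <- add_mixed_summaries(val, mixed, split$validation)
fits <- fit_model_set(der, c("last", "current_sd"))
cmp <- compare_models(val, fits, referent = "last", n_boot = 200, boot_seed = 1)
cmp[, c("model", "c_index", "c_lo", "c_hi", "c_diff",
        "c_diff_lo", "c_diff_hi", "brier")]
```

Printed output (about 5 minutes on one CPU):

```
      model   c_index      c_lo      c_hi     c_diff   c_diff_lo  c_diff_hi     brier
       last 0.6821063 0.6534897 0.7140249 0.00000000 0.000000000 0.00000000 0.1335682
 current_sd 0.6937878 0.6646165 0.7273115 0.01168145 0.003000277 0.02080907 0.1316869
```

Adding the four within-person SDs to the mixed-model current-value model
raises the validation C-index by +0.0117 (95% bootstrap CI 0.0030 to
0.0208) over the last-observed-value model in this 4000-subject world,
whose generator gives within-person variability a real effect on the
hazard. `run_experiment(experiment_config(...))` wraps the same pipeline
end to end and serialises every artifact with a hashed manifest.

## Main analysis

The numbered drivers under `analysis/` run the full study at the default
conditions (4000 subjects, seed 1; outputs land in `analysis/output/`,
not versioned):

```sh
for s in analysis/0*.R; do Rscript "$s"; done   # ~12 min total
```

Headline results from that run:

| model        | C-index | ΔC vs last [95% CI]        | Brier  |
|--------------|---------|----------------------------|--------|
| last         | 0.6821  | —                          | 0.1336 |
| mean         | 0.6833  | +0.0012 [−0.0036, 0.0078]  | 0.1336 |
| current      | 0.6866  | +0.0045 [+0.0005, 0.0091]  | 0.1330 |
| last + SD    | 0.6891  | +0.0069 [+0.0006, 0.0140]  | 0.1324 |
| mean + SD    | 0.6905  | +0.0084 [−0.0003, 0.0184]  | 0.1324 |
| current + SD | 0.6938  | +0.0117 [+0.0030, 0.0208]  | 0.1317 |

Continuous NRI of current + SD over last: 0.1965.

Designed experiments (`analysis/06_designed_experiments.R`):

* **Coefficient recovery** — across 20 replicate flat-trajectory cohorts
  fitted on true covariates, 95.8% of 360 coefficient estimates fall
  within 2 cluster-robust SEs of the generator's coefficients.
* **Variability signal** — with the generator's variability effect
  concentrated on SBP, ΔC of current + SD over last is +0.0308
  [0.0131, 0.0468], and the SBP-only SD augmentation gives much the
  largest single-factor gain (+0.0317 vs ≤ 0.0010 for the others).
* **Null arm** — with all variability effects set to zero the gain
  vanishes: +0.0030 [−0.0088, 0.0122].

## Reproduction

`scripts/acceptance.R` runs the complete default experiment against the
**installed** package and writes the main computed quantities as a flat
JSON object:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

It simulates the default 2000-subject cohort with the given seed, splits
practices 2:1, builds the stacked landmark datasets, fits the Stage-1
mixed models and all ten Stage-2 Cox specifications, and evaluates them
on the validation records (200 bootstrap replicates for the headline
comparison). The JSON holds per-model C-indexes, the ΔC of current + SD
vs last with its CI, single-factor SD ΔCs, Brier scores, the pooled
calibration slope, the continuous NRI, the mean predicted risk, and the
Kaplan–Meier event fraction. Runtime is a few minutes; the same seed
reproduces the numbers exactly.

## License

MIT (see `LICENSE`).
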