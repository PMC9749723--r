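---
title: "Two-stage super landmark models with within-person variability"
author: "landmarkvar"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`landmarkvar` implements a two-stage "super landmark" (stacked landmark)
approach to dynamic 10-year cardiovascular risk prediction from
longitudinal primary-care records of people with type 2 diabetes, and a
seeded synthetic-cohort generator with known ground truth so that every
stage is testable without access to licensed health records.

The scientific question the package is built to examine: does a person's
*within-person variability* in routinely measured risk factors —
systolic blood pressure (SBP), total cholesterol (TC), HDL cholesterol
(HDL) and HbA1c — carry prognostic information for cardiovascular
disease beyond the level of those factors, and how should the level
itself be summarised (last observed value, cumulative mean, or
mixed-model estimated current value)?

# The landmark design

Prediction is anchored at **landmark ages** $s \in \{40, 41, \ldots,
85\}$ (46 ages). A subject contributes a record at landmark age $s$ when
they are under follow-up and event-free at $s$, have diabetes diagnosed
on or before $s$, and (in the primary complete-case analysis) have at
least one measurement of every risk factor and an observed smoking
status strictly before $s$. The outcome of the record is the first
cardiovascular event in the **closed horizon** $(s, s + w]$ with $w =
10$ years; follow-up is truncated at $s + w$, and an event at exactly
$s + w$ counts as in-horizon.

All pre-landmark information is restricted to the half-open age window
$[30, s)$: a measurement taken at exactly the landmark age is *not*
available for prediction at it.

The records of all landmark ages are **stacked** into one dataset (a
subject appears up to 46 times) and analysed jointly — the "super
landmark" model — with landmark age entering the model as a covariate
(centred at 60, with a quadratic term and interactions) rather than via
separate per-age models.

# Stage 1: summaries of the measurement history

For each record, each factor's history in $[30, s)$ is summarised by:

* **last** — the most recent observed value;
* **mean** — the crude mean of all prior values;
* **sd** — the within-person sample standard deviation ($n - 1$
  denominator), defined only when at least two prior measurements
  exist;
* **current / slope** — the best linear unbiased predictions (BLUPs) of
  the subject's value and rate of change at $s$ from a multivariate
  linear mixed model.

The Stage-1 mixed model describes all four factors jointly. For subject
$i$, factor $k$, measurement age $a$ (values standardised per factor,
ages centred at 50):

$$y_{ik}(a) = \beta_{k0} + \beta_{k1}(a - 50) + \beta_{k2}(a - 50)^2 +
b_{0ik} + b_{1ik}(a - 50) + \epsilon_{ik}(a),$$

with the stacked random effects $b_i \in \mathbb{R}^8$ multivariate
normal with unstructured covariance $G$ (capturing cross-factor
correlation) and independent factor-specific residual variances
$\sigma_k^2$. It is fitted by maximum likelihood with a deterministic
expectation/conditional-maximisation (ECM) algorithm, sex-specifically,
on the derivation subjects only; BLUPs for any record then use only that
record's pre-landmark history. A `"diagonal"` mode (independent
per-factor blocks, equivalent to four univariate fits) exists chiefly to
allow verification against independent univariate mixed-model software.

A bespoke ECM implementation is used because the model couples four
outcome series with *different residual variances* through one
random-effect covariance — a structure standard single-outcome mixed
model interfaces do not expose directly. It is verified in the test
suite against `lme4` in the separable (diagonal) case and against exact
joint-Gaussian conditioning for the BLUPs.

# Stage 2: sex-specific super landmark Cox models

For each candidate covariate specification, a Cox proportional-hazards
model is fitted to the stacked records of each sex, on the time scale
*years since landmark*:

* landmark age: $s - 60$, $(s - 60)^2$;
* ethnicity (reference "Unspecified"), diabetes duration at $s$,
  current smoking, antihypertensive-medication and atrial-fibrillation
  history (ever before $s$);
* the four factors under the chosen summary (last / mean / current),
  each also interacted with $s - 60$, plus a smoking interaction;
* optionally, the within-person SDs of some or all factors.

Because a subject contributes up to 46 correlated records, standard
errors use a cluster-robust sandwich estimator clustered on subject.
Ties are handled by the Efron approximation. The baseline cumulative
hazard is a Breslow step function stored at the derivation covariate
means; at a zero linear predictor it reduces exactly to the
Nelson-Aalen estimator. Predicted 10-year risk is

$$\hat{P}(T \le s + 10 \mid \text{history at } s) =
1 - \exp\{-\hat\Lambda_0(10)\, e^{\hat\beta'(x - \bar{x})}\}.$$

Ethnicity categories whose derivation carriers are fewer than five or
contribute no (or only) events are merged into the reference category;
their coefficients would otherwise be unbounded.

The canonical model set compares: `last`, `mean`, `current`, each
`+ SD` of all four factors, and the four single-factor SD augmentations
of the current-value model.

# Evaluation

Models are compared on the validation records (held-out practices; see
below) by:

* **Harrell's C-index** on the stacked records, under the convention
  that a pair is comparable only when the strictly shorter follow-up
  time ends in an event (pairs with exactly equal times are not
  comparable);
* **Brier score** for 10-year risk with Graf-style inverse probability
  of censoring weights from the Kaplan-Meier censoring distribution
  ($1/G(T-)$ for events, $1/G(w-)$ for survivors at $w$, weight zero
  for records censored before $w$, normalised by all records);
* **calibration slope**: per landmark-age bin, the Cox coefficient of
  the prognostic index $\log(-\log(1 - \hat{p}))$, with single-year
  bins merged upward until each holds at least 20 events;
* **continuous net reclassification improvement (NRI)** in its
  Kaplan-Meier-adjusted form for censored data.

Confidence intervals for metrics and their differences come from a
cluster bootstrap: *subjects* are resampled with replacement with all
their landmark records, preserving the within-subject dependence. When
any compared model uses SDs, all models are evaluated on the records
with all four SDs available, so comparisons stay paired.

## Derivation/validation split

General practices — not subjects — are randomised 2:1 to derivation and
validation, so all records of a practice (and hence of a subject) fall
on one side; this mirrors internal-external validation of clustered
primary-care data.

# The synthetic cohort generator

The generator draws, per subject: sex, ethnicity, practice, entry age
(uniform 40-80), diabetes diagnosis age, latent linear age trajectories
$\mu_{ik}(a) = \alpha_k + \beta_k (a - 50) + b_{0ik} + b_{1ik}(a - 50)$
for the four factors, a per-person *within-person measurement SD*
$\sigma_{ik}$ (lognormal), a yearly smoking state path, and
medication/atrial-fibrillation onset ages. Observed measurements are
$\mu_{ik}(a) + \sigma_{ik} \varepsilon$ at Poisson-process visit times
over the recording window $[\max(30, \text{entry} - 5), \text{exit}]$.

Events are generated from an age-scale proportional-hazards model with
Weibull baseline:

$$\lambda_i(a) = \lambda_0(a) \exp\Big\{\sum_k \beta^{(c)}_k \mu_{ik}(a)
+ \sum_k \gamma_k \sigma_{ik} + \text{binary terms}\Big\},$$

inverted on a 0.1-year grid. The $\gamma_k$ terms make true risk depend
on within-person variability itself, so the ground truth contains the
phenomenon the Stage-2 SD models look for. Setting all $\gamma_k = 0$
gives a null world in which SD terms carry no information.

Default parameters are fixed once to mimic a routine-care type 2
diabetes cohort — e.g. SBP mean about 140 mmHg with within-person SD
around 9 mmHg, HbA1c around 7.6%, diagnosis age 59 (SD 12), about 39%
women, an event rate near 17.5 per 1000 person-years, and SBP measured
about twice a year (the most frequent factor) — and are *not* tuned to
test outcomes. All randomness flows from one seed through per-subject
substreams; the same configuration yields a byte-identical cohort.

Ground truth (random effects, $\sigma_{ik}$, smoking paths) is stored
alongside the data for testing, never written to the exported CSVs, and
never consumed by the inference code paths.

# Designed experiments

Three configurations back the package's acceptance claims:

* `design_flat_recovery()`: zero population and person-level slopes,
  frozen smoking, medication/AF/duration terms off — every subject's
  true log hazard ratio is constant, so the stacked Cox model fitted on
  the *true* covariates (`true_covariate_records()`) targets exactly
  the generator's coefficients. Across 20 replicate seeds of 2000
  subjects, the fraction of coefficients within 2 cluster-robust SEs of
  truth is required to be at least 90%.
* `design_sd_signal()`: variability coefficients concentrated on SBP,
  the most frequently measured factor. The current+SD model must beat
  the last-value model on C-index with a bootstrap CI excluding zero,
  and the SBP-SD single augmentation must give the largest gain.
* `design_sd_null()`: the same with $\gamma = 0$; the CI must cover
  zero.

# Typical problem sizes and runtimes

A 4000-subject cohort generates in roughly 5-7 s and yields about
35,000-40,000 landmark records; one sex-specific mixed-model fit takes
5-10 s, a Cox fit 1-3 s, and a 200-replicate cluster bootstrap of a
two-model comparison 20-40 s. The full default experiment
(`run_experiment()`) completes in a few minutes on one CPU.

# Worked example

```{r example}
library(landmarkvar)

cfg <- experiment_config(
  simulation = sim_config(n_subjects = 2000, seed = 1),
  models = c("last", "mean", "current", "current_sd"),
  output_dir = "landmarkvar_run")
res <- run_experiment(cfg)
res$comparison
```

Or stage by stage:

```{r stages}
cohort <- generate_cohort(sim_config(n_subjects = 2000, seed = 1))
split <- split_by_practice(cohort, seed = 1)
der <- build_landmark_dataset(split$derivation, landmark_grid())
val <- build_landmark_dataset(split$validation, landmark_grid())
mixed <- list(M = fit_mixed(split$derivation, "M"),
              F = fit_mixed(split$derivation, "F"))
der <- add_mixed_summaries(der, mixed, split$derivation)
val <- add_mixed_summaries(val, mixed, split$validation)
fits <- fit_model_set(der, c("last", "current_sd"))
compare_models(val, fits, referent = "last", n_boot = 200, boot_seed = 1)
```

# Limitations

* The generator's trajectories are linear in age and its hazard is
  Weibull on the age scale; the stacked Cox model (time since landmark,
  pooled baseline) is deliberately *mis*specified relative to it, as
  any landmark model is relative to reality. Coefficient-recovery
  claims therefore use the flat-trajectory design where the mapping is
  exact.
* Within-person SD is treated as time-constant per subject in the
  generator; the empirical SD summary, by contrast, accumulates with
  the history, as it would in practice.
* Calibration slopes at extreme landmark ages rest on few events even
  after bin merging and are reported with the merge boundaries.
* Bootstrap confidence intervals are percentile intervals; no
  small-sample corrections are applied.
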