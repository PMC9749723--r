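# Stage-2 Cox machinery: the practice split, partial-likelihood estimates
# against a direct-optimisation oracle, the Breslow baseline against a
# hand Nelson-Aalen, risk-prediction identities and model comparison.

test_that("split_by_practice is deterministic, disjoint and 2/3-sized", {
  co <- small_cohort(n = 300, seed = 7)
  sp1 <- split_by_practice(co, seed = 4)
  sp2 <- split_by_practice(co, seed = 4)
  expect_identical(sp1$derivation$subjects, sp2$derivation$subjects)
  pd <- unique(sp1$derivation$subjects$practice_id)
  pv <- unique(sp1$validation$subjects$practice_id)
  expect_length(intersect(pd, pv), 0)
  n_prac <- length(unique(co$subjects$practice_id))
  expect_equal(length(pd), round(2 / 3 * n_prac))
  # every subject is on exactly one side
  expect_equal(sort(c(sp1$derivation$subjects$subject_id,
                      sp1$validation$subjects$subject_id)),
               sort(co$subjects$subject_id))
  # measurements follow their subjects
  expect_true(all(sp1$derivation$measurements$subject_id %in%
                    sp1$derivation$subjects$subject_id))
  # a different seed gives a different split
  sp3 <- split_by_practice(co, seed = 5)
  expect_false(setequal(pd, unique(sp3$derivation$subjects$practice_id)))
  # split leaves the global RNG state untouched
  set.seed(99); before <- .Random.seed
  invisible(split_by_practice(co, seed = 4))
  expect_identical(.Random.seed, before)
})

test_that("split_by_practice needs at least two practices", {
  co <- make_manual_cohort(data.frame(subject_id = 1:4))
  expect_error(split_by_practice(co), "two practices")
})

test_that("the Cox fit matches a direct partial-likelihood optimisation", {
  # records engineered so exactly one covariate (SBP) is non-constant:
  # everyone shares landmark age 60 (so the centred age, its square and
  # all interactions vanish) and all other covariates are identical
  set.seed(51)
  n <- 120
  rec <- make_cox_records(n = n, seed = 51, beta_sbp = 0.04)
  rec$landmark_age <- 60
  rec$ethnicity <- "Unspecified"
  rec$smoking_last <- 0L
  rec$bp_med_ever <- 0L
  rec$af_ever <- 0L
  rec$diabetes_duration <- 5
  for (k in c("tc", "hdl", "hba1c")) {
    rec[[paste0(k, "_last")]] <- 1
    rec[[paste0(k, "_sd")]] <- 1
  }
  rec$sbp_sd <- 1
  # continuous times: no ties, so Efron = Breslow = the oracle form
  fit <- fit_super_landmark_cox(rec, covariate_spec("last"), "M")
  expect_equal(names(fit$beta), "sbp")
  b_oracle <- oracle_cox_beta(rec$follow_time, rec$event_in_horizon,
                              rec$sbp_last, interval = c(-1, 1))
  expect_equal(unname(fit$beta), b_oracle, tolerance = 1e-4)
  # and agrees with coxph called directly
  cf <- survival::coxph(survival::Surv(follow_time, event_in_horizon) ~
                          sbp_last, data = rec)
  expect_equal(unname(fit$beta), unname(coef(cf)), tolerance = 1e-8)
})

test_that("the Breslow baseline at zero lp is exactly Nelson-Aalen", {
  set.seed(61)
  time <- round(runif(40, 0.2, 10), 2)
  event <- rbinom(40, 1, 0.6)
  bh <- breslow_basehaz(time, event, rep(0, 40))
  for (t in c(0.5, 2, 5, 9.9, 12)) {
    expect_equal(eval_cumhaz(bh, t), oracle_nelson_aalen(time, event, t),
                 tolerance = 1e-12)
  }
  expect_equal(eval_cumhaz(bh, 0), 0)
  # cumulative hazard is a non-decreasing step function
  expect_true(all(diff(bh$cumhaz) >= 0))
})

test_that("predict_risk applies the stored fit exactly and sensibly", {
  rec <- make_cox_records(n = 250, seed = 11)
  fit <- fit_super_landmark_cox(rec, covariate_spec("last"), "M")
  pr <- predict_risk(fit, rec, w = 10)
  expect_equal(nrow(pr), nrow(rec))
  expect_true(all(pr$predicted_risk > 0 & pr$predicted_risk < 1))
  # the documented identity risk = 1 - exp(-Lambda0(w) e^lp)
  H10 <- eval_cumhaz(fit$basehaz, 10)
  expect_equal(pr$predicted_risk,
               1 - exp(-H10 * exp(pr$linear_predictor)), tolerance = 1e-12)
  # a subject at the derivation covariate means has lp = 0 and the
  # baseline risk itself
  i <- which.min(abs(pr$linear_predictor))
  expect_equal(pr$predicted_risk[i], 1 - exp(-H10 * exp(pr$linear_predictor[i])))
  # risk is increasing in the linear predictor
  o <- order(pr$linear_predictor)
  expect_true(all(diff(pr$predicted_risk[o]) >= 0))
  # zero horizon means zero risk
  expect_true(all(predict_risk(fit, rec, w = 0)$predicted_risk == 0))
})

test_that("location shifts of a covariate do not change predictions", {
  rec <- make_cox_records(n = 250, seed = 13)
  fit0 <- fit_super_landmark_cox(rec, covariate_spec("last"), "M")
  rec2 <- rec
  rec2$sbp_last <- rec2$sbp_last + 25
  fit2 <- fit_super_landmark_cox(rec2, covariate_spec("last"), "M")
  expect_equal(fit0$beta[["sbp"]], fit2$beta[["sbp"]], tolerance = 1e-6)
  expect_equal(predict_risk(fit0, rec, w = 10)$predicted_risk,
               predict_risk(fit2, rec2, w = 10)$predicted_risk,
               tolerance = 1e-6)
})

test_that("cluster-robust variance reacts to duplicated subject records", {
  rec <- make_cox_records(n = 200, seed = 17)
  dup <- rbind(rec, rec)  # two identical landmark rows per subject
  fit <- fit_super_landmark_cox(dup, covariate_spec("last"), "M")
  rse <- sqrt(diag(fit$robust_vcov))["sbp"]
  nse <- sqrt(diag(fit$naive_vcov))["sbp"]
  # duplication halves the naive variance but the clustered sandwich
  # recognises the dependence
  expect_gt(rse / nse, 1.2)
})

test_that("degenerate fits are rejected with informative errors", {
  rec <- make_cox_records(n = 100, seed = 19)
  expect_error(fit_super_landmark_cox(rec, covariate_spec("last"), "F"),
               "no records for sex F")
  rec0 <- rec
  rec0$event_in_horizon <- 0L
  expect_error(fit_super_landmark_cox(rec0, covariate_spec("last"), "M"),
               "censored")
  # missing SD values surface as a named covariate error
  recna <- rec
  recna$tc_sd[1] <- NA
  expect_error(fit_super_landmark_cox(
    recna, covariate_spec("last", include_sd = RISK_FACTORS), "M"),
    "tc_sd")
})

test_that("rare no-event ethnicity categories are merged into the reference", {
  rec <- make_cox_records(n = 200, seed = 23)
  rec$ethnicity[1:3] <- "Mixed"
  rec$event_in_horizon[1:3] <- 0L  # carriers contribute no events
  rec$follow_time[1:3] <- 10
  fit <- fit_super_landmark_cox(rec, covariate_spec("last"), "M")
  expect_true("eth_mixed" %in% fit$dropped)
  expect_false("eth_mixed" %in% names(fit$beta))
  # prediction still works for those subjects
  pr <- predict_risk(fit, rec, w = 10)
  expect_false(anyNA(pr$predicted_risk))
})

test_that("canonical specs expose the documented model set", {
  specs <- canonical_model_specs()
  expect_setequal(
    names(specs),
    c("last", "mean", "current", "last_sd", "mean_sd", "current_sd",
      paste0("current_sd_", tolower(RISK_FACTORS), "_only")))
  expect_equal(specs$current_sd$summary_method, "current")
  expect_setequal(specs$current_sd$include_sd, RISK_FACTORS)
  expect_equal(specs$current_sd_sbp_only$include_sd, "SBP")
  expect_error(covariate_spec("last", include_sd = "LDL"), "must name factors")
})

test_that("fit_model_set and compare_models produce a coherent table", {
  rec <- make_cox_records(n = 400, seed = 29)
  rec$sex <- rep(c("M", "F"), each = 200)
  fits <- fit_model_set(rec, c("last", "mean", "current_sd"))
  expect_named(fits, c("last", "mean", "current_sd"))
  expect_s3_class(fits$last$M, "lmv_cox_fit")
  cmp <- compare_models(rec, fits, referent = "last", n_boot = 30,
                        boot_seed = 2)
  expect_equal(cmp$model, c("last", "mean", "current_sd"))
  expect_equal(cmp$c_diff[cmp$model == "last"], 0)
  expect_equal(cmp$brier_diff[cmp$model == "last"], 0)
  expect_true(all(cmp$c_index > 0 & cmp$c_index < 1))
  expect_true(all(cmp$c_diff_lo <= cmp$c_diff & cmp$c_diff <= cmp$c_diff_hi))
  # bootstrap is deterministic in its seed
  cmp2 <- compare_models(rec, fits, referent = "last", n_boot = 30,
                         boot_seed = 2)
  expect_equal(cmp, cmp2)
  # a model compared against itself under a different name has exactly
  # zero difference in every replicate
  fits2 <- list(last = fits$last, also_last = fits$last)
  cmp3 <- compare_models(rec, fits2, referent = "last", n_boot = 20,
                         boot_seed = 3)
  expect_equal(cmp3$c_diff[2], 0)
  expect_equal(cmp3$c_diff_lo[2], 0)
  expect_equal(cmp3$c_diff_hi[2], 0)
  expect_error(fit_model_set(rec, "lasso"), "unknown model")
})

test_that("ph_diagnostic reports per-term and global tests", {
  rec <- make_cox_records(n = 250, seed = 31)
  tab <- ph_diagnostic(rec, covariate_spec("last"), "M")
  expect_true("GLOBAL" %in% rownames(tab))
  expect_true("sbp" %in% rownames(tab))
  expect_true(all(tab$p >= 0 & tab$p <= 1, na.rm = TRUE))
})
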