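#' Split a cohort into derivation and validation sets by practice
#'
#' Randomises general practices (not subjects) so that all subjects of a
#' practice land on the same side, mirroring internal-external validation
#' of clustered primary-care data.
#'
#' @param cohort an `lmv_cohort`.
#' @param fraction fraction of practices assigned to derivation (default 2/3).
#' @param seed integer seed; the split is deterministic given it.
#' @return list with `lmv_cohort`s `derivation` and `validation`.
#' @export
split_by_practice <- function(cohort, fraction = 2 / 3, seed = 1L) {
  practices <- sort(unique(cohort$subjects$practice_id))
  if (length(practices) < 2)
    stop("at least two practices are required to split by practice",
         call. = FALSE)
  n_der <- round(fraction * length(practices))
  n_der <- min(max(n_der, 1), length(practices) - 1)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  der_practices <- sample(practices, n_der)
  list(derivation = subset_cohort(cohort, practice_ids = der_practices),
       validation = subset_cohort(cohort,
                                  practice_ids = setdiff(practices, der_practices)))
}

subset_cohort <- function(cohort, practice_ids = NULL, subject_ids = NULL) {
  sub <- cohort$subjects
  keep <- rep(TRUE, nrow(sub))
  if (!is.null(practice_ids)) keep <- keep & sub$practice_id %in% practice_ids
  if (!is.null(subject_ids)) keep <- keep & sub$subject_id %in% subject_ids
  ids <- sub$subject_id[keep]
  truth <- cohort$truth
  if (!is.null(truth)) {
    truth$random_effects <- truth$random_effects[
      truth$random_effects$subject_id %in% ids, ]
    truth$smoking_states <- truth$smoking_states[
      truth$smoking_states$subject_id %in% ids, ]
  }
  structure(list(
    subjects = sub[keep, ],
    measurements = cohort$measurements[cohort$measurements$subject_id %in% ids, ],
    smoking = cohort$smoking[cohort$smoking$subject_id %in% ids, ],
    truth = truth), class = "lmv_cohort")
}

#' Covariate specification for the super landmark Cox model
#'
#' Fixes the covariate expansion of the stacked Cox model: landmark age
#' (centred at 60) and its square, ethnicity, diabetes duration, smoking,
#' antihypertensive-medication and atrial-fibrillation history, the four
#' continuous factors under the chosen summary, landmark-age interactions
#' with the four factors and with smoking, and optionally the
#' within-person SDs and/or individual-level slopes of selected factors.
#'
#' @param summary_method `"last"`, `"mean"` or `"current"`: which Stage-1
#'   summary carries the continuous factors (and their age interactions).
#' @param include_sd character vector of factors whose within-person SD
#'   enters the model (subset of [RISK_FACTORS]; empty for none).
#' @param include_slope logical; include the individual-level slopes
#'   (default `FALSE`: slopes were not associated with the outcome and
#'   are not part of the canonical model set).
#' @return an object of class `lmv_cov_spec`.
#' @export
covariate_spec <- function(summary_method = c("last", "mean", "current"),
                           include_sd = character(0),
                           include_slope = FALSE) {
  summary_method <- match.arg(summary_method)
  include_sd <- toupper(include_sd)
  if (!all(include_sd %in% RISK_FACTORS))
    stop("include_sd must name factors among: ",
         paste(RISK_FACTORS, collapse = ", "), call. = FALSE)
  structure(list(summary_method = summary_method, include_sd = include_sd,
                 include_slope = isTRUE(include_slope)),
            class = "lmv_cov_spec")
}

#' Canonical model names and their covariate specifications
#'
#' The ten models of the comparison design: the three summary methods,
#' each augmented by the SDs of all four factors, plus the four
#' single-factor SD variants of the current-value model.
#'
#' @return named list of [covariate_spec()] objects.
#' @export
canonical_model_specs <- function() {
  specs <- list(
    last = covariate_spec("last"),
    mean = covariate_spec("mean"),
    current = covariate_spec("current"),
    last_sd = covariate_spec("last", include_sd = RISK_FACTORS),
    mean_sd = covariate_spec("mean", include_sd = RISK_FACTORS),
    current_sd = covariate_spec("current", include_sd = RISK_FACTORS))
  for (k in RISK_FACTORS)
    specs[[paste0("current_sd_", tolower(k), "_only")]] <-
      covariate_spec("current", include_sd = k)
  specs
}

ETH_DUMMY_LEVELS <- c("White", "Asian", "Black", "Mixed", "Other")

# expand landmark records into the numeric design matrix of a covariate
# specification; missing values in used columns raise a named error
build_cox_design <- function(records, spec) {
  stopifnot(inherits(spec, "lmv_cov_spec"))
  fkey <- tolower(RISK_FACTORS)
  vcols <- paste0(fkey, "_", spec$summary_method)
  miss <- setdiff(vcols, names(records))
  if (length(miss))
    stop("records lack required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  s_c <- records$landmark_age - 60
  X <- cbind(s_c = s_c, s_c2 = s_c^2)
  for (lv in ETH_DUMMY_LEVELS)
    X <- cbind(X, as.integer(records$ethnicity == lv))
  colnames(X)[2 + seq_along(ETH_DUMMY_LEVELS)] <-
    paste0("eth_", tolower(ETH_DUMMY_LEVELS))
  X <- cbind(X,
             diabetes_duration = records$diabetes_duration,
             smoking = records$smoking_last,
             bp_med = records$bp_med_ever,
             af = records$af_ever)
  for (ki in seq_along(fkey)) {
    v <- records[[vcols[ki]]]
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- fkey[ki]
  }
  for (ki in seq_along(fkey)) {
    X <- cbind(X, s_c * records[[vcols[ki]]])
    colnames(X)[ncol(X)] <- paste0("s_c_x_", fkey[ki])
  }
  X <- cbind(X, s_c_x_smoking = s_c * records$smoking_last)
  for (k in spec$include_sd) {
    col <- paste0(tolower(k), "_sd")
    X <- cbind(X, records[[col]])
    colnames(X)[ncol(X)] <- col
  }
  if (spec$include_slope) {
    for (ki in seq_along(fkey)) {
      X <- cbind(X, records[[paste0(fkey[ki], "_slope")]])
      colnames(X)[ncol(X)] <- paste0(fkey[ki], "_slope")
    }
  }
  if (anyNA(X)) {
    bad <- colnames(X)[colSums(is.na(X)) > 0]
    stop("missing values in covariates: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  X
}

# Breslow estimator of the baseline cumulative hazard at the given
# (already centred) linear predictor; at lp = 0 for everyone it equals
# the Nelson-Aalen estimator exactly
breslow_basehaz <- function(time, event, lp) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; elp <- exp(lp[ord])
  # risk-set sums: all subjects with observed time >= t
  rev_cum <- rev(cumsum(rev(elp)))
  ev_times <- unique(time[event == 1])
  haz <- numeric(length(ev_times))
  for (j in seq_along(ev_times)) {
    t_j <- ev_times[j]
    i0 <- which(time >= t_j)[1]
    d_j <- sum(event == 1 & time == t_j)
    haz[j] <- d_j / rev_cum[i0]
  }
  data.frame(time = ev_times, cumhaz = cumsum(haz))
}

eval_cumhaz <- function(basehaz, t) {
  idx <- findInterval(t, basehaz$time)
  ifelse(idx == 0, 0, basehaz$cumhaz[pmax(idx, 1)])
}

#' Fit a sex-specific super landmark Cox model
#'
#' Maximises the Cox partial likelihood (Efron tie handling) on the
#' stacked landmark records of one sex, with robust sandwich standard
#' errors clustered on subject (each subject contributes up to one record
#' per landmark age). The baseline cumulative hazard is a Breslow step
#' function stored at the derivation covariate means, whose values are
#' kept in the fit so predictions are exactly reproducible.
#'
#' Constant covariate columns (e.g. an ethnicity category absent from the
#' derivation data) are dropped from the fit and recorded; they act as
#' reference categories at prediction time.
#'
#' @param records stacked landmark dataset (one sex is selected via `sex`).
#' @param spec a [covariate_spec()].
#' @param sex `"M"` or `"F"`.
#' @return an object of class `lmv_cox_fit`.
#' @export
fit_super_landmark_cox <- function(records, spec, sex) {
  stopifnot(sex %in% c("M", "F"))
  rec <- records[records$sex == sex, , drop = FALSE]
  if (nrow(rec) == 0)
    stop("no records for sex ", sex, call. = FALSE)
  if (sum(rec$event_in_horizon) == 0)
    stop("all records are censored for sex ", sex,
         "; a Cox model cannot be fitted", call. = FALSE)
  X <- build_cox_design(rec, spec)
  keep <- apply(X, 2, function(col) stats::var(col) > 0)
  # an ethnicity category whose carriers contribute no events (or almost no
  # records) has an unbounded coefficient; merge it into the reference
  for (j in grep("^eth_", colnames(X))) {
    carriers <- X[, j] == 1
    if (keep[j] && (sum(carriers) < 5 ||
                    sum(rec$event_in_horizon[carriers]) == 0 ||
                    all(rec$event_in_horizon[carriers] == 1)))
      keep[j] <- FALSE
  }
  dropped <- colnames(X)[!keep]
  Xf <- X[, keep, drop = FALSE]

  y <- survival::Surv(rec$follow_time, rec$event_in_horizon)
  cluster_id <- rec$subject_id
  sep_warn <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(y ~ Xf, cluster = cluster_id, ties = "efron",
                    robust = TRUE, x = FALSE, y = FALSE,
                    control = survival::coxph.control(iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|did not converge|out of iterations",
                conditionMessage(w))) {
        sep_warn <<- c(sep_warn, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    })
  beta <- stats::coef(fit)
  names(beta) <- colnames(Xf)
  if (length(sep_warn) || anyNA(beta) || any(abs(beta) > 50)) {
    off <- names(beta)[is.na(beta) | abs(beta) > 50]
    stop("Cox fit failed to converge (possible separation)",
         if (length(off)) paste0("; offending coefficients: ",
                                 paste(off, collapse = ", ")),
         if (length(sep_warn)) paste0(" [", sep_warn[1], "]"),
         call. = FALSE)
  }
  rv <- fit$var
  nv <- fit$naive.var
  dimnames(rv) <- dimnames(nv) <- list(names(beta), names(beta))

  xbar <- colMeans(Xf)
  lp_centred <- drop(Xf %*% beta) - sum(xbar * beta)
  bh <- breslow_basehaz(rec$follow_time, rec$event_in_horizon, lp_centred)

  structure(list(sex = sex, spec = spec, beta = beta,
                 robust_vcov = rv, naive_vcov = nv,
                 xbar = xbar, basehaz = bh, dropped = dropped,
                 n = nrow(rec), n_events = sum(rec$event_in_horizon),
                 loglik = fit$loglik, score_test = fit$score),
            class = "lmv_cox_fit")
}

#' @export
print.lmv_cox_fit <- function(x, ...) {
  cat(sprintf("<lmv_cox_fit> sex %s (%s%s), %d records, %d events, %d coefficients\n",
              x$sex, x$spec$summary_method,
              if (length(x$spec$include_sd))
                paste0(" + SD[", paste(x$spec$include_sd, collapse = ","), "]")
              else "", x$n, x$n_events, length(x$beta)))
  invisible(x)
}

#' Predict w-year risk from a fitted super landmark Cox model
#'
#' Applies the stored hazard ratios and Breslow baseline:
#' `risk = 1 - exp(-Lambda0(w) * exp(lp - lp_bar))`, with the linear
#' predictor centred at the derivation covariate means.
#'
#' @param fit an `lmv_cox_fit`.
#' @param records landmark records to predict for (any sex column values
#'   are accepted; callers normally pass records of `fit$sex`).
#' @param w horizon in years (default 10).
#' @return data frame with `subject_id`, `landmark_age`,
#'   `linear_predictor` (centred) and `predicted_risk`.
#' @export
predict_risk <- function(fit, records, w = 10) {
  stopifnot(inherits(fit, "lmv_cox_fit"))
  X <- build_cox_design(records, fit$spec)
  used <- names(fit$beta)
  miss <- setdiff(used, colnames(X))
  if (length(miss))
    stop("records lack covariates required by the fit: ",
         paste(miss, collapse = ", "), call. = FALSE)
  lp <- drop(X[, used, drop = FALSE] %*% fit$beta) - sum(fit$xbar * fit$beta)
  H <- eval_cumhaz(fit$basehaz, w)
  risk <- 1 - exp(-H * exp(lp))
  data.frame(subject_id = records$subject_id,
             landmark_age = records$landmark_age,
             linear_predictor = lp, predicted_risk = risk)
}

#' Predict w-year risk for mixed-sex records from sex-specific fits
#'
#' Applies [predict_risk()] with the matching sex's fit to each record.
#'
#' @param fits named list `list(M = , F = )` of `lmv_cox_fit` objects.
#' @param records landmark records (both sexes).
#' @param w horizon in years (default 10).
#' @return numeric vector of predicted risks aligned with `records`.
#' @export
predict_risk_by_sex <- function(fits, records, w = 10) {
  out <- rep(NA_real_, nrow(records))
  for (sex in unique(records$sex)) {
    sel <- records$sex == sex
    out[sel] <- predict_risk(fits[[sex]], records[sel, , drop = FALSE], w)$predicted_risk
  }
  out
}

#' Fit the canonical model set on a derivation landmark dataset
#'
#' Convenience wrapper: fits sex-specific super landmark Cox models for
#' each named covariate specification.
#'
#' @param records derivation landmark dataset (both sexes).
#' @param model_names subset of `names(canonical_model_specs())`.
#' @return named list; each element is `list(M = , F = )` of
#'   `lmv_cox_fit` objects.
#' @export
fit_model_set <- function(records, model_names = c("last", "mean", "current",
                                                   "last_sd", "mean_sd",
                                                   "current_sd")) {
  specs <- canonical_model_specs()
  unknown <- setdiff(model_names, names(specs))
  if (length(unknown))
    stop("unknown model name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  sd_records <- records[stats::complete.cases(
    records[paste0(tolower(RISK_FACTORS), "_sd")]), , drop = FALSE]
  out <- list()
  for (nm in model_names) {
    spec <- specs[[nm]]
    rec <- if (length(spec$include_sd)) sd_records else records
    out[[nm]] <- list(M = fit_super_landmark_cox(rec, spec, "M"),
                      F = fit_super_landmark_cox(rec, spec, "F"))
  }
  out
}

#' Compare fitted models on a validation landmark dataset
#'
#' Predicts w-year risk on the validation records for every fitted model,
#' and reports Harrell's C-index and the IPCW Brier score with their
#' differences against a referent model, with cluster-bootstrap
#' percentile confidence intervals (subjects resampled with all their
#' landmark records). When any compared model uses within-person SDs, all
#' models are evaluated on the records with all four SDs present so the
#' comparisons stay paired.
#'
#' @param records validation landmark dataset.
#' @param fits named list of per-sex fit pairs, as from [fit_model_set()].
#' @param w horizon (years).
#' @param referent model name differences are taken against.
#' @param n_boot bootstrap replicates (0 disables CIs).
#' @param boot_seed seed for the bootstrap.
#' @return data frame, one row per model, mirroring the comparison table
#'   layout: C-index and Brier score with CIs and differences with CIs.
#' @export
compare_models <- function(records, fits, w = 10, referent = "last",
                           n_boot = 200, boot_seed = 1L) {
  stopifnot(referent %in% names(fits))
  any_sd <- any(vapply(fits, function(f) length(f$M$spec$include_sd) > 0,
                       logical(1)))
  rec <- records
  if (any_sd)
    rec <- rec[stats::complete.cases(
      rec[paste0(tolower(RISK_FACTORS), "_sd")]), , drop = FALSE]
  if (nrow(rec) == 0) stop("no validation records to compare on", call. = FALSE)

  preds <- lapply(fits, function(f) predict_risk_by_sex(f, rec, w))
  tm <- rec$follow_time; ev <- rec$event_in_horizon

  point <- lapply(preds, function(p)
    c(c_index = harrell_c(p, tm, ev),
      brier = brier_score(p, tm, ev, w = w)))

  boots <- NULL
  if (n_boot > 0) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()))
    set.seed(boot_seed)
    idx_by_subj <- split(seq_len(nrow(rec)), rec$subject_id)
    subj <- names(idx_by_subj)
    boots <- array(NA_real_, c(n_boot, length(fits), 2),
                   dimnames = list(NULL, names(fits), c("c_index", "brier")))
    for (b in seq_len(n_boot)) {
      take <- sample(subj, length(subj), replace = TRUE)
      ix <- unlist(idx_by_subj[take], use.names = FALSE)
      tb <- tm[ix]; eb <- ev[ix]
      for (m in names(fits)) {
        pb <- preds[[m]][ix]
        boots[b, m, "c_index"] <- tryCatch(harrell_c(pb, tb, eb),
                                           error = function(e) NA_real_)
        boots[b, m, "brier"] <- tryCatch(brier_score(pb, tb, eb, w = w),
                                         error = function(e) NA_real_)
      }
    }
  }

  ci <- function(v) {
    if (is.null(v) || all(is.na(v))) return(c(NA_real_, NA_real_))
    stats::quantile(v, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  }
  rows <- lapply(names(fits), function(m) {
    cb <- if (!is.null(boots)) boots[, m, "c_index"] else NULL
    bb <- if (!is.null(boots)) boots[, m, "brier"] else NULL
    cdb <- if (!is.null(boots)) boots[, m, "c_index"] - boots[, referent, "c_index"] else NULL
    bdb <- if (!is.null(boots)) boots[, m, "brier"] - boots[, referent, "brier"] else NULL
    cci <- ci(cb); bci <- ci(bb); cdci <- ci(cdb); bdci <- ci(bdb)
    data.frame(
      model = m,
      c_index = point[[m]]["c_index"],
      c_lo = cci[1], c_hi = cci[2],
      c_diff = point[[m]]["c_index"] - point[[referent]]["c_index"],
      c_diff_lo = cdci[1], c_diff_hi = cdci[2],
      brier = point[[m]]["brier"],
      brier_lo = bci[1], brier_hi = bci[2],
      brier_diff = point[[m]]["brier"] - point[[referent]]["brier"],
      brier_diff_lo = bdci[1], brier_diff_hi = bdci[2],
      n = nrow(rec), n_events = sum(ev), row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$model <- as.character(out$model)
  attr(out, "referent") <- referent
  out
}

#' Scaled Schoenfeld residual check of proportional hazards
#'
#' Convenience wrapper around [survival::cox.zph()] refitted on the
#' stored design; reports the global and per-term slope tests. A
#' diagnostic aid, not a gate.
#'
#' @param records landmark records of one sex.
#' @param spec a [covariate_spec()].
#' @param sex `"M"` or `"F"`.
#' @return the `cox.zph` table as a data frame.
#' @export
ph_diagnostic <- function(records, spec, sex) {
  rec <- records[records$sex == sex, , drop = FALSE]
  X <- build_cox_design(rec, spec)
  keep <- apply(X, 2, function(col) stats::var(col) > 0)
  df <- as.data.frame(X[, keep, drop = FALSE])
  df$.time <- rec$follow_time
  df$.event <- rec$event_in_horizon
  form <- stats::reformulate(colnames(X)[keep],
                             response = quote(survival::Surv(.time, .event)))
  fit <- survival::coxph(form, data = df, ties = "efron")
  zp <- survival::cox.zph(fit, transform = "km", global = TRUE)
  as.data.frame(zp$table)
}
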