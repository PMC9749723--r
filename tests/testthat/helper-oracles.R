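# Independent reference implementations ("oracles") used to verify the
# package's metrics, survival machinery and BLUP algebra. These are
# written from the mathematical definitions with no shared code paths:
# pair enumeration, hand product-limit estimators, direct optimisation of
# the partial likelihood and joint-Gaussian conditioning.

# --- concordance by full pair enumeration ------------------------------
# A pair (i, j) is comparable iff the member with the strictly shorter
# follow-up time had an event; concordant when that member carries the
# higher prediction; prediction ties count 1/2.
oracle_concordance <- function(pred, time, event) {
  n <- length(pred)
  conc <- 0; total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (time[i] == time[j]) next
      short <- if (time[i] < time[j]) i else j
      long <- if (short == i) j else i
      if (event[short] != 1) next
      total <- total + 1
      if (pred[short] > pred[long]) conc <- conc + 1
      else if (pred[short] == pred[long]) conc <- conc + 0.5
    }
  }
  if (total == 0) return(NA_real_)
  conc / total
}

# --- product-limit estimators by hand ----------------------------------
# S(t) of the indicated event type; `minus` gives the left limit S(t-).
oracle_km <- function(time, status, t, minus = FALSE) {
  dt <- sort(unique(time[status == 1]))
  s <- 1
  for (tj in dt) {
    if (if (minus) tj >= t else tj > t) break
    d <- sum(time == tj & status == 1)
    r <- sum(time >= tj)
    s <- s * (1 - d / r)
  }
  s
}

# --- IPCW Brier score from the Graf definition -------------------------
oracle_brier <- function(pred, time, event, w) {
  n <- length(pred)
  G <- function(t, minus) oracle_km(time, 1 - event, t, minus = minus)
  total <- 0
  for (i in seq_len(n)) {
    if (event[i] == 1 && time[i] <= w) {
      total <- total + (pred[i] - 1)^2 / G(time[i], minus = TRUE)
    } else if (time[i] >= w) {
      total <- total + pred[i]^2 / G(w, minus = TRUE)
    }
    # censored strictly before w: weight zero
  }
  total / n
}

# --- continuous NRI from the definition --------------------------------
oracle_nri <- function(pred_new, pred_old, time, event, w) {
  up <- pred_new > pred_old
  down <- pred_new < pred_old
  pe <- function(sel) {
    if (!any(sel)) return(0)
    1 - oracle_km(time[sel], event[sel], w)
  }
  pe_all <- 1 - oracle_km(time, event, w)
  p_up <- mean(up); p_down <- mean(down)
  nri_e <- (p_up * pe(up) - p_down * pe(down)) / pe_all
  nri_ne <- (p_down * (1 - pe(down)) - p_up * (1 - pe(up))) / (1 - pe_all)
  list(nri = nri_e + nri_ne, nri_events = nri_e, nri_nonevents = nri_ne)
}

# --- one-covariate Cox fit by direct optimisation ----------------------
# Breslow form of the partial log-likelihood; with no tied event times it
# coincides with the Efron form used by the package.
oracle_cox_beta <- function(time, event, x, interval = c(-10, 10)) {
  loglik <- function(b) {
    ll <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      ll <- ll + x[i] * b - log(sum(exp(x[risk] * b)))
    }
    ll
  }
  stats::optimize(loglik, interval = interval, maximum = TRUE,
                  tol = 1e-10)$maximum
}

# Nelson-Aalen cumulative hazard by hand, evaluated at t
oracle_nelson_aalen <- function(time, event, t) {
  dt <- sort(unique(time[event == 1]))
  h <- 0
  for (tj in dt) {
    if (tj > t) break
    h <- h + sum(time == tj & event == 1) / sum(time >= tj)
  }
  h
}

# --- BLUP by joint-Gaussian conditioning -------------------------------
# E[b | y] = G Z' (Z G Z' + R)^{-1} (y - X beta), computed on the
# standardised scale of the fit, then mapped to natural-scale current
# value and slope at landmark age s exactly as the package documents.
oracle_blup_current_slope <- function(fit, history, s) {
  nfac <- length(landmarkvar::RISK_FACTORS)
  h <- history[history$age >= 30 & history$age < s, , drop = FALSE]
  bmean <- numeric(2 * nfac)
  if (nrow(h)) {
    kidx <- match(h$factor, landmarkvar::RISK_FACTORS)
    u <- h$age - 50
    ystd <- (h$value - fit$center[kidx]) / fit$scale[kidx]
    X <- matrix(0, nrow(h), 3 * nfac)
    Z <- matrix(0, nrow(h), 2 * nfac)
    for (j in seq_len(nrow(h))) {
      X[j, 3 * (kidx[j] - 1) + 1:3] <- c(1, u[j], u[j]^2)
      Z[j, 2 * (kidx[j] - 1) + 1:2] <- c(1, u[j])
    }
    R <- diag(fit$sigma2[kidx], nrow(h))
    V <- Z %*% fit$G %*% t(Z) + R
    bmean <- drop(fit$G %*% t(Z) %*% solve(V, ystd - drop(X %*% fit$beta)))
  }
  us <- s - 50
  out <- data.frame(factor = landmarkvar::RISK_FACTORS,
                    est_current = NA_real_, est_slope = NA_real_)
  for (ki in seq_len(nfac)) {
    bc <- fit$beta[3 * (ki - 1) + 1:3]
    cur <- bc[1] + bc[2] * us + bc[3] * us^2 +
      bmean[2 * (ki - 1) + 1] + bmean[2 * (ki - 1) + 2] * us
    out$est_current[ki] <- fit$center[ki] + fit$scale[ki] * cur
    out$est_slope[ki] <- fit$scale[ki] * (bc[2] + 2 * bc[3] * us +
                                            bmean[2 * (ki - 1) + 2])
  }
  out
}

# a synthetic lmv_mixed_fit with known parameters (no EM involved)
make_known_mixed_fit <- function(sex = "M") {
  nfac <- length(landmarkvar::RISK_FACTORS)
  center <- c(SBP = 140, TC = 5, HDL = 1.2, HBA1C = 7.5)
  scale_ <- c(SBP = 15, TC = 1, HDL = 0.3, HBA1C = 1.4)
  beta <- rep(c(0.1, 0.02, -0.0005), nfac)
  names(beta) <- as.vector(t(outer(tolower(landmarkvar::RISK_FACTORS),
                                   c("_int", "_age", "_age2"), paste0)))
  set.seed(42)
  A <- matrix(rnorm((2 * nfac)^2, sd = 0.05), 2 * nfac)
  G <- crossprod(A) + diag(rep(c(0.6, 0.004), nfac))
  sigma2 <- c(SBP = 0.35, TC = 0.3, HDL = 0.32, HBA1C = 0.28)
  structure(list(sex = sex, spec = landmarkvar::mixed_model_spec(),
                 center = center, scale = scale_, beta = beta, G = G,
                 sigma2 = sigma2, loglik = 0, iterations = 0,
                 converged = TRUE, ridged = FALSE,
                 n_subjects = 0, n_obs = 0),
            class = "lmv_mixed_fit")
}

# --- hand-built cohorts ------------------------------------------------
# Assemble an lmv_cohort directly from explicit tables, for tests whose
# expected values are worked out by hand.
make_manual_cohort <- function(subjects, measurements = NULL, smoking = NULL) {
  defaults <- data.frame(
    subject_id = subjects$subject_id,
    practice_id = 1L, sex = "M", ethnicity = "Unspecified",
    entry_age = 40, exit_age = 85, diabetes_dx_age = 40,
    event_indicator = 0L, af_dx_age = NA_real_, bp_med_first_age = NA_real_)
  for (col in names(subjects)) defaults[[col]] <- subjects[[col]]
  if (is.null(measurements))
    measurements <- data.frame(subject_id = integer(), factor = character(),
                               age = numeric(), value = numeric())
  if (is.null(smoking))
    smoking <- data.frame(subject_id = defaults$subject_id,
                          age = defaults$entry_age, current_smoker = 0L)
  structure(list(subjects = defaults, measurements = measurements,
                 smoking = smoking, truth = NULL), class = "lmv_cohort")
}

# measurements for one subject: one row per (factor, age, value) triple
meas_rows <- function(subject_id, factor, age, value) {
  data.frame(subject_id = subject_id, factor = factor, age = age,
             value = value)
}

# small simulated cohort memoised across tests in one file run
small_cohort <- local({
  cache <- list()
  function(n = 300, seed = 7L, ...) {
    key <- paste(n, seed, length(list(...)), sep = "_")
    if (is.null(cache[[key]]))
      cache[[key]] <<- landmarkvar::generate_cohort(
        landmarkvar::sim_config(n_subjects = n, seed = seed, ...))
    cache[[key]]
  }
})

# landmark records with fully populated covariates for direct Cox tests:
# deterministic covariates, exponential outcome times
make_cox_records <- function(n = 250, seed = 11, beta_sbp = 0.03,
                             two_practices = TRUE) {
  set.seed(seed)
  fkey <- tolower(landmarkvar::RISK_FACTORS)
  rec <- data.frame(
    subject_id = seq_len(n),
    practice_id = if (two_practices) rep(1:5, length.out = n) else 1L,
    sex = "M",
    ethnicity = sample(c("Unspecified", "White"), n, replace = TRUE),
    landmark_age = sample(55:65, n, replace = TRUE))
  for (k in fkey) {
    base <- switch(k, sbp = rnorm(n, 140, 15), tc = rnorm(n, 5, 1),
                   hdl = rnorm(n, 1.2, 0.25), hba1c = rnorm(n, 7.5, 1.2))
    rec[[paste0(k, "_last")]] <- base
    rec[[paste0(k, "_mean")]] <- base + rnorm(n, 0, 0.01)
    rec[[paste0(k, "_sd")]] <- abs(rnorm(n, 1, 0.2))
    rec[[paste0(k, "_n")]] <- 3L
    rec[[paste0(k, "_current")]] <- base
    rec[[paste0(k, "_slope")]] <- rnorm(n, 0, 0.1)
  }
  rec$smoking_last <- rbinom(n, 1, 0.3)
  rec$bp_med_ever <- rbinom(n, 1, 0.5)
  rec$af_ever <- rbinom(n, 1, 0.05)
  rec$diabetes_duration <- runif(n, 0, 15)
  lp <- beta_sbp * (rec$sbp_last - 140)
  t_ev <- rexp(n, rate = 0.08 * exp(lp))
  t_cens <- rexp(n, rate = 0.05)
  rec$follow_time <- pmin(t_ev, t_cens, 10)
  rec$event_in_horizon <- as.integer(t_ev <= pmin(t_cens, 10))
  rec
}
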