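#' Continuous risk-factor names used throughout the package
#'
#' The four repeatedly measured continuous predictors: systolic blood
#' pressure (mmHg), total cholesterol (mmol/L), HDL cholesterol (mmol/L)
#' and HbA1c (%).
#'
#' @export
RISK_FACTORS <- c("SBP", "TC", "HDL", "HBA1C")

#' Binary / duration covariates entering the simulated hazard
#' @keywords internal
BINARY_TERMS <- c("smoking", "bp_med", "af", "diabetes_duration")

#' Simulation configuration for the synthetic longitudinal cohort
#'
#' Defines every parameter of the synthetic electronic-health-record
#' generator: the visit processes, person-specific biomarker trajectories,
#' person-specific within-person variability, binary covariate dynamics,
#' and the age-scale Weibull-baseline hazard through which the true
#' current values and the within-person SDs act on cardiovascular risk.
#'
#' Trajectories are linear in age: for subject i and factor k the latent
#' mean at age a is
#' \deqn{\mu_{ik}(a) = \alpha_k + \beta_k (a - 50) + b_{0ik} + b_{1ik}(a - 50),}
#' with `(b0, b1)` drawn from `random_effects_cov[[k]]` and observed values
#' equal to the latent mean plus Normal noise with person-specific SD
#' `sigma_ik ~ logNormal(within_person_sd_law[[k]])`. The hazard at age a is
#' \deqn{\lambda(a) = \lambda_0(a) \exp\{\sum_k \beta^c_k \mu_{ik}(a)
#'   + \sum_k \gamma_k \sigma_{ik} + \text{binary terms}\}}
#' with a Weibull baseline \eqn{\lambda_0}.
#'
#' @param n_subjects number of subjects.
#' @param n_practices number of general practices subjects are nested in.
#' @param seed integer root seed; fully determines the cohort.
#' @param age_entry_range two ages (years); entry age drawn uniformly.
#' @param visit_rate named vector, expected measurements per year per factor.
#' @param fixed_trajectory named list, per factor `c(intercept, slope)`:
#'   population value at age 50 and change per year.
#' @param random_effects_cov named list of 2x2 PSD covariance matrices of
#'   the person-specific (intercept, slope) deviations.
#' @param within_person_sd_law named list, per factor `c(meanlog, sdlog)`
#'   of the log-normal law for the person-specific residual SD.
#' @param hazard_baseline `c(shape, scale)` of the age-scale Weibull
#'   baseline hazard.
#' @param beta_current named vector, log-hazard per unit of the true
#'   current value of each factor.
#' @param gamma_sd named vector, log-hazard per unit of the person-specific
#'   within-person SD of each factor.
#' @param beta_binary named vector, log-hazards for `smoking`, `bp_med`,
#'   `af` and `diabetes_duration` (the latter per year of duration).
#' @param censoring_rate exponential dropout rate per year (0 = none).
#' @param recording_years_before_entry length (years) of the pre-entry
#'   recording window: measurements exist from
#'   `max(30, entry_age - recording_years_before_entry)` onwards,
#'   emulating registration-limited history in primary-care databases.
#' @param admin_exit_age administrative exit age for landmarking (years);
#'   follow-up is retained for `horizon_extension` further years so that
#'   the last landmark age keeps a full prediction window.
#' @param horizon_extension years of follow-up retained past
#'   `admin_exit_age` (default 10).
#' @param lp_bound reject configurations whose realised linear predictor
#'   exceeds this absolute bound (guards against hazard overflow).
#' @param sex_male_prob probability a subject is male.
#' @param ethnicity_probs named probability vector over the six ethnicity
#'   categories.
#' @param diabetes_dx_mean,diabetes_dx_sd Normal law for age at type-2
#'   diabetes diagnosis (years), truncated to plausible ages.
#' @param smoking_init_prob probability of being a smoker at age 30.
#' @param smoking_start_rate,smoking_quit_rate yearly transition
#'   probabilities of the persistent smoking state.
#' @param smoking_obs_rate expected smoking-status observations per year.
#' @param af_prob,bp_med_prob lifetime probabilities of an atrial
#'   fibrillation diagnosis / a first antihypertensive prescription.
#' @param grid_step age step (years) of the piecewise-constant hazard grid
#'   used for event-time inversion.
#'
#' @return an object of class `lmv_sim_config` (a validated list).
#' @export
sim_config <- function(n_subjects = 2000,
                       n_practices = 60,
                       seed = 1L,
                       age_entry_range = c(40, 80),
                       visit_rate = c(SBP = 2.0, TC = 1.0, HDL = 0.9, HBA1C = 1.2),
                       fixed_trajectory = list(
                         SBP   = c(138,  0.35),
                         TC    = c(5.2, -0.015),
                         HDL   = c(1.25, 0.002),
                         HBA1C = c(7.6,  0.02)),
                       random_effects_cov = list(
                         SBP   = diag(c(14, 0.30)^2),
                         TC    = diag(c(1.0, 0.030)^2),
                         HDL   = diag(c(0.28, 0.008)^2),
                         HBA1C = diag(c(1.5, 0.060)^2)),
                       within_person_sd_law = list(
                         SBP   = c(log(9.0), 0.40),
                         TC    = c(log(0.60), 0.35),
                         HDL   = c(log(0.12), 0.35),
                         HBA1C = c(log(0.70), 0.40)),
                       hazard_baseline = c(shape = 5, scale = 198),
                       beta_current = c(SBP = 0.012, TC = 0.12, HDL = -0.5, HBA1C = 0.10),
                       gamma_sd = c(SBP = 0.035, TC = 0.12, HDL = 0.5, HBA1C = 0.12),
                       beta_binary = c(smoking = 0.35, bp_med = 0.15, af = 0.55,
                                       diabetes_duration = 0.02),
                       censoring_rate = 0.06,
                       recording_years_before_entry = 5,
                       admin_exit_age = 85,
                       horizon_extension = 10,
                       lp_bound = 30,
                       sex_male_prob = 0.61,
                       ethnicity_probs = c(White = 0.35, Asian = 0.027, Black = 0.018,
                                           Mixed = 0.004, Other = 0.009,
                                           Unspecified = 0.592),
                       diabetes_dx_mean = 59.3,
                       diabetes_dx_sd = 12,
                       smoking_init_prob = 0.38,
                       smoking_start_rate = 0.005,
                       smoking_quit_rate = 0.02,
                       smoking_obs_rate = 1.0,
                       af_prob = 0.05,
                       bp_med_prob = 0.55,
                       grid_step = 0.1) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_practices = as.integer(n_practices),
    seed = as.integer(seed), age_entry_range = age_entry_range,
    visit_rate = visit_rate, fixed_trajectory = fixed_trajectory,
    random_effects_cov = random_effects_cov,
    within_person_sd_law = within_person_sd_law,
    hazard_baseline = hazard_baseline, beta_current = beta_current,
    gamma_sd = gamma_sd, beta_binary = beta_binary,
    censoring_rate = censoring_rate,
    recording_years_before_entry = recording_years_before_entry,
    admin_exit_age = admin_exit_age,
    horizon_extension = horizon_extension, lp_bound = lp_bound,
    sex_male_prob = sex_male_prob, ethnicity_probs = ethnicity_probs,
    diabetes_dx_mean = diabetes_dx_mean, diabetes_dx_sd = diabetes_dx_sd,
    smoking_init_prob = smoking_init_prob,
    smoking_start_rate = smoking_start_rate,
    smoking_quit_rate = smoking_quit_rate,
    smoking_obs_rate = smoking_obs_rate,
    af_prob = af_prob, bp_med_prob = bp_med_prob, grid_step = grid_step)
  class(cfg) <- "lmv_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_subjects >= 1, cfg$n_practices >= 1)
  if (any(cfg$visit_rate <= 0))
    stop("visit_rate must be positive for every factor", call. = FALSE)
  if (cfg$censoring_rate < 0)
    stop("censoring_rate must be non-negative", call. = FALSE)
  if (any(cfg$hazard_baseline < 0))
    stop("hazard_baseline shape and scale must be non-negative", call. = FALSE)
  for (k in RISK_FACTORS) {
    for (fld in c("visit_rate", "beta_current", "gamma_sd"))
      if (is.na(cfg[[fld]][k]))
        stop(sprintf("config field '%s' is missing factor '%s'", fld, k),
             call. = FALSE)
    G <- cfg$random_effects_cov[[k]]
    if (is.null(G) || !isTRUE(all.equal(G, t(G))) || any(eigen(G, only.values = TRUE)$values < -1e-8))
      stop(sprintf("random_effects_cov for '%s' is not symmetric PSD", k),
           call. = FALSE)
  }
  if (any(is.na(cfg$beta_binary[BINARY_TERMS])))
    stop("beta_binary must name smoking, bp_med, af and diabetes_duration",
         call. = FALSE)
  if (abs(sum(cfg$ethnicity_probs) - 1) > 1e-6)
    stop("ethnicity_probs must sum to 1", call. = FALSE)
  invisible(cfg)
}

# Draw n rows from N(0, Sigma) via eigendecomposition (tolerates singular
# PSD matrices, which chol() does not).
mvn_draw <- function(n, Sigma) {
  p <- nrow(Sigma)
  e <- eigen(Sigma, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  z <- matrix(stats::rnorm(n * p), n, p)
  z %*% (t(e$vectors) * sqrt(lam))
}

ETHNICITY_LEVELS <- c("White", "Asian", "Black", "Mixed", "Other", "Unspecified")

#' Generate a synthetic longitudinal diabetes cohort
#'
#' Draws a complete cohort — subject attributes, irregular per-factor
#' measurement series, smoking observation histories and survival
#' outcomes — from the data-generating model described in
#' [sim_config()]. Event ages are obtained by inverting the cumulative
#' hazard on the age scale with a piecewise-constant covariate
#' approximation on a `grid_step`-year grid. All randomness flows from
#' `config$seed` through deterministic per-subject substreams, so the same
#' configuration always yields a byte-identical cohort.
#'
#' @param config an [sim_config()] object.
#' @return an object of class `lmv_cohort`: a list with data frames
#'   `subjects`, `measurements`, `smoking` and a `truth` list holding the
#'   person-level random effects, within-person SDs and smoking state
#'   paths (ground truth for parameter-recovery tests; never used by the
#'   inference modules).
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  cfg <- config
  n <- cfg$n_subjects
  cap_age <- cfg$admin_exit_age + cfg$horizon_extension

  set.seed(cfg$seed)
  subject_seed <- sample.int(.Machine$integer.max - 1L, n)
  practice_id <- sample.int(cfg$n_practices, n, replace = TRUE)
  sex <- ifelse(stats::runif(n) < cfg$sex_male_prob, "M", "F")
  ethnicity <- sample(ETHNICITY_LEVELS, n, replace = TRUE,
                      prob = cfg$ethnicity_probs[ETHNICITY_LEVELS])

  entry_v <- exit_v <- dx_v <- af_v <- bp_v <- numeric(n)
  event_v <- integer(n)
  meas_rows <- vector("list", n)
  smoke_rows <- vector("list", n)
  re_b0 <- re_b1 <- re_sig <- matrix(0, n, length(RISK_FACTORS),
                                     dimnames = list(NULL, RISK_FACTORS))
  state_mat <- NULL  # n x length(state_ages), filled below
  wb_shape <- cfg$hazard_baseline[["shape"]]
  wb_scale <- cfg$hazard_baseline[["scale"]]
  state_ages <- seq(30, ceiling(cap_age))
  state_mat <- matrix(0L, n, length(state_ages))

  for (i in seq_len(n)) {
    set.seed(subject_seed[i])
    entry <- stats::runif(1, cfg$age_entry_range[1], cfg$age_entry_range[2])

    # age at diabetes diagnosis: mostly before entry, sometimes after
    repeat {
      if (stats::runif(1) < 0.7) dx <- entry - stats::rexp(1, 1 / 6)
      else dx <- entry + stats::rexp(1, 1 / 4)
      dx <- dx + stats::rnorm(1, 0, 2)
      if (dx >= 30 && dx <= cfg$admin_exit_age - 1) break
    }

    # person-specific trajectory deviations and within-person SDs
    b <- matrix(0, length(RISK_FACTORS), 2,
                dimnames = list(RISK_FACTORS, c("b0", "b1")))
    sig <- numeric(length(RISK_FACTORS)); names(sig) <- RISK_FACTORS
    for (k in RISK_FACTORS) {
      b[k, ] <- mvn_draw(1, cfg$random_effects_cov[[k]])
      law <- cfg$within_person_sd_law[[k]]
      sig[k] <- stats::rlnorm(1, law[1], law[2])
    }

    # persistent smoking state, yearly transitions from age 30
    st <- integer(length(state_ages))
    st[1] <- as.integer(stats::runif(1) < cfg$smoking_init_prob)
    for (j in seq_along(state_ages)[-1]) {
      p <- if (st[j - 1] == 1L) 1 - cfg$smoking_quit_rate else cfg$smoking_start_rate
      st[j] <- as.integer(stats::runif(1) < p)
    }

    af_age <- if (stats::runif(1) < cfg$af_prob) stats::runif(1, 30, 90) else NA_real_
    bp_age <- if (stats::runif(1) < cfg$bp_med_prob) stats::runif(1, 35, 85) else NA_real_

    # hazard on the age grid from entry to the follow-up cap
    grid <- seq(entry, cap_age, by = cfg$grid_step)
    lp <- rep(sum(cfg$gamma_sd[RISK_FACTORS] * sig), length(grid))
    for (k in RISK_FACTORS) {
      tr <- cfg$fixed_trajectory[[k]]
      mu <- tr[1] + tr[2] * (grid - 50) + b[k, 1] + b[k, 2] * (grid - 50)
      lp <- lp + cfg$beta_current[[k]] * mu
    }
    smoke_at <- st[pmin(pmax(floor(grid) - 29, 1), length(state_ages))]
    lp <- lp + cfg$beta_binary[["smoking"]] * smoke_at
    if (!is.na(bp_age)) lp <- lp + cfg$beta_binary[["bp_med"]] * (grid >= bp_age)
    if (!is.na(af_age)) lp <- lp + cfg$beta_binary[["af"]] * (grid >= af_age)
    lp <- lp + cfg$beta_binary[["diabetes_duration"]] * pmax(0, grid - dx)
    if (max(abs(lp)) > cfg$lp_bound) {
      a_worst <- grid[which.max(abs(lp))]
      contrib <- c(
        vapply(RISK_FACTORS, function(k) {
          tr <- cfg$fixed_trajectory[[k]]
          mu <- tr[1] + tr[2] * (a_worst - 50) + b[k, 1] + b[k, 2] * (a_worst - 50)
          abs(cfg$beta_current[[k]] * mu)
        }, numeric(1)),
        abs(cfg$gamma_sd[RISK_FACTORS] * sig))
      names(contrib) <- c(paste0("beta_current.", RISK_FACTORS),
                          paste0("gamma_sd.", RISK_FACTORS))
      worst <- names(which.max(contrib))
      stop(sprintf(paste0("linear predictor exceeds bound %g (overflow guard); ",
                          "largest contribution from coefficient on '%s'"),
                   cfg$lp_bound, worst), call. = FALSE)
    }
    haz <- if (wb_scale > 0)
      (wb_shape / wb_scale) * (grid / wb_scale)^(wb_shape - 1) * exp(lp)
    else rep(0, length(grid))

    # invert the cumulative hazard (piecewise-constant on the grid)
    E <- stats::rexp(1)
    cumhaz <- c(0, cumsum(haz[-length(haz)] * cfg$grid_step))
    event_age <- NA_real_
    idx <- which(cumhaz >= E)[1]
    if (!is.na(idx)) {
      j <- idx - 1L
      event_age <- grid[j] + (E - cumhaz[j]) / haz[j]
    } else if (cumhaz[length(cumhaz)] + haz[length(haz)] * cfg$grid_step >= E) {
      j <- length(grid)
      event_age <- grid[j] + (E - cumhaz[j]) / haz[j]
      if (event_age > cap_age) event_age <- NA_real_
    }

    dropout_age <- if (cfg$censoring_rate > 0)
      entry + stats::rexp(1, cfg$censoring_rate) else Inf
    exit_age <- min(event_age, dropout_age, cap_age, na.rm = TRUE)
    event <- as.integer(!is.na(event_age) && event_age <= min(dropout_age, cap_age))
    if (event == 1L) exit_age <- event_age
    dx <- min(dx, exit_age)  # diagnosis cannot postdate exit

    # irregular measurement visits per factor over the recording window
    hist_start <- max(30, entry - cfg$recording_years_before_entry)
    mk_fac <- character(0); mk_age <- numeric(0); mk_val <- numeric(0)
    for (ki in seq_along(RISK_FACTORS)) {
      k <- RISK_FACTORS[ki]
      span <- exit_age - hist_start
      nv <- if (span > 0) stats::rpois(1, cfg$visit_rate[[k]] * span) else 0L
      if (nv > 0) {
        ages <- sort(unique(stats::runif(nv, hist_start, exit_age)))
        tr <- cfg$fixed_trajectory[[k]]
        mu <- tr[1] + tr[2] * (ages - 50) + b[k, 1] + b[k, 2] * (ages - 50)
        vals <- mu + stats::rnorm(length(ages), 0, sig[k])
        mk_fac <- c(mk_fac, rep(k, length(ages)))
        mk_age <- c(mk_age, ages); mk_val <- c(mk_val, vals)
      }
    }
    if (length(mk_age))
      meas_rows[[i]] <- list(fac = mk_fac, age = mk_age, val = mk_val)

    # smoking observations at their own visit process
    ns <- stats::rpois(1, cfg$smoking_obs_rate * (exit_age - hist_start))
    if (ns > 0) {
      sa <- sort(unique(stats::runif(ns, hist_start, exit_age)))
      obs <- st[pmin(pmax(floor(sa) - 29, 1), length(state_ages))]
      smoke_rows[[i]] <- list(age = sa, obs = obs)
    }

    entry_v[i] <- entry; exit_v[i] <- exit_age; dx_v[i] <- dx
    event_v[i] <- event
    af_v[i] <- if (is.na(af_age)) NA_real_ else af_age
    bp_v[i] <- if (is.na(bp_age)) NA_real_ else bp_age
    re_b0[i, ] <- b[, 1]; re_b1[i, ] <- b[, 2]; re_sig[i, ] <- sig
    state_mat[i, ] <- st
  }

  subjects <- data.frame(
    subject_id = seq_len(n), practice_id = practice_id, sex = sex,
    ethnicity = ethnicity, entry_age = entry_v, exit_age = exit_v,
    diabetes_dx_age = dx_v, event_indicator = event_v,
    af_dx_age = af_v, bp_med_first_age = bp_v)
  m_len <- vapply(meas_rows, function(x) if (is.null(x)) 0L else length(x$age),
                  integer(1))
  measurements <- if (sum(m_len) > 0) data.frame(
    subject_id = rep(seq_len(n), m_len),
    factor = unlist(lapply(meas_rows, `[[`, "fac")),
    age = unlist(lapply(meas_rows, `[[`, "age")),
    value = unlist(lapply(meas_rows, `[[`, "val")))
  else data.frame(subject_id = integer(), factor = character(),
                  age = numeric(), value = numeric())
  s_len <- vapply(smoke_rows, function(x) if (is.null(x)) 0L else length(x$age),
                  integer(1))
  smoking <- if (sum(s_len) > 0) data.frame(
    subject_id = rep(seq_len(n), s_len),
    age = unlist(lapply(smoke_rows, `[[`, "age")),
    current_smoker = unlist(lapply(smoke_rows, `[[`, "obs")))
  else data.frame(subject_id = integer(), age = numeric(),
                  current_smoker = integer())

  random_effects <- data.frame(
    subject_id = rep(seq_len(n), each = length(RISK_FACTORS)),
    factor = rep(RISK_FACTORS, n),
    b0 = as.vector(t(re_b0)), b1 = as.vector(t(re_b1)),
    sigma = as.vector(t(re_sig)))
  smoking_states <- data.frame(
    subject_id = rep(seq_len(n), each = length(state_ages)),
    age = rep(state_ages, n),
    state = as.vector(t(state_mat)))

  structure(list(
    subjects = subjects, measurements = measurements, smoking = smoking,
    truth = list(random_effects = random_effects,
                 smoking_states = smoking_states,
                 config = cfg)),
    class = "lmv_cohort")
}

#' @export
print.lmv_cohort <- function(x, ...) {
  cat(sprintf("<lmv_cohort> %d subjects, %d practices, %d measurements, %d events\n",
              nrow(x$subjects), length(unique(x$subjects$practice_id)),
              nrow(x$measurements), sum(x$subjects$event_indicator)))
  invisible(x)
}

#' True latent current value of a factor at a given age
#'
#' Evaluates the data-generating trajectory \eqn{\mu_{ik}(a)} for given
#' subjects from the stored ground truth. Used only by tests and designed
#' experiments, never by the inference modules.
#'
#' @param cohort an `lmv_cohort` with ground truth.
#' @param subject_ids vector of subject ids.
#' @param factor one of `RISK_FACTORS`.
#' @param age age (years), scalar or vector matching `subject_ids`.
#' @return numeric vector of latent current values.
#' @export
true_current_value <- function(cohort, subject_ids, factor, age) {
  cfg <- cohort$truth$config
  re <- cohort$truth$random_effects
  re <- re[re$factor == factor, ]
  idx <- match(subject_ids, re$subject_id)
  tr <- cfg$fixed_trajectory[[factor]]
  tr[1] + tr[2] * (age - 50) + re$b0[idx] + re$b1[idx] * (age - 50)
}

#' True w-year event probability at a landmark age
#'
#' Integrates the realised data-generating hazard over `(s, s + w]` for
#' every subject under follow-up and event-free at `s`, yielding the true
#' conditional event probability \eqn{1 - \exp(-\int_s^{s+w} \lambda(a) da)}.
#' This is the oracle predictor used to check calibration of the
#' evaluation machinery against the generator.
#'
#' @param cohort an `lmv_cohort` with ground truth.
#' @param s landmark age (years).
#' @param w horizon (years), default 10.
#' @return data frame with `subject_id` and `true_risk`.
#' @export
true_risk <- function(cohort, s, w = 10) {
  cfg <- cohort$truth$config
  sub <- cohort$subjects
  at_risk <- sub$entry_age <= s & s < sub$exit_age
  ids <- sub$subject_id[at_risk]
  if (length(ids) == 0)
    return(data.frame(subject_id = integer(), true_risk = numeric()))
  re <- cohort$truth$random_effects
  st <- cohort$truth$smoking_states
  wb_shape <- cfg$hazard_baseline[["shape"]]
  wb_scale <- cfg$hazard_baseline[["scale"]]
  grid <- seq(s, s + w, by = cfg$grid_step)
  grid <- grid[-length(grid)]  # left endpoints of the grid cells
  out <- numeric(length(ids))
  for (j in seq_along(ids)) {
    id <- ids[j]
    row <- sub[sub$subject_id == id, ]
    rei <- re[re$subject_id == id, ]
    lp <- rep(sum(cfg$gamma_sd[rei$factor] * rei$sigma), length(grid))
    for (k in RISK_FACTORS) {
      tr <- cfg$fixed_trajectory[[k]]
      ri <- rei[rei$factor == k, ]
      mu <- tr[1] + tr[2] * (grid - 50) + ri$b0 + ri$b1 * (grid - 50)
      lp <- lp + cfg$beta_current[[k]] * mu
    }
    sti <- st[st$subject_id == id, ]
    smoke_at <- sti$state[match(pmin(floor(grid), max(sti$age)), sti$age)]
    lp <- lp + cfg$beta_binary[["smoking"]] * smoke_at
    if (!is.na(row$bp_med_first_age))
      lp <- lp + cfg$beta_binary[["bp_med"]] * (grid >= row$bp_med_first_age)
    if (!is.na(row$af_dx_age))
      lp <- lp + cfg$beta_binary[["af"]] * (grid >= row$af_dx_age)
    lp <- lp + cfg$beta_binary[["diabetes_duration"]] * pmax(0, grid - row$diabetes_dx_age)
    haz <- if (wb_scale > 0)
      (wb_shape / wb_scale) * (grid / wb_scale)^(wb_shape - 1) * exp(lp)
    else rep(0, length(grid))
    out[j] <- 1 - exp(-sum(haz * cfg$grid_step))
  }
  data.frame(subject_id = ids, true_risk = out)
}
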