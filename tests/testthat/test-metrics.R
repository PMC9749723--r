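# Metrics are checked against hand-worked frozen examples and against
# independent oracle implementations (pair enumeration, hand
# product-limit estimators) on random instances.

test_that("harrell_c matches hand-worked frozen examples", {
  # [DERIVED] pred (0.2, 0.8, 0.5, 0.5), times (1, 4, 3, 6), events
  # (1, 1, 0, 0): comparable pairs are (1,2), (1,3), (1,4), (2,4);
  # only (2,4) is concordant, so C = 1/4.
  expect_equal(harrell_c(c(0.2, 0.8, 0.5, 0.5), c(1, 4, 3, 6), c(1, 1, 0, 0)),
               0.25)
  # perfect ranking
  expect_equal(harrell_c(c(0.9, 0.1, 0.5, 0.3), c(2, 8, 5, 10), c(1, 0, 1, 0)),
               1)
  # a prediction tie counts 1/2
  expect_equal(harrell_c(c(0.5, 0.5), c(1, 2), c(1, 0)), 0.5)
})

test_that("harrell_c handles tied event times under the strict convention", {
  # [DERIVED] times (2, 2, 5): the time-tied pair is not comparable;
  # remaining pairs (1,3) concordant and (2,3) discordant give C = 1/2.
  expect_equal(harrell_c(c(0.9, 0.1, 0.5), c(2, 2, 5), c(1, 1, 0)), 0.5)
})

test_that("harrell_c errors on degenerate inputs", {
  expect_error(harrell_c(0.5, 1, 1), "two records")
  expect_error(harrell_c(c(0.1, 0.9), c(1, 2), c(0, 0)), "no events")
  # single event with the longest follow-up: no comparable pairs
  expect_error(harrell_c(c(0.1, 0.9), c(1, 2), c(0, 1)), "no comparable pairs")
})

test_that("harrell_c agrees with pair enumeration on random instances", {
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(3:12, 1)
    time <- round(runif(n, 0.5, 12), 3)  # continuous, ties improbable
    event <- rbinom(n, 1, 0.6)
    pred <- round(runif(n), 2)           # prediction ties possible
    orc <- oracle_concordance(pred, time, event)
    if (is.na(orc)) {
      expect_error(harrell_c(pred, time, event), "no comparable|no events")
    } else {
      expect_equal(harrell_c(pred, time, event), orc, tolerance = 1e-10)
    }
  }
})

test_that("harrell_c agrees with enumeration when event times are tied", {
  set.seed(202)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    time <- sample(1:4, n, replace = TRUE)  # heavy ties
    event <- rbinom(n, 1, 0.6)
    pred <- round(runif(n), 1)
    orc <- oracle_concordance(pred, time, event)
    if (is.na(orc)) {
      expect_error(harrell_c(pred, time, event))
    } else {
      expect_equal(harrell_c(pred, time, event), orc, tolerance = 1e-10)
    }
  }
})

test_that("brier_score without censoring is the plain mean squared error", {
  # [DERIVED] no censoring before w = 10, so all weights are 1:
  # ((0.8-1)^2 + 0.2^2 + (0.6-1)^2 + 0.1^2) / 4 = 0.0625
  pred <- c(0.8, 0.2, 0.6, 0.1)
  time <- c(3, 12, 7, 12)
  event <- c(1, 0, 1, 0)
  expect_equal(brier_score(pred, time, event, w = 10), 0.0625)
  expect_equal(brier_score(pred, time, event, w = 10, ipcw = FALSE), 0.0625)
})

test_that("brier_score matches a hand-worked IPCW example", {
  # [DERIVED] censoring KM: drop at t = 4 (3 at risk) gives G = 2/3.
  # Weights: event at 2 -> 1/G(2-) = 1; censored at 4 before w -> 0;
  # event at 6 -> 1/G(6-) = 3/2; survivor -> 1/G(10-) = 3/2.
  # Score = (1*0.09 + 1.5*0.16 + 1.5*0.04) / 4 = 0.0975.
  pred <- c(0.7, 0.5, 0.6, 0.2)
  time <- c(2, 4, 6, 12)
  event <- c(1, 0, 1, 0)
  expect_equal(brier_score(pred, time, event, w = 10), 0.0975)
})

test_that("brier_score agrees with the Graf-definition oracle", {
  set.seed(303)
  for (rep in 1:40) {
    n <- sample(5:20, 1)
    time <- round(runif(n, 0.5, 14), 3)
    event <- rbinom(n, 1, 0.6)
    pred <- runif(n)
    g10 <- oracle_km(time, 1 - event, 10, minus = TRUE)
    if (g10 <= 0 && any(time >= 10 & !(event == 1 & time <= 10))) next
    expect_equal(brier_score(pred, time, event, w = 10),
                 oracle_brier(pred, time, event, 10), tolerance = 1e-10)
  }
})

test_that("unweighted brier_score uses only determinate-status records", {
  # [DERIVED] record 2 is censored at 5 < w, so only the event (0.5 vs 1)
  # and the survivor (0.9 vs 0) remain: ((0.5-1)^2 + 0.81) / 2 = 0.53
  expect_equal(brier_score(c(0.5, 0.2, 0.9), c(3, 5, 12), c(1, 0, 0),
                           w = 10, ipcw = FALSE), 0.53)
})

test_that("continuous_nri has the expected exact values and symmetry", {
  time <- c(2, 5, 12, 12, 12, 12)
  event <- c(1, 1, 0, 0, 0, 0)
  old <- rep(0.5, 6)
  new <- c(1, 1, 0, 0, 0, 0)  # perfect up/down movement
  # [DERIVED] all events up, all non-events down, no censoring:
  # NRI_e = 1, NRI_ne = 1, total 2.
  r <- continuous_nri(new, old, time, event, w = 10)
  expect_equal(r$nri_events, 1)
  expect_equal(r$nri_nonevents, 1)
  expect_equal(r$nri, 2)
  # identical predictions move nobody
  r0 <- continuous_nri(old, old, time, event, w = 10)
  expect_equal(r0$nri, 0)
  # swapping the models negates the index
  fwd <- continuous_nri(new, old, time, event, w = 10)
  bwd <- continuous_nri(old, new, time, event, w = 10)
  expect_equal(fwd$nri, -bwd$nri)
})

test_that("continuous_nri agrees with the definition oracle under censoring", {
  set.seed(404)
  for (rep in 1:25) {
    n <- sample(8:25, 1)
    time <- round(runif(n, 0.5, 14), 3)
    event <- rbinom(n, 1, 0.6)
    p_old <- runif(n); p_new <- runif(n)
    pe_all <- 1 - oracle_km(time, event, 10)
    if (pe_all <= 0 || pe_all >= 1) next
    got <- continuous_nri(p_new, p_old, time, event, w = 10)
    want <- oracle_nri(p_new, p_old, time, event, 10)
    expect_equal(got$nri, want$nri, tolerance = 1e-10)
    expect_equal(got$nri_events, want$nri_events, tolerance = 1e-10)
    expect_equal(got$nri_nonevents, want$nri_nonevents, tolerance = 1e-10)
  }
})

test_that("continuous_nri validates its inputs", {
  expect_error(continuous_nri(c(0.1, 0.2), 0.1, c(1, 2), c(1, 0)),
               "paired")
  expect_error(continuous_nri(c(0.1, 0.2), c(0.2, 0.1), c(12, 12), c(0, 0)),
               "degenerate")
})

test_that("calibration_slope recovers 1 for calibrated risks and 0.5 for doubled lp", {
  set.seed(505)
  n <- 4000
  lp <- rnorm(n, 0, 0.8)
  lam0 <- 0.05
  t_ev <- rexp(n, rate = lam0 * exp(lp))
  time <- pmin(t_ev, 10)
  event <- as.integer(t_ev <= 10)
  risk <- 1 - exp(-lam0 * 10 * exp(lp))        # true 10-year risk
  cs <- calibration_slope(risk, time, event)
  expect_equal(nrow(cs), 1)
  expect_true(is.na(cs$reason))
  expect_equal(cs$slope, 1, tolerance = 0.05)
  # risks from a doubled prognostic index are overdispersed: slope ~ 1/2
  risk2 <- 1 - exp(-lam0 * 10 * exp(2 * lp))
  cs2 <- calibration_slope(risk2, time, event)
  expect_equal(cs2$slope, 0.5, tolerance = 0.05)
})

test_that("calibration_slope merges sparse age bins and flags degenerate ones", {
  set.seed(606)
  n <- 600
  age <- sample(60:62, n, replace = TRUE)
  lp <- rnorm(n)
  t_ev <- rexp(n, 0.04 * exp(lp))
  time <- pmin(t_ev, 10); event <- as.integer(t_ev <= 10)
  risk <- 1 - exp(-0.4 * exp(lp))
  # huge threshold: everything collapses into one bin spanning all ages
  cs <- calibration_slope(risk, time, event, landmark_age = age,
                          min_events = 10 * n)
  expect_equal(nrow(cs), 1)
  expect_equal(cs$age_lo, 60)
  expect_equal(cs$age_hi, 62)
  expect_equal(cs$n, n)
  # per-age bins with a tiny threshold
  cs3 <- calibration_slope(risk, time, event, landmark_age = age,
                           min_events = 1)
  expect_equal(nrow(cs3), 3)
  expect_equal(sum(cs3$n), n)
  # a bin with no events yields NA with the reason recorded
  csd <- calibration_slope(c(0.2, 0.4, 0.3), c(10, 10, 10), c(0, 0, 0))
  expect_true(is.na(csd$slope))
  expect_equal(csd$reason, "no events")
  # constant prognostic index
  csc <- calibration_slope(rep(0.3, 20), rep(c(2, 10), 10),
                           rep(c(1, 0), 10))
  expect_equal(csc$reason, "constant prognostic index")
})

test_that("bootstrap_ci is deterministic, clustered and validates failures", {
  rec <- make_cox_records(n = 120, seed = 31)
  metric <- function(d) harrell_c(d$pred, d$follow_time, d$event_in_horizon)
  rec$pred <- rec$sbp_last
  a <- bootstrap_ci(metric, rec, n_boot = 50, seed = 9)
  b <- bootstrap_ci(metric, rec, n_boot = 50, seed = 9)
  expect_identical(a$replicates, b$replicates)
  expect_lte(a$lo, a$hi)
  # a constant metric has a degenerate interval
  cst <- bootstrap_ci(function(d) 0.5, rec, n_boot = 20, seed = 1)
  expect_equal(cst$lo, 0.5)
  expect_equal(cst$hi, 0.5)
  # all-failing metric aborts
  expect_error(bootstrap_ci(function(d) stop("boom"), rec, n_boot = 20,
                            seed = 1),
               "failed in")
  # cluster resampling keeps a subject's records together
  rec2 <- rbind(rec, rec)  # two records per subject
  seen <- bootstrap_ci(function(d) {
    tab <- table(table(d$subject_id))
    if (!all(as.integer(names(tab)) %% 2 == 0))
      stop("subject split across resample")
    0
  }, rec2, n_boot = 20, seed = 2)
  expect_true(all(seen$replicates == 0))
})
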