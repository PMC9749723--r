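# Generator determinism, schema, marginal behaviour against closed forms,
# and the CSV round trip with its validation rules.

test_that("generation is deterministic in the seed and responds to it", {
  a <- generate_cohort(sim_config(n_subjects = 120, seed = 5))
  b <- generate_cohort(sim_config(n_subjects = 120, seed = 5))
  expect_identical(a, b)
  c <- generate_cohort(sim_config(n_subjects = 120, seed = 6))
  expect_false(identical(a$subjects$exit_age, c$subjects$exit_age))
})

test_that("the cohort tables satisfy the documented schema", {
  co <- small_cohort(n = 300, seed = 7)
  sub <- co$subjects
  expect_equal(nrow(sub), 300)
  expect_true(all(sub$exit_age > sub$entry_age))
  expect_true(all(sub$event_indicator %in% 0:1))
  expect_true(all(sub$sex %in% c("M", "F")))
  expect_true(all(sub$ethnicity %in% c("White", "Asian", "Black", "Mixed",
                                       "Other", "Unspecified")))
  expect_true(all(sub$exit_age <= 95 + 1e-9))
  m <- co$measurements
  expect_true(all(m$factor %in% RISK_FACTORS))
  expect_true(all(m$subject_id %in% sub$subject_id))
  # measurements only inside each subject's recording window
  lo <- pmax(30, sub$entry_age - 5)[match(m$subject_id, sub$subject_id)]
  hi <- sub$exit_age[match(m$subject_id, sub$subject_id)]
  expect_true(all(m$age >= lo - 1e-9 & m$age <= hi + 1e-9))
  expect_true(all(is.finite(m$value)))
  expect_true(all(co$smoking$current_smoker %in% 0:1))
  # ground truth present and complete
  expect_equal(nrow(co$truth$random_effects), 300 * length(RISK_FACTORS))
  expect_true(all(co$truth$random_effects$sigma > 0))
})

test_that("measurement counts scale with the visit rate and follow-up", {
  co <- small_cohort(n = 300, seed = 7)
  sub <- co$subjects
  m <- co$measurements
  # expected SBP count for a subject: 2.0 per year over the recording
  # window [max(30, entry - 5), exit]
  win <- pmin(sub$exit_age, 95) - pmax(30, sub$entry_age - 5)
  n_sbp <- tabulate(factor(m$subject_id[m$factor == "SBP"],
                           levels = sub$subject_id), nbins = nrow(sub))
  expect_equal(mean(n_sbp), 2.0 * mean(win), tolerance = 0.1)
  # factor ordering of counts follows the configured rates
  cnt <- table(m$factor)[RISK_FACTORS]
  expect_true(cnt[["SBP"]] > cnt[["HBA1C"]])
  expect_true(cnt[["HBA1C"]] > cnt[["TC"]])
  expect_true(cnt[["TC"]] > cnt[["HDL"]])
})

test_that("survival margins match the closed-form Weibull when covariate effects vanish", {
  # with all hazard coefficients zero and no dropout, exit is
  # min(Weibull(shape, scale) conditional on exceeding entry, cap)
  cfg <- sim_config(
    n_subjects = 2500, seed = 21,
    beta_current = c(SBP = 0, TC = 0, HDL = 0, HBA1C = 0),
    gamma_sd = c(SBP = 0, TC = 0, HDL = 0, HBA1C = 0),
    beta_binary = c(smoking = 0, bp_med = 0, af = 0, diabetes_duration = 0),
    censoring_rate = 0, hazard_baseline = c(shape = 5, scale = 110))
  co <- generate_cohort(cfg)
  sub <- co$subjects
  # conditional exceedance: P(T > t | T > entry) = exp(H(entry) - H(t))
  H <- function(t) (t / 110)^5
  t0 <- 75
  sel <- sub$entry_age < t0
  p_emp <- mean(sub$exit_age[sel] > t0 | (sub$exit_age[sel] == t0 &
                                            sub$event_indicator[sel] == 0))
  p_thy <- mean(exp(H(sub$entry_age[sel]) - H(t0)))
  expect_equal(p_emp, p_thy, tolerance = 0.03)
  # overall event fraction matches 1 - E[exp(H(entry) - H(95))] with the
  # administrative cap at age 95 and no other censoring
  expect_equal(mean(sub$event_indicator),
               1 - mean(exp(H(sub$entry_age) - H(95))), tolerance = 0.03)
})

test_that("zero baseline hazard yields no events; huge hazard events everyone", {
  cfg0 <- sim_config(n_subjects = 100, seed = 3,
                     hazard_baseline = c(shape = 5, scale = 0),
                     censoring_rate = 0)
  co0 <- generate_cohort(cfg0)
  expect_true(all(co0$subjects$event_indicator == 0))
  expect_true(all(co0$subjects$exit_age == 95))
  cfg1 <- sim_config(n_subjects = 100, seed = 3,
                     hazard_baseline = c(shape = 1, scale = 1e-3),
                     censoring_rate = 0)
  co1 <- generate_cohort(cfg1)
  expect_true(all(co1$subjects$event_indicator == 1))
})

test_that("larger gamma_sd shifts events toward high-variability subjects", {
  cfg <- sim_config(n_subjects = 1500, seed = 9,
                    gamma_sd = c(SBP = 0.08, TC = 0, HDL = 0, HBA1C = 0),
                    censoring_rate = 0)
  co <- generate_cohort(cfg)
  re <- co$truth$random_effects
  sig <- re$sigma[re$factor == "SBP"][match(co$subjects$subject_id,
                                            unique(re$subject_id))]
  ev <- co$subjects$event_indicator == 1
  expect_gt(mean(sig[ev]), mean(sig[!ev]))
})

test_that("true_current_value and true_risk agree with the stored truth", {
  co <- small_cohort(n = 300, seed = 7)
  cfg <- co$truth$config
  re <- co$truth$random_effects
  id <- co$subjects$subject_id[5]
  r <- re[re$subject_id == id & re$factor == "SBP", ]
  want <- cfg$fixed_trajectory$SBP[1] + cfg$fixed_trajectory$SBP[2] * 10 +
    r$b0 + r$b1 * 10
  expect_equal(true_current_value(co, id, "SBP", 60), want)
  tr <- true_risk(co, 60)
  sub <- co$subjects
  expect_setequal(tr$subject_id,
                  sub$subject_id[sub$entry_age <= 60 & sub$exit_age > 60])
  expect_true(all(tr$true_risk >= 0 & tr$true_risk <= 1))
  # risk increases with the horizon
  tr5 <- true_risk(co, 60, w = 5)
  common <- intersect(tr$subject_id, tr5$subject_id)
  expect_true(all(tr$true_risk[match(common, tr$subject_id)] >=
                    tr5$true_risk[match(common, tr5$subject_id)]))
})

test_that("config validation rejects malformed inputs", {
  expect_error(sim_config(visit_rate = c(SBP = 0, TC = 1, HDL = 1, HBA1C = 1)),
               "positive")
  expect_error(sim_config(beta_current = c(SBP = 0.01)), "missing factor")
  expect_error(sim_config(ethnicity_probs = c(White = 0.5, Asian = 0.1,
                                              Black = 0.1, Mixed = 0.1,
                                              Other = 0.1, Unspecified = 0.4)),
               "sum to 1")
  expect_error(sim_config(random_effects_cov = list(
    SBP = matrix(c(1, 2, 0, 1), 2), TC = diag(2), HDL = diag(2),
    HBA1C = diag(2))), "symmetric")
})

test_that("cohort IO round-trips exactly and truth stays out of the files", {
  co <- small_cohort(n = 120, seed = 13)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_setequal(list.files(dir),
                  c("subjects.csv", "measurements.csv", "smoking.csv"))
  back <- read_cohort(dir)
  expect_equal(back$subjects, co$subjects, tolerance = 1e-12)
  expect_equal(back$measurements, co$measurements, tolerance = 1e-12)
  expect_equal(back$smoking, co$smoking, tolerance = 1e-12)
  expect_null(back$truth)
})

test_that("read_cohort validation catches corrupted tables", {
  co <- small_cohort(n = 60, seed = 17)
  base <- withr::local_tempdir()
  write_cohort(co, base)
  corrupt <- function(fn) {
    d <- withr::local_tempdir(.local_envir = parent.frame())
    file.copy(file.path(base, c("subjects.csv", "measurements.csv",
                                "smoking.csv")), d)
    fn(d)
    d
  }
  # exit before entry, named by subject
  d1 <- corrupt(function(d) {
    s <- utils::read.csv(file.path(d, "subjects.csv"))
    s$exit_age[3] <- s$entry_age[3] - 1
    utils::write.csv(s, file.path(d, "subjects.csv"), row.names = FALSE)
  })
  expect_error(read_cohort(d1), as.character(co$subjects$subject_id[3]))
  # unknown factor
  d2 <- corrupt(function(d) {
    m <- utils::read.csv(file.path(d, "measurements.csv"))
    m$factor[1] <- "LDL"
    utils::write.csv(m, file.path(d, "measurements.csv"), row.names = FALSE)
  })
  expect_error(read_cohort(d2), "factor")
  # duplicated subject id
  d3 <- corrupt(function(d) {
    s <- utils::read.csv(file.path(d, "subjects.csv"))
    s$subject_id[2] <- s$subject_id[1]
    utils::write.csv(s, file.path(d, "subjects.csv"), row.names = FALSE)
  })
  expect_error(read_cohort(d3), "[Dd]uplicate")
  # measurement referencing a nonexistent subject
  d4 <- corrupt(function(d) {
    m <- utils::read.csv(file.path(d, "measurements.csv"))
    m$subject_id[1] <- max(co$subjects$subject_id) + 1000
    utils::write.csv(m, file.path(d, "measurements.csv"), row.names = FALSE)
  })
  expect_error(read_cohort(d4), "unknown subject")
  # missing column
  d5 <- corrupt(function(d) {
    s <- utils::read.csv(file.path(d, "subjects.csv"))
    s$entry_age <- NULL
    utils::write.csv(s, file.path(d, "subjects.csv"), row.names = FALSE)
  })
  expect_error(read_cohort(d5), "entry_age")
})
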