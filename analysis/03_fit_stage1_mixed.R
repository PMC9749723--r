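# Stage 3: fit the sex-specific multivariate mixed models on the
# derivation subjects and add the BLUP current-value and slope summaries
# to both landmark datasets.

source(file.path("analysis", "00_common.R"))

cohort <- read_cohort(file.path(OUT_DIR, "cohort"))
der_ids <- as.integer(readLines(file.path(OUT_DIR,
                                          "derivation_subject_ids.txt")))

fits <- list(
  M = fit_mixed(cohort, "M", subject_ids = der_ids),
  F = fit_mixed(cohort, "F", subject_ids = der_ids))
write_mixed_fit(fits$M, file.path(OUT_DIR, "mixed_fit_M.json"))
write_mixed_fit(fits$F, file.path(OUT_DIR, "mixed_fit_F.json"))

for (nm in c("landmark_derivation", "landmark_validation")) {
  path <- file.path(OUT_DIR, paste0(nm, ".csv"))
  rec <- read.csv(path, stringsAsFactors = FALSE)
  rec <- add_mixed_summaries(rec, fits, cohort)
  write.csv(rec, path, row.names = FALSE)
}

params <- do.call(rbind, lapply(c("M", "F"), function(sx) {
  f <- fits[[sx]]
  data.frame(sex = sx, factor = RISK_FACTORS,
             mean_at_50 = round(f$center + f$scale *
                                  f$beta[seq(1, 12, by = 3)], 3),
             slope_per_year = round(f$scale * f$beta[seq(2, 12, by = 3)], 4),
             residual_sd = round(f$scale * sqrt(f$sigma2), 3),
             iterations = f$iterations, row.names = NULL)
}))
write.csv(params, file.path(OUT_DIR, "stage1_parameters.csv"),
          row.names = FALSE)
print(params, row.names = FALSE)
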