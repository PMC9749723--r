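# Stage 4: fit the sex-specific super landmark Cox models of the
# canonical comparison set on the derivation records, serialise every
# fit, and tabulate the coefficients with cluster-robust standard errors.

source(file.path("analysis", "00_common.R"))

der <- read.csv(file.path(OUT_DIR, "landmark_derivation.csv"),
                stringsAsFactors = FALSE)
fits <- fit_model_set(der, MAIN_MODELS)

coef_rows <- list()
for (nm in names(fits)) {
  for (sx in c("M", "F")) {
    f <- fits[[nm]][[sx]]
    write_cox_fit(f, file.path(OUT_DIR, sprintf("cox_%s_%s.json", nm, sx)))
    coef_rows[[paste(nm, sx)]] <- data.frame(
      model = nm, sex = sx, term = names(f$beta),
      estimate = unname(f$beta),
      robust_se = sqrt(diag(f$robust_vcov)), row.names = NULL)
  }
}
coefs <- do.call(rbind, c(coef_rows, make.row.names = FALSE))
write.csv(coefs, file.path(OUT_DIR, "stage2_coefficients.csv"),
          row.names = FALSE)

key <- coefs[coefs$model %in% c("last", "current_sd") &
               coefs$term %in% c(tolower(RISK_FACTORS),
                                 paste0(tolower(RISK_FACTORS), "_sd")), ]
key$estimate <- round(key$estimate, 4)
key$robust_se <- round(key$robust_se, 4)
print(key, row.names = FALSE)
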