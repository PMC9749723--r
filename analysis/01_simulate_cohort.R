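# Stage 1 of the analysis: simulate the synthetic longitudinal diabetes
# cohort under the default study conditions and write it to CSV, along
# with a table of descriptive statistics.

source(file.path("analysis", "00_common.R"))

cfg <- main_sim_config()
cohort <- generate_cohort(cfg)
write_cohort(cohort, file.path(OUT_DIR, "cohort"))

sub <- cohort$subjects
m <- cohort$measurements
py <- sum(sub$exit_age - sub$entry_age)
counts <- sapply(RISK_FACTORS, function(k)
  stats::median(tabulate(factor(m$subject_id[m$factor == k],
                                levels = sub$subject_id))))

desc <- data.frame(
  quantity = c("subjects", "women_pct", "entry_age_mean", "dx_age_mean",
               "events", "events_per_1000py", "followup_years_mean",
               paste0("median_n_", tolower(RISK_FACTORS))),
  value = round(c(nrow(sub), 100 * mean(sub$sex == "F"),
                  mean(sub$entry_age), mean(sub$diabetes_dx_age),
                  sum(sub$event_indicator),
                  1000 * sum(sub$event_indicator) / py,
                  mean(sub$exit_age - sub$entry_age), counts), 2))
write.csv(desc, file.path(OUT_DIR, "cohort_descriptives.csv"),
          row.names = FALSE)
print(desc, row.names = FALSE)
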