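# Stage 2: split the cohort into derivation and validation sets by
# general practice, and build the stacked landmark datasets (landmark
# ages 40-85, 10-year horizon, complete-case eligibility).

source(file.path("analysis", "00_common.R"))

cohort <- read_cohort(file.path(OUT_DIR, "cohort"))
split <- split_by_practice(cohort, seed = SPLIT_SEED)
grid <- landmark_grid()

der <- build_landmark_dataset(split$derivation, grid)
val <- build_landmark_dataset(split$validation, grid)

write.csv(der, file.path(OUT_DIR, "landmark_derivation.csv"),
          row.names = FALSE)
write.csv(val, file.path(OUT_DIR, "landmark_validation.csv"),
          row.names = FALSE)
writeLines(as.character(split$derivation$subjects$subject_id),
           file.path(OUT_DIR, "derivation_subject_ids.txt"))

by_age <- aggregate(cbind(records = subject_id) ~ landmark_age,
                    data = der, FUN = length)
by_age$events <- aggregate(event_in_horizon ~ landmark_age, data = der,
                           FUN = sum)$event_in_horizon
write.csv(by_age, file.path(OUT_DIR, "landmark_counts_by_age.csv"),
          row.names = FALSE)

cat(sprintf("derivation: %d records (%d events), validation: %d records (%d events)\n",
            nrow(der), sum(der$event_in_horizon),
            nrow(val), sum(val$event_in_horizon)))
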