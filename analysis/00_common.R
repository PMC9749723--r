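# Shared settings for the numbered analysis scripts. Each script can be
# run on its own (in order) from the repository root:
#
#   Rscript analysis/01_simulate_cohort.R
#   Rscript analysis/02_build_landmarks.R
#   ...
#
# All intermediate artifacts live in analysis/output/ as flat files, so
# every stage is independently inspectable and rerunnable.

suppressPackageStartupMessages(library(landmarkvar))

OUT_DIR <- file.path("analysis", "output")
dir.create(OUT_DIR, showWarnings = FALSE, recursive = TRUE)

ANALYSIS_SEED <- 1L       # simulation seed of the main experiment
SPLIT_SEED <- 1L          # practice-level derivation/validation split
BOOT_SEED <- 1L           # bootstrap confidence intervals
N_SUBJECTS <- 4000L       # main-experiment cohort size
N_BOOT <- 200L

MAIN_MODELS <- names(canonical_model_specs())

main_sim_config <- function() {
  sim_config(n_subjects = N_SUBJECTS, seed = ANALYSIS_SEED)
}
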