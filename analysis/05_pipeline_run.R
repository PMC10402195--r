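#!/usr/bin/env Rscript
# One-command end-to-end run through the pipeline orchestrator, including a
# small signal-level cohort processed through the spectral/atlas path.
library(ieegfocal)

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

res <- run_pipeline(run_config(out_dir = "results/run_feature",
                               spec = cohort_spec(n_patients = 60),
                               seed = seed))
print(res)

res_sig <- suppressWarnings(run_pipeline(run_config(
  out_dir = "results/run_signal",
  spec = cohort_spec(n_patients = 12, n_contacts_range = c(14, 18)),
  mode = "signal", feature_sets = "sense_ieeg",
  n_clips = 2, clip_duration_s = 8, seed = seed
)))
cat("signal-mode run complete:\n")
print(res_sig)
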