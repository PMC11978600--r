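#!/usr/bin/env Rscript
# Stage 1 — simulate the default three-wave cohort.
#
# Writes long-format modality tables, per-participant risk factors, and the
# ground-truth archetype labels under results/. All downstream stages read
# only these files.

library(cogtraj)

outdir <- "results"
dir.create(outdir, showWarnings = FALSE)

config <- cohort_config()   # 582 participants, waves 211/503/113, seed fixed
cohort <- generate_cohort(config)
print(cohort)

write_long_table(cohort$cognitive, file.path(outdir, "cognitive_raw.csv"))
write_long_table(cohort$mri, file.path(outdir, "mri_raw.csv"))
readr::write_csv(cohort$icv, file.path(outdir, "icv.csv"))
readr::write_csv(cohort$risk_factors, file.path(outdir, "risk_factors.csv"))
readr::write_csv(cohort$truth, file.path(outdir, "truth_archetypes.csv"))
readr::write_csv(cohort$eeg_truth, file.path(outdir, "eeg_recordings.csv"))
readr::write_csv(cohort$visits, file.path(outdir, "visits.csv"))

cat(sprintf(
  "simulated %d participants (%d visits); cognitive %d obs, MRI %d obs, %d EEG recordings\n",
  nrow(cohort$participants), nrow(cohort$visits), nrow(cohort$cognitive),
  nrow(cohort$mri), nrow(cohort$eeg_truth)))
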