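#!/usr/bin/env Rscript
# Stage 2 — quality control of the cognitive battery.
#
# Applies, in order: per-visit coverage (>= 75 participants), constancy
# within the [5, 95] percentile band, 5x-IQR outlier removal, and the drop
# of participants without any usable cognitive data. MRI volumes are
# ICV-normalized and both ancillary modalities are restricted to the
# surviving cognitive participants.

library(cogtraj)

cognitive <- read_long_table("results/cognitive_raw.csv")
mri <- read_long_table("results/mri_raw.csv")
icv <- readr::read_csv("results/icv.csv", show_col_types = FALSE)
truth <- readr::read_csv("results/truth_archetypes.csv",
                         show_col_types = FALSE)

pp <- preprocess_cognitive(cognitive, roster = truth$participant_id)
for (qc in pp$qc) print(qc)

norm <- icv_normalize(mri, icv)
matched <- match_modalities(pp$table, norm$table)

write_long_table(pp$table, "results/cognitive_clean.csv")
write_long_table(matched$mri, "results/mri_clean.csv")

cat(sprintf(
  "retained %d cognitive scores over %d participants; MRI: %d participants\n",
  length(unique(pp$table$variable)),
  length(unique(pp$table$participant_id)),
  length(unique(matched$mri$participant_id))))
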