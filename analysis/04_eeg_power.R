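#!/usr/bin/env Rscript
# Stage 4 — extract Z-scored SSVEP regional powers.
#
# Synthesizes each available 64-channel recording, takes Welch spectra per
# channel, compensates the 1/f background, reads the peak power at the 8 Hz
# (alpha) and 36 Hz (gamma) stimulation frequencies, averages channels into
# five scalp regions, and z-scores each region-band across the cohort.

library(cogtraj)

cohort <- generate_cohort(cohort_config())   # same seed as stage 1
eeg <- cohort_regional_powers(cohort)
write_long_table(eeg, "results/eeg_powers.csv")

counts <- table(paste(eeg$participant_id, eeg$visit_index))
cat(sprintf("extracted %d regional measures (%d features per recording) from %d recordings\n",
            nrow(eeg), unique(counts), length(counts)))
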