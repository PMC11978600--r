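#!/usr/bin/env Rscript
# Stage 7 — validate the cluster labels by high/low classification.
#
# Merges the four clusters into high- and low-performing classes, fits one
# ridge-logistic model per modality on first-visit features, and reports
# in-sample and 5-fold cross-validated ROC/AUC, plus a univariate AUC scan
# over the individual cognitive scores.

library(cogtraj)

labels <- readr::read_csv("results/cluster_labels.csv",
                          show_col_types = FALSE)
cognitive <- read_long_table("results/cognitive_clean.csv")
eeg <- read_long_table("results/eeg_powers.csv")
mri <- read_long_table("results/mri_clean.csv")

arch_map <- setNames(labels$archetype, labels$cluster)[
  !duplicated(labels$cluster)]
labeling <- merge_high_low(labels, arch_map)
cat(sprintf("high/low split: %d / %d participants\n",
            sum(labeling$class == "high"), sum(labeling$class == "low")))

tables <- list(cognitive = cognitive, mri = mri, eeg = eeg)
insample <- modality_auc_comparison(tables, labeling)
cv <- modality_auc_comparison(tables, labeling, cv_folds = 5)
auc_tab <- tibble::tibble(
  modality = names(insample),
  auc_insample = vapply(insample, function(r) r$auc, numeric(1)),
  auc_cv5 = vapply(cv[names(insample)], function(r) r$auc, numeric(1)),
  n = vapply(insample, function(r) r$n_used, numeric(1)))
readr::write_csv(auc_tab, "results/modality_auc.csv")
print(auc_tab)

roc_points <- dplyr::bind_rows(lapply(insample, function(r) {
  tibble::tibble(modality = r$modality, fpr = r$fpr, tpr = r$tpr)
}))
readr::write_csv(roc_points, "results/roc_curves.csv")

scan <- univariate_auc_scan(cognitive, labeling)
readr::write_csv(scan, "results/univariate_auc.csv")
cat("top univariate cognitive predictors of the low-performing class:\n")
print(head(scan, 8))
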