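#!/usr/bin/env Rscript
# Stage 6 — nonparametric group comparisons and trajectory summaries.
#
# Risk factors, regional EEG powers, and ICV-corrected volumes are compared
# across the four named clusters (Kruskal-Wallis / chi-square) and across
# the merged high/low split (Wilcoxon / Fisher). Two example cognitive
# trajectories are summarized per group and visit with 95% CIs of the mean.

library(cogtraj)

labels <- readr::read_csv("results/cluster_labels.csv",
                          show_col_types = FALSE)
risk <- readr::read_csv("results/risk_factors.csv", show_col_types = FALSE)
cognitive <- read_long_table("results/cognitive_clean.csv")
eeg <- read_long_table("results/eeg_powers.csv")
mri <- read_long_table("results/mri_clean.csv")

groups <- tibble::tibble(participant_id = labels$participant_id,
                         group = labels$archetype)
risk <- risk[risk$participant_id %in% groups$participant_id,
             setdiff(names(risk), "archetype")]

four <- compare_all(risk, groups)
merged <- compare_all(risk, groups, merge = TRUE)
readr::write_csv(four[, 1:4], "results/stats_risk_4groups.csv")
readr::write_csv(merged[, 1:4], "results/stats_risk_merged.csv")
cat(sprintf("risk factors significant at p<0.05: %d/%d (4 groups), %d/%d (merged)\n",
            sum(four$significant), nrow(four),
            sum(merged$significant), nrow(merged)))

# first-visit biomarker features per participant, compared across clusters
biomarker_stats <- function(tab, label) {
  X <- first_visit_features(tab)
  feats <- tibble::as_tibble(X)
  feats$participant_id <- rownames(X)
  res <- compare_all(feats, groups)
  readr::write_csv(res[, 1:4],
                   sprintf("results/stats_%s_4groups.csv", label))
  cat(sprintf("%s measures significant across clusters: %d/%d\n",
              label, sum(res$significant), nrow(res)))
}
biomarker_stats(eeg, "eeg")
biomarker_stats(mri, "mri")

# per-group per-visit trajectories of two illustrative scores
example_scores <- c("rvp_a_prime", "tmt_b_time")
cl_of <- setNames(labels$archetype, labels$participant_id)
for (v in example_scores) {
  d <- cognitive[cognitive$variable == v, ]
  s <- trajectory_summary(d$value, cl_of[d$participant_id], d$visit_index)
  readr::write_csv(s, sprintf("results/trajectory_%s.csv", v))
}
cat("wrote per-group trajectory summaries for",
    paste(example_scores, collapse = " and "), "\n")
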