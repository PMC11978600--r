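#' Run the full analysis pipeline on a synthetic cohort
#'
#' Simulate -> preprocess -> cognitive summary -> trajectory clustering ->
#' EEG power extraction -> group statistics -> high/low classification,
#' in order, returning every stage result plus a reproducibility manifest
#' (per-stage row counts and content hashes). Identical config + seed
#' reproduces identical manifests.
#'
#' @param config A [cohort_config()]; its seed drives every stage.
#' @param k_range Candidate cluster counts.
#' @param latent_fraction Autoencoder latent fraction.
#' @param epochs Autoencoder training epochs.
#' @param n_init Temporal k-means restarts.
#' @param min_n Coverage-filter threshold (participants per visit).
#' @param run_eeg Extract EEG regional powers (the slowest stage).
#' @param outdir Optional directory; stage outputs are persisted as CSV.
#' @return A list with `cohort`, `cognitive` (preprocessed), `latent`,
#'   `clustering` (select_k output), `archetype_map`, `labels`, `eeg`,
#'   `stats`, `classification`, `manifest`.
#' @export
run_pipeline <- function(config = cohort_config(), k_range = 2:8,
                         latent_fraction = 0.65, epochs = 300L,
                         n_init = 10, min_n = 75, run_eeg = TRUE,
                         outdir = NULL) {
  t0 <- Sys.time()
  cohort <- generate_cohort(config)

  pp <- preprocess_cognitive(cohort$cognitive, min_n = min_n,
                             roster = cohort$participants$participant_id)
  cognitive <- pp$table

  summ <- summarize_cognitive(cognitive, latent_fraction = latent_fraction,
                              epochs = epochs,
                              seed = child_seed(config$seed, 60L))
  trajs <- build_trajectories(summ$latent)

  sel <- select_k(trajs, k_range = k_range,
                  seed = child_seed(config$seed, 61L), n_init = n_init)
  model <- sel$models[[as.character(sel$k)]]
  composite <- composite_cognitive(cognitive)
  arch_map <- label_archetypes(model, composite)
  labels <- tibble::tibble(
    participant_id = names(model$labels),
    cluster = unname(model$labels),
    archetype = unname(arch_map[as.character(model$labels)]))

  mri_norm <- icv_normalize(cohort$mri, cohort$icv)$table
  eeg <- if (run_eeg) cohort_regional_powers(cohort) else NULL
  matched <- match_modalities(cognitive, mri_norm, eeg)

  group_tbl <- tibble::tibble(participant_id = labels$participant_id,
                              group = labels$archetype)
  risk <- cohort$risk_factors[cohort$risk_factors$participant_id %in%
                                labels$participant_id, ]
  stats_risk <- compare_all(risk, group_tbl)

  labeling <- merge_high_low(
    setNames(labels$cluster, labels$participant_id), arch_map)
  tables <- list(cognitive = cognitive)
  if (!is.null(matched$mri)) tables$mri <- matched$mri
  if (!is.null(matched$eeg)) tables$eeg <- matched$eeg
  rocs <- modality_auc_comparison(tables, labeling)

  truth <- cohort$truth[match(labels$participant_id,
                              cohort$truth$participant_id), ]
  ari <- if (requireNamespace("mclust", quietly = TRUE)) {
    ari_score(truth$archetype, labels$cluster)
  } else NA_real_

  manifest <- list(
    seed = config$seed,
    config_hash = rlang::hash(config),
    n_participants = nrow(cohort$participants),
    n_analysis_participants = length(unique(cognitive$participant_id)),
    n_cognitive_scores = length(unique(cognitive$variable)),
    latent_dim = summ$model$spec$latent_dim,
    k_selected = sel$k,
    db_index = model$db_index,
    ari = ari,
    modality_counts = matched$counts,
    auc = vapply(rocs, function(r) r$auc, numeric(1)),
    stage_hashes = c(
      cognitive = rlang::hash(cognitive),
      latent = rlang::hash(summ$latent),
      labels = rlang::hash(labels)),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  out <- list(cohort = cohort, cognitive = cognitive, latent = summ$latent,
              clustering = sel, archetype_map = arch_map, labels = labels,
              eeg = eeg, mri = matched$mri, stats = stats_risk,
              classification = rocs, manifest = manifest)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_long_table(cognitive, file.path(outdir, "cognitive_clean.csv"))
    readr::write_csv(labels, file.path(outdir, "cluster_labels.csv"))
    readr::write_csv(sel$curve, file.path(outdir, "db_curve.csv"))
    if (!is.null(eeg)) write_long_table(eeg, file.path(outdir,
                                                       "eeg_powers.csv"))
  }
  out
}
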