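#' Catalog of synthetic MRI regions
#'
#' 35 regional volumes patterned on a whole-brain volumetric segmentation.
#' `tag` drives the generator: `ventricle` regions expand with age,
#' `neocortical` regions atrophy (faster in declining archetypes and with a
#' level deficit in low-performing archetypes), `subcortical`/`global`
#' regions shrink mildly. `baseline_mm3` are order-of-magnitude realistic
#' adult volumes.
#'
#' @return A tibble with columns `variable`, `tag`, `baseline_mm3`,
#'   `aging_slope` (proportional change per year shared by all archetypes).
#' @export
mri_region_catalog <- function() {
  reg <- function(variable, tag, baseline_mm3, aging_slope) {
    tibble::tibble(variable = variable, tag = tag,
                   baseline_mm3 = baseline_mm3, aging_slope = aging_slope)
  }
  dplyr::bind_rows(
    reg(c("lateral_ventricle", "inferior_lateral_ventricle",
          "third_ventricle", "fourth_ventricle", "csf"),
        "ventricle", c(25000, 800, 1200, 1800, 1500), 0.020),
    reg(c("frontal_cortex", "parietal_cortex", "temporal_cortex",
          "occipital_cortex", "precuneus", "fusiform", "entorhinal",
          "supramarginal", "insula", "cingulate", "lingual",
          "lateral_occipital"),
        "neocortical",
        c(160000, 110000, 120000, 60000, 18000, 17000, 3800, 20000, 13000,
          22000, 12000, 25000), -0.006),
    reg(c("hippocampus", "amygdala", "thalamus", "caudate", "putamen",
          "pallidum", "accumbens", "brain_stem"),
        "subcortical",
        c(8000, 3200, 13000, 7000, 9500, 3500, 1000, 21000), -0.003),
    reg(c("cerebral_white_matter", "corpus_callosum", "cerebellum_cortex",
          "cerebellum_white_matter", "total_brain", "supratentorial",
          "gray_matter", "cortex", "optic_chiasm", "ventral_dc"),
        "global",
        c(450000, 3300, 100000, 28000, 1100000, 950000, 600000, 480000,
          250, 8000), -0.002)
  )
}

# --- participants, waves, visits --------------------------------------------

generate_participants <- function(cfg) {
  w <- cfg$wave_sizes
  o <- cfg$wave_overlaps
  n <- cfg$n_participants
  ids <- sprintf("P%04d", seq_len(n))
  local_seed(child_seed(cfg$seed, 1L), {
    wave_members <- list(integer(0), integer(0), integer(0))
    n1 <- w[1]
    wave_members[[1]] <- seq_len(n1)
    new2 <- w[2] - o[1]
    wave_members[[2]] <- c(if (o[1] > 0) sample(wave_members[[1]], o[1])
                           else integer(0),
                           if (new2 > 0) n1 + seq_len(new2) else integer(0))
    new3 <- w[3] - o[2] - o[3]
    from2 <- if (o[2] > 0) sample(wave_members[[2]], o[2]) else integer(0)
    w1_only <- setdiff(wave_members[[1]], wave_members[[2]])
    from1 <- if (o[3] > 0) sample(w1_only, o[3]) else integer(0)
    wave_members[[3]] <- c(from2, from1,
                           if (new3 > 0) n1 + new2 + seq_len(new3)
                           else integer(0))

    arch <- cfg$archetypes
    assignment <- sample(arch$name, n, replace = TRUE,
                         prob = arch$mixing_weight)

    visits <- vector("list", n)
    for (i in seq_len(n)) {
      waves <- which(vapply(wave_members, function(m) i %in% m, logical(1)))
      ages <- numeric(length(waves))
      prev <- -Inf
      for (k in seq_along(waves)) {
        win <- cfg$wave_age_windows[[waves[k]]]
        lo <- max(win[1], prev + 0.25)
        ages[k] <- runif(1, lo, max(win[2], lo + 1e-3))
        prev <- ages[k]
      }
      # visit_index is the assessment wave (a wave-2-only participant has
      # a single visit with visit_index 2)
      visits[[i]] <- tibble::tibble(
        participant_id = ids[i],
        visit_index = as.integer(waves),
        wave = as.integer(waves),
        age = ages
      )
    }
    participants <- tibble::tibble(
      participant_id = ids,
      archetype = assignment,
      waves = vapply(seq_len(n), function(i)
        paste(which(vapply(wave_members, function(m) i %in% m, logical(1))),
              collapse = ","), character(1)),
      n_visits = vapply(visits, nrow, integer(1))
    )
    list(participants = participants, visits = dplyr::bind_rows(visits))
  })
}

generate_latent <- function(cfg, participants, visits,
                            intercept_sd = 0.25, visit_sd = 0.10) {
  arch <- cfg$archetypes
  local_seed(child_seed(cfg$seed, 2L), {
    n <- nrow(participants)
    b <- matrix(rnorm(2 * n, 0, intercept_sd), ncol = 2)
    rownames(b) <- participants$participant_id
    idx <- match(participants$archetype[match(visits$participant_id,
                                              participants$participant_id)],
                 arch$name)
    offset <- visits$age - cfg$age_range[1]
    z1 <- unname(arch$baseline_level[idx] + arch$slope_per_year[idx] *
                   offset + b[visits$participant_id, 1] +
                   rnorm(nrow(visits), 0, visit_sd))
    z2 <- unname(arch$profile[idx] + b[visits$participant_id, 2] +
                   rnorm(nrow(visits), 0, visit_sd))
    tibble::tibble(
      participant_id = visits$participant_id,
      visit_index = visits$visit_index,
      age = visits$age,
      z1 = z1, z2 = z2
    )
  })
}

# --- loading matrix and cognitive scores ------------------------------------

#' Default loading matrix mapping latent cognition to observed scores
#'
#' Row j gives score j's weights on the latent dimensions: a positive weight
#' on the composite level (all tests track overall cognition) and a signed
#' weight on the profile axis (domains differ in which archetypes they
#' favor). Latency/error scores keep positive loadings here; orientation is
#' applied by the direction flag at score-generation time.
#'
#' @param n_scores Number of scores (rows).
#' @param rank Latent dimensionality (>= 1; extra columns get small weights).
#' @param seed Seed for the weight draw.
#' @return A `n_scores x rank` matrix.
#' @export
default_loading <- function(n_scores = 77L, rank = 2L, seed = 1L) {
  local_seed(child_seed(seed, 3L), {
    L <- matrix(0, n_scores, rank)
    L[, 1] <- runif(n_scores, 0.6, 1.0)
    if (rank >= 2) L[, 2] <- runif(n_scores, -0.9, 0.9)
    if (rank > 2) {
      L[, 3:rank] <- matrix(runif(n_scores * (rank - 2), -0.2, 0.2),
                            n_scores)
    }
    L
  })
}

#' Generate observed cognitive scores from latent trajectories
#'
#' Score for participant i, visit t, test j is
#' `dir_j * (loading_j . latent_it) + noise`, with `dir_j = -1` for tests
#' flagged `higher_is_worse` (latency/error scores), so that archetype
#' ordering reverses for those tests.
#'
#' @param cohort A `synthetic_cohort` (or a list with `config` and `latent`).
#' @param loading Loading matrix (`n_scores x rank`); default from
#'   [default_loading()] seeded by the cohort config.
#' @param noise_sd Observation noise SD; defaults to the config value.
#' @return A long feature table of cognitive scores.
#' @export
generate_cognitive_scores <- function(cohort, loading = NULL,
                                      noise_sd = NULL) {
  cfg <- cohort$config
  catalog <- cognitive_score_catalog()
  catalog <- catalog[seq_len(min(nrow(catalog), cfg$n_cognitive_scores)), ]
  if (nrow(catalog) < cfg$n_cognitive_scores) {
    extra <- cfg$n_cognitive_scores - nrow(catalog)
    catalog <- dplyr::bind_rows(catalog, tibble::tibble(
      variable = sprintf("extra_score_%02d", seq_len(extra)),
      battery = "extra", higher_is_worse = FALSE))
  }
  if (is.null(loading)) {
    loading <- default_loading(cfg$n_cognitive_scores,
                               cfg$loading_matrix_rank, cfg$seed)
  }
  if (nrow(loading) != cfg$n_cognitive_scores ||
      ncol(loading) != cfg$loading_matrix_rank) {
    stop(sprintf("loading matrix must be %d x %d, got %d x %d",
                 cfg$n_cognitive_scores, cfg$loading_matrix_rank,
                 nrow(loading), ncol(loading)), call. = FALSE)
  }
  if (is.null(noise_sd)) noise_sd <- cfg$noise_sd
  latent <- cohort$latent
  Z <- as.matrix(latent[, c("z1", "z2")[seq_len(cfg$loading_matrix_rank)],
                        drop = FALSE])
  signal <- Z %*% t(loading)           # visits x scores
  dir <- ifelse(catalog$higher_is_worse, -1, 1)
  signal <- sweep(signal, 2, dir, `*`)
  local_seed(child_seed(cfg$seed, 4L), {
    eps <- matrix(rnorm(length(signal), 0, noise_sd), nrow(signal))
    obs <- signal + eps
    tibble::tibble(
      participant_id = rep(latent$participant_id, times = nrow(catalog)),
      visit_index = rep(latent$visit_index, times = nrow(catalog)),
      age = rep(latent$age, times = nrow(catalog)),
      variable = rep(catalog$variable, each = nrow(latent)),
      value = as.vector(obs)
    )
  })
}

# --- MRI --------------------------------------------------------------------

#' Generate regional MRI volumes and intracranial volumes
#'
#' Per-region baseline volumes scale with each participant's head size
#' (intracranial volume, constant across visits). Ventricle/CSF regions
#' expand with age in all archetypes; neocortical regions atrophy, with
#' steeper slopes in the declining archetypes and a small level deficit in
#' the low-performing archetypes, which carries the group signal available
#' to the MRI classifier.
#'
#' @param cohort A `synthetic_cohort`.
#' @param atrophy_scale Multiplier on all age slopes (0 freezes aging).
#' @param noise_sd_log Log-normal per-observation measurement noise SD.
#' @param low_neocortical_deficit Proportional neocortical volume deficit of
#'   the low-performing archetypes.
#' @param decline_slope_boost Additional proportional annual atrophy in
#'   declining archetypes (applied to neocortical regions, and as faster
#'   expansion of ventricles).
#' @return A list with `volumes` (long feature table, mm^3) and `icv`
#'   (tibble `participant_id`, `icv` in mm^3).
#' @export
generate_mri <- function(cohort, atrophy_scale = 1,
                         noise_sd_log = 0.02,
                         low_neocortical_deficit = 0.015,
                         decline_slope_boost = 0.004) {
  cfg <- cohort$config
  catalog <- mri_region_catalog()
  catalog <- catalog[seq_len(min(nrow(catalog), cfg$n_mri_regions)), ]
  visits <- cohort$visits
  participants <- cohort$participants
  local_seed(child_seed(cfg$seed, 5L), {
    icv <- tibble::tibble(
      participant_id = participants$participant_id,
      icv = pmax(rnorm(nrow(participants), 1.5e6, 1.2e5), 1e6)
    )
    subj_scale <- setNames(exp(rnorm(nrow(participants), 0, 0.03)),
                           participants$participant_id)
    arch <- participants$archetype[match(visits$participant_id,
                                         participants$participant_id)]
    declining <- arch %in% c("low_declining", "high_lower")
    low_perf <- arch %in% c("low_stable", "low_declining")
    offset <- visits$age - cfg$age_range[1]
    head_size <- icv$icv[match(visits$participant_id, icv$participant_id)] /
      1.5e6

    rows <- lapply(seq_len(nrow(catalog)), function(r) {
      slope <- catalog$aging_slope[r]
      boost <- if (catalog$tag[r] == "neocortical") -decline_slope_boost
               else if (catalog$tag[r] == "ventricle") 2 * decline_slope_boost
               else 0
      slope_v <- (slope + ifelse(declining, boost, 0)) * atrophy_scale
      level <- ifelse(low_perf & catalog$tag[r] == "neocortical",
                      1 - low_neocortical_deficit, 1)
      vol <- as.numeric(catalog$baseline_mm3[r] * head_size *
                          subj_scale[visits$participant_id] * level *
                          (1 + slope_v * offset) *
                          exp(rnorm(nrow(visits), 0, noise_sd_log)))
      tibble::tibble(
        participant_id = visits$participant_id,
        visit_index = visits$visit_index,
        age = visits$age,
        variable = catalog$variable[r],
        value = vol
      )
    })
    list(volumes = dplyr::bind_rows(rows), icv = icv)
  })
}

# --- risk factors -----------------------------------------------------------

#' Default per-archetype risk-factor distributions
#'
#' Bernoulli prevalences, categorical distributions, and Gaussian parameters
#' per archetype. Binary and father's-education values are calibrated to the
#' printed per-group counts of the emulated cohort study (e.g. alcohol use
#' 65/4 yes/no in the low-stable group); father's occupation (20 job
#' categories) and BMI have no printed per-group statistics and use
#' synthetic defaults with a socioeconomic tilt favoring the high-performing
#' groups.
#'
#' @return A list with elements `binary` (tibble variable x archetype
#'   prevalence), `categorical` (list of per-archetype probability vectors),
#'   `gaussian` (tibble of means/SDs).
#' @export
default_risk_prevalences <- function() {
  groups <- c("low_stable", "high_upper", "low_declining", "high_lower")
  bin <- function(variable, yes, total) {
    tibble::tibble(variable = variable, archetype = groups,
                   prevalence = yes / total)
  }
  binary <- dplyr::bind_rows(
    bin("alcohol_use",      c(65, 243, 63, 128), c(69, 256, 65, 136)),
    bin("smoking",          c(40, 147, 41, 78),  c(69, 256, 65, 136)),
    bin("illness",          c(58, 213, 58, 114), c(69, 256, 65, 136)),
    bin("medication_use",   c(30, 95, 30, 52),   c(69, 256, 65, 136)),
    bin("fam_hypertension", c(27, 88, 26, 44),   c(66, 241, 62, 128)),
    bin("fam_diabetes",     c(10, 51, 17, 16),   c(69, 252, 61, 132)),
    bin("fam_depression",   c(11, 63, 16, 20),   c(69, 250, 64, 132)),
    bin("fam_dementia",     c(19, 65, 15, 38),   c(69, 249, 64, 134))
  )
  father_edu <- list(
    low_stable    = c(primary = 17, middle = 20, high = 29) / 66,
    high_upper    = c(primary = 41, middle = 90, high = 102) / 233,
    low_declining = c(primary = 14, middle = 17, high = 27) / 58,
    high_lower    = c(primary = 29, middle = 45, high = 51) / 125
  )
  # 20 job categories ordered from unskilled (1) to director-level (20);
  # synthetic geometric tilt, flatter (more high-status mass) in the
  # high-performing groups.
  occ <- function(decay) {
    p <- decay ^ (20:1)
    p / sum(p)
  }
  father_occ <- list(
    low_stable = occ(1.12), high_upper = occ(1.02),
    low_declining = occ(1.12), high_lower = occ(1.06)
  )
  gaussian <- tibble::tibble(
    variable = rep(c("school_years", "iq", "bmi"), each = 4),
    archetype = rep(groups, times = 3),
    mean = c(10.76, 12.27, 11.05, 11.52,
             65.09, 79.85, 65.27, 71.91,
             27.2, 26.1, 27.5, 26.5),
    sd = c(2.59, 2.84, 2.56, 2.66,
           15.60, 14.27, 16.65, 14.43,
           3.8, 3.4, 4.0, 3.5)
  )
  list(binary = binary,
       categorical = list(father_education = father_edu,
                          father_occupation = father_occ),
       gaussian = gaussian)
}

#' Generate per-participant risk factors
#'
#' Factors are drawn independently per participant given the archetype
#' (marginal calibration only; the source tables report no cross-factor
#' correlations).
#'
#' @param cohort A `synthetic_cohort`.
#' @param prevalence_table See [default_risk_prevalences()].
#' @return A wide tibble, one row per participant.
#' @export
generate_risk_factors <- function(cohort,
                                  prevalence_table =
                                    default_risk_prevalences()) {
  cfg <- cohort$config
  participants <- cohort$participants
  if (any(prevalence_table$binary$prevalence < 0 |
          prevalence_table$binary$prevalence > 1)) {
    stop("binary prevalences must be in [0, 1]", call. = FALSE)
  }
  local_seed(child_seed(cfg$seed, 6L), {
    n <- nrow(participants)
    out <- tibble::tibble(participant_id = participants$participant_id,
                          archetype = participants$archetype)
    for (v in unique(prevalence_table$binary$variable)) {
      tab <- prevalence_table$binary[prevalence_table$binary$variable == v, ]
      p <- tab$prevalence[match(participants$archetype, tab$archetype)]
      p[is.na(p)] <- mean(tab$prevalence)
      out[[v]] <- ifelse(rbinom(n, 1, p) == 1, "yes", "no")
    }
    for (v in names(prevalence_table$categorical)) {
      probs <- prevalence_table$categorical[[v]]
      fallback <- Reduce(`+`, probs) / length(probs)
      out[[v]] <- vapply(participants$archetype, function(a) {
        p <- probs[[a]] %||% fallback
        lev <- names(p) %||% as.character(seq_along(p))
        sample(lev, 1, prob = p)
      }, character(1), USE.NAMES = FALSE)
    }
    g <- prevalence_table$gaussian
    for (v in unique(g$variable)) {
      tab <- g[g$variable == v, ]
      i <- match(participants$archetype, tab$archetype)
      mu <- tab$mean[i]; s <- tab$sd[i]
      mu[is.na(mu)] <- mean(tab$mean); s[is.na(s)] <- mean(tab$sd)
      out[[v]] <- rnorm(n, mu, s)
    }
    out
  })
}

# --- missingness ------------------------------------------------------------

#' Remove observations completely at random
#'
#' @param table A long feature table.
#' @param missing_rate Proportion removed, in `[0, 1)`.
#' @param seed Integer seed.
#' @param level `"cell"` removes individual observations; `"visit"` removes
#'   whole participant-visit blocks (modality absent at that visit).
#' @return A new feature table; the input is untouched.
#' @export
apply_missingness <- function(table, missing_rate, seed,
                              level = c("cell", "visit")) {
  level <- match.arg(level)
  stopifnot(missing_rate >= 0, missing_rate < 1)
  if (missing_rate == 0 || nrow(table) == 0) return(table)
  local_seed(seed, {
    if (level == "cell") {
      keep <- runif(nrow(table)) >= missing_rate
      table[keep, , drop = FALSE]
    } else {
      key <- unique(table[, c("participant_id", "visit_index")])
      drop <- key[runif(nrow(key)) < missing_rate, , drop = FALSE]
      bad <- paste(table$participant_id, table$visit_index) %in%
        paste(drop$participant_id, drop$visit_index)
      table[!bad, , drop = FALSE]
    }
  })
}

# --- cohort assembly --------------------------------------------------------

#' Generate a full synthetic cohort
#'
#' Draws participants with wave membership and visit ages, assigns trajectory
#' archetypes from the mixing weights, and generates every modality:
#' cognitive scores (with cell-level missingness and a complete-dropout
#' subset), ICV-corrected-ready MRI volumes (participant-level
#' availability), EEG availability plus per-visit SSVEP amplitude truths
#' (signals themselves are synthesized lazily by
#' [generate_eeg_signals()]), and risk factors. Identical config (including
#' seed) reproduces identical output.
#'
#' @param config A [cohort_config()].
#' @return An object of class `synthetic_cohort`: a list with `config`,
#'   `participants`, `visits`, `latent` (ground-truth latent trajectories),
#'   `cognitive`, `mri`, `icv`, `eeg_truth`, `risk_factors`, and `truth`
#'   (per-participant archetype labels).
#' @export
generate_cohort <- function(config = cohort_config()) {
  cfg <- validate_cohort_config(config)
  pv <- generate_participants(cfg)
  cohort <- list(config = cfg, participants = pv$participants,
                 visits = pv$visits)
  cohort$latent <- generate_latent(cfg, pv$participants, pv$visits)
  class(cohort) <- "synthetic_cohort"

  cognitive <- generate_cognitive_scores(cohort)
  # participants with completely missing cognitive data across all visits
  local_seed(child_seed(cfg$seed, 7L), {
    dropout <- pv$participants$participant_id[
      runif(nrow(pv$participants)) < cfg$cognitive_dropout_rate]
  })
  cognitive <- cognitive[!cognitive$participant_id %in% dropout, ,
                         drop = FALSE]
  cohort$cognitive <- apply_missingness(cognitive, cfg$missing_rate,
                                        child_seed(cfg$seed, 8L))

  mri <- generate_mri(cohort)
  local_seed(child_seed(cfg$seed, 9L), {
    has_mri <- pv$participants$participant_id[
      runif(nrow(pv$participants)) < cfg$mri_rate]
    has_eeg <- pv$participants$participant_id[
      runif(nrow(pv$participants)) < cfg$eeg_rate]
  })
  cohort$mri <- apply_missingness(
    mri$volumes[mri$volumes$participant_id %in% has_mri, , drop = FALSE],
    0.10, child_seed(cfg$seed, 10L), level = "visit")
  cohort$icv <- mri$icv

  eeg_truth <- eeg_amplitude_truth(cohort)
  eeg_truth <- eeg_truth[eeg_truth$participant_id %in% has_eeg, ,
                         drop = FALSE]
  # at most eeg_max_visits recordings per participant (earliest visits)
  eeg_truth <- dplyr::slice_min(
    dplyr::group_by(eeg_truth, .data$participant_id),
    .data$visit_index, n = cfg$eeg_max_visits, with_ties = FALSE)
  eeg_truth <- dplyr::ungroup(eeg_truth)
  cohort$eeg_truth <- eeg_truth

  cohort$risk_factors <- generate_risk_factors(cohort)
  cohort$truth <- tibble::tibble(
    participant_id = pv$participants$participant_id,
    archetype = pv$participants$archetype
  )
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>\n")
  cat(sprintf("  %d participants, %d visits\n", nrow(x$participants),
              nrow(x$visits)))
  cat(sprintf("  cognitive: %d obs of %d scores (%d participants)\n",
              nrow(x$cognitive), length(unique(x$cognitive$variable)),
              length(unique(x$cognitive$participant_id))))
  cat(sprintf("  mri      : %d obs of %d regions (%d participants)\n",
              nrow(x$mri), length(unique(x$mri$variable)),
              length(unique(x$mri$participant_id))))
  cat(sprintf("  eeg      : %d recordings (%d participants)\n",
              nrow(x$eeg_truth), length(unique(x$eeg_truth$participant_id))))
  tab <- table(x$participants$archetype)
  cat("  archetypes:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}
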