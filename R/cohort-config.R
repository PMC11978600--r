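#' Default trajectory archetypes
#'
#' Four latent trajectory classes emulate the qualitative cluster structure
#' of a middle-aged male birth cohort: a low-performing stable group, a
#' high-performing upper group, a low-performing declining group, and a
#' high-performing lower group. The latent space has two dimensions: a
#' composite cognitive level (z-scale) and a domain profile axis capturing
#' which cognitive domains dominate a participant's battery. Mixing weights
#' are proportional to the observed group sizes 69/256/65/136.
#'
#' The four archetype means form a near-equidistant configuration: the
#' level axis separates the high from the low pair, the profile axis
#' separates the two archetypes within each pair, and within-archetype
#' variation (random intercept + visit noise, ~0.3 z-units) stays small
#' against every pairwise separation. This realizes four cluster-detectable
#' groups rather than two nested super-groups, mirroring clearly separated
#' empirical clusters.
#'
#' @return A tibble with columns `name`, `baseline_level` (composite latent
#'   level, z-scale), `profile` (second latent dimension), `slope_per_year`
#'   (latent units/year on the composite dimension), `mixing_weight`.
#' @export
default_archetypes <- function() {
  tibble::tibble(
    name = c("low_stable", "high_upper", "low_declining", "high_lower"),
    baseline_level = c(-1.4, 1.7, -1.6, 1.3),
    profile = c(3.0, 3.0, -3.0, -3.0),
    slope_per_year = c(-0.010, 0.005, -0.100, -0.040),
    mixing_weight = c(69, 256, 65, 136) / 526
  )
}

validate_archetypes <- function(a) {
  stopifnot(is.data.frame(a), nrow(a) >= 1)
  if (abs(sum(a$mixing_weight) - 1) > 1e-9) {
    stop("archetype mixing weights must sum to 1", call. = FALSE)
  }
  low <- a$baseline_level[grepl("^low_", a$name)]
  high <- a$baseline_level[grepl("^high_", a$name)]
  if (length(low) && length(high) && max(low) >= min(high)) {
    stop("low_* archetypes must have baseline_level below high_* archetypes",
         call. = FALSE)
  }
  if ("low_declining" %in% a$name &&
      a$slope_per_year[a$name == "low_declining"] != min(a$slope_per_year)) {
    stop("low_declining must have the most negative slope_per_year",
         call. = FALSE)
  }
  invisible(a)
}

#' Catalog of synthetic cognitive scores
#'
#' 77 score names patterned on a standard neuropsychological battery:
#' 70 computerized-battery scores (motor screening, spatial/pattern
#' recognition memory, paired-associate learning, Stockings-of-Cambridge
#' planning, reaction time, rapid visual processing, spatial working memory,
#' delayed matching, set-shifting) plus 7 pencil-and-paper measures (MMSE,
#' ACE, SDMT, Trail-Making A/B, word pairs, retention). `higher_is_worse`
#' flags latency/error-type scores whose orientation is inverted relative to
#' the latent cognitive level (e.g. trail-making completion times).
#'
#' @return A tibble with columns `variable`, `battery`, `higher_is_worse`.
#' @export
cognitive_score_catalog <- function() {
  def <- function(test, items, flagged) {
    tibble::tibble(
      variable = paste(test, items, sep = "_"),
      battery = if (test %in% c("mmse", "ace", "sdmt", "tmt", "wordpairs",
                                "retention")) "paper" else "cantab",
      higher_is_worse = flagged
    )
  }
  out <- dplyr::bind_rows(
    def("mot", c("mean_latency", "mean_error", "accuracy"),
        c(TRUE, TRUE, FALSE)),
    def("srm", c("percent_correct", "mean_latency", "total_errors",
                 "a_prime"), c(FALSE, TRUE, TRUE, FALSE)),
    def("prm", c("percent_correct", "mean_latency", "total_errors",
                 "a_prime"), c(FALSE, TRUE, TRUE, FALSE)),
    def("pal", c("total_errors", "total_errors_adjusted", "total_trials",
                 "stages_completed", "first_trial_memory", "errors_to_success",
                 "trials_to_success", "memory_score", "errors_6_shapes",
                 "errors_8_shapes", "first_trial_stages", "total_attempts"),
        c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE,
          TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)),
    def("soc", c("problems_min_moves", "mean_moves_2", "mean_moves_3",
                 "mean_moves_4", "mean_moves_5", "initial_time_2",
                 "initial_time_5", "subsequent_time_2", "subsequent_time_5",
                 "problems_solved"),
        c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)),
    def("rti", c("simple_reaction_time", "simple_movement_time",
                 "choice_reaction_time", "choice_movement_time",
                 "simple_accuracy", "choice_accuracy", "simple_total_latency",
                 "choice_total_latency", "anticipatory_responses",
                 "correct_responses"),
        c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE)),
    def("rvp", c("a_prime", "b_double_prime", "hits", "misses",
                 "false_alarms", "correct_rejections", "mean_latency",
                 "total_correct", "prob_hit", "prob_false_alarm",
                 "total_misses", "total_false_alarms"),
        c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE,
          TRUE, TRUE)),
    def("swm", c("between_errors", "within_errors", "strategy",
                 "total_errors"), c(TRUE, TRUE, TRUE, TRUE)),
    def("dms", c("percent_correct", "percent_correct_delay", "mean_latency",
                 "total_errors", "prob_error_given_error"),
        c(FALSE, FALSE, TRUE, TRUE, TRUE)),
    def("ied", c("stages_completed", "total_errors", "ed_errors",
                 "pre_ed_errors", "total_trials", "stage_trials"),
        c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE)),
    def("mmse", "total", FALSE),
    def("ace", "total", FALSE),
    def("sdmt", "score", FALSE),
    def("tmt", c("a_time", "b_time"), c(TRUE, TRUE)),
    def("wordpairs", "score", FALSE),
    def("retention", "score", FALSE)
  )
  out
}

#' Cohort configuration
#'
#' Bundles every knob of the synthetic-cohort generator. Defaults emulate
#' the structure of a three-wave longitudinal male birth-cohort study:
#' wave sizes 211/503/113 with overlaps 136/99/10 giving 582 unique
#' participants, ages 57-68, 77 cognitive scores, 35 intracranial-volume
#' corrected regional brain volumes, 64-channel 2 kHz EEG with 8 Hz (alpha)
#' and 36 Hz (gamma) photic-stimulation responses.
#'
#' @param n_participants Unique participants implied by waves (default 582).
#' @param wave_sizes Participants assessed in each of 3 waves.
#' @param wave_overlaps `c(wave2-and-wave1, wave3-from-wave2, wave3-from-wave1-only)`.
#' @param age_range Assessment age limits in years.
#' @param wave_age_windows List of per-wave age windows (years).
#' @param n_cognitive_scores Number of cognitive scores (default 77).
#' @param n_mri_regions Number of regional brain volumes (default 35).
#' @param n_eeg_channels EEG montage size (default 64).
#' @param eeg_sampling_hz EEG sampling rate (default 2000 Hz).
#' @param stim_freqs_hz Named stimulation frequencies, Hz.
#' @param loading_matrix_rank Latent dimensionality feeding the scores.
#' @param noise_sd Per-score observation noise SD (z-scale).
#' @param missing_rate Cognitive cell-level missingness proportion.
#' @param cognitive_dropout_rate Fraction of participants with no cognitive
#'   data at all (emulates 526/582 analyzable participants).
#' @param mri_rate,eeg_rate Per-participant modality availability.
#' @param eeg_max_visits EEG recorded at most this many visits.
#' @param archetypes Archetype tibble, see [default_archetypes()].
#' @param seed Integer master seed.
#' @return An object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_participants = 582L,
                          wave_sizes = c(211L, 503L, 113L),
                          wave_overlaps = c(136L, 99L, 10L),
                          age_range = c(57, 68),
                          wave_age_windows = list(c(57, 59), c(61, 67),
                                                  c(66, 68)),
                          n_cognitive_scores = 77L,
                          n_mri_regions = 35L,
                          n_eeg_channels = 64L,
                          eeg_sampling_hz = 2000,
                          stim_freqs_hz = c(alpha = 8, gamma = 36),
                          loading_matrix_rank = 2L,
                          noise_sd = 0.3,
                          missing_rate = 0.05,
                          cognitive_dropout_rate = 56 / 582,
                          mri_rate = 0.36,
                          eeg_rate = 0.66,
                          eeg_max_visits = 2L,
                          archetypes = default_archetypes(),
                          seed = 20260101L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    wave_sizes = as.integer(wave_sizes),
    wave_overlaps = as.integer(wave_overlaps),
    age_range = as.numeric(age_range),
    wave_age_windows = wave_age_windows,
    n_cognitive_scores = as.integer(n_cognitive_scores),
    n_mri_regions = as.integer(n_mri_regions),
    n_eeg_channels = as.integer(n_eeg_channels),
    eeg_sampling_hz = as.numeric(eeg_sampling_hz),
    stim_freqs_hz = stim_freqs_hz,
    loading_matrix_rank = as.integer(loading_matrix_rank),
    noise_sd = as.numeric(noise_sd),
    missing_rate = as.numeric(missing_rate),
    cognitive_dropout_rate = as.numeric(cognitive_dropout_rate),
    mri_rate = as.numeric(mri_rate),
    eeg_rate = as.numeric(eeg_rate),
    eeg_max_visits = as.integer(eeg_max_visits),
    archetypes = archetypes,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  w <- cfg$wave_sizes
  o <- cfg$wave_overlaps
  if (length(w) != 3 || length(o) != 3 || any(w < 0) || any(o < 0)) {
    stop("wave_sizes and wave_overlaps must be 3 non-negative integers",
         call. = FALSE)
  }
  if (o[1] > min(w[1], w[2])) {
    stop("overlap wave1-wave2 exceeds a wave size", call. = FALSE)
  }
  if (o[2] + o[3] > w[3]) {
    stop("wave-3 overlaps exceed the wave-3 size", call. = FALSE)
  }
  implied <- w[1] + (w[2] - o[1]) + (w[3] - o[2] - o[3])
  if (implied != cfg$n_participants) {
    stop(sprintf(
      paste0("wave arithmetic inconsistent: %d + (%d - %d) + ",
             "(%d - %d - %d) = %d unique participants, but n_participants ",
             "= %d"),
      w[1], w[2], o[1], w[3], o[2], o[3], implied, cfg$n_participants),
      call. = FALSE)
  }
  if (max(cfg$stim_freqs_hz) >= cfg$eeg_sampling_hz / 2) {
    stop("stimulation frequencies must lie below the Nyquist frequency",
         call. = FALSE)
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  }
  validate_archetypes(cfg$archetypes)
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  participants : %d unique over waves %s (overlaps %s)\n",
              x$n_participants, paste(x$wave_sizes, collapse = "/"),
              paste(x$wave_overlaps, collapse = "/")))
  cat(sprintf("  ages         : %g-%g years\n", x$age_range[1],
              x$age_range[2]))
  cat(sprintf("  modalities   : %d cognitive scores, %d MRI regions, %d EEG channels @ %g Hz\n",
              x$n_cognitive_scores, x$n_mri_regions, x$n_eeg_channels,
              x$eeg_sampling_hz))
  cat(sprintf("  archetypes   : %s\n",
              paste(x$archetypes$name, collapse = ", ")))
  cat(sprintf("  seed         : %d\n", x$seed))
  invisible(x)
}
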