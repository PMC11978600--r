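#' 64-channel montage (10-20 extension)
#'
#' Channel labels for an extended 10-20 elastic-cap layout with 64
#' electrodes.
#'
#' @return Character vector of 64 channel names.
#' @export
channel_montage_64 <- function() {
  c("Fp1", "Fpz", "Fp2", "AF7", "AF3", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO5", "PO3", "POz", "PO4", "PO6", "PO8",
    "CB1", "O1", "Oz", "O2", "CB2")
}

#' Scalp regions for the 64-channel montage
#'
#' Disjoint assignment of the montage channels to the five analysis
#' regions; fronto-central/centro-parietal rows and midline channels are
#' assigned to `central`.
#'
#' @return Named list mapping region name to channel names.
#' @export
region_map_64 <- function() {
  list(
    temporal = c("FT7", "FT8", "T7", "T8", "TP7", "TP8"),
    frontal = c("Fp1", "Fpz", "Fp2", "AF7", "AF3", "AF4", "AF8",
                "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"),
    central = c("FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6",
                "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
                "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6"),
    parietal = c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
                 "PO7", "PO5", "PO3", "POz", "PO4", "PO6", "PO8"),
    occipital = c("CB1", "O1", "Oz", "O2", "CB2")
  )
}

# Archetype multipliers on SSVEP amplitude: the low-stable group has the
# lowest evoked power; differences are carried mainly by the parietal and
# temporal channels (attenuated elsewhere).
eeg_group_factors <- function() {
  tibble::tibble(
    archetype = c("low_stable", "high_upper", "low_declining", "high_lower"),
    alpha = c(0.82, 1.08, 0.93, 1.00),
    gamma = c(0.86, 1.08, 0.96, 1.00)
  )
}

# Per participant-visit SSVEP amplitude truth (uV), with log-normal
# between-recording jitter.
eeg_amplitude_truth <- function(cohort, base_alpha = 4, base_gamma = 1.5,
                                jitter_sd_log = 0.25) {
  cfg <- cohort$config
  visits <- cohort$visits
  fac <- eeg_group_factors()
  arch <- cohort$participants$archetype[
    match(visits$participant_id, cohort$participants$participant_id)]
  i <- match(arch, fac$archetype)
  ga <- ifelse(is.na(i), 1, fac$alpha[i])
  gg <- ifelse(is.na(i), 1, fac$gamma[i])
  local_seed(child_seed(cfg$seed, 11L), {
    tibble::tibble(
      participant_id = visits$participant_id,
      visit_index = visits$visit_index,
      age = visits$age,
      amp_alpha = base_alpha * ga * exp(rnorm(nrow(visits), 0,
                                              jitter_sd_log)),
      amp_gamma = base_gamma * gg * exp(rnorm(nrow(visits), 0,
                                              jitter_sd_log))
    )
  })
}

# Pink (1/f) noise via spectral shaping of white noise, unit variance.
pink_noise <- function(n) {
  x <- rnorm(n)
  X <- fft(x)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)            # two-sided frequency index
  X <- X / sqrt(pmax(f, 1))
  y <- Re(fft(X, inverse = TRUE)) / n
  s <- sd(y)
  if (s > 0) y / s else y
}

#' Generate one synthetic SSVEP EEG recording
#'
#' Each channel is 1/f-shaped background noise plus sinusoids at the two
#' stimulation frequencies. The stimulus amplitude is modulated by the
#' channel's scalp region: parietal and temporal channels carry the full
#' archetype-dependent amplitude; other regions receive a damped group
#' effect, so group differences concentrate temporo-parietally.
#'
#' @param amp_alpha,amp_gamma Stimulus-response amplitudes (uV) at the two
#'   stimulation frequencies for this recording.
#' @param fs Sampling rate, Hz.
#' @param duration_s Recording length, seconds (>= 4).
#' @param noise_sd Background noise SD (uV); 0 gives the noiseless limit.
#' @param channels Channel names; defaults to the 64-channel montage.
#' @param stim_freqs_hz Named stimulation frequencies, Hz.
#' @param seed Integer seed.
#' @return A list with `samples` (channels x time matrix, uV), `fs`,
#'   `channels`.
#' @export
generate_eeg_recording <- function(amp_alpha, amp_gamma, fs = 2000,
                                   duration_s = 8, noise_sd = 6,
                                   channels = channel_montage_64(),
                                   stim_freqs_hz = c(alpha = 8, gamma = 36),
                                   seed = 1L) {
  stopifnot(duration_s >= 4)
  n <- round(fs * duration_s)
  t <- (seq_len(n) - 1) / fs
  rmap <- region_map_64()
  region_of <- rep("central", length(channels))
  for (r in names(rmap)) region_of[channels %in% rmap[[r]]] <- r
  # regional gain on the evoked response; temporo-parietal dominant
  base_gain <- c(temporal = 1.0, frontal = 0.7, central = 0.8,
                 parietal = 1.2, occipital = 1.1)
  # fraction of the archetype amplitude modulation expressed per region
  mod_gain <- c(temporal = 1.0, frontal = 0.35, central = 0.35,
                parietal = 1.0, occipital = 0.35)
  local_seed(seed, {
    samples <- matrix(0, length(channels), n,
                      dimnames = list(channels, NULL))
    phi <- runif(2, 0, 2 * pi)
    for (ch in seq_along(channels)) {
      reg <- region_of[ch]
      # damped modulation: pull amplitude toward the montage mean outside
      # the carrier regions
      aa <- amp_alpha * mod_gain[reg] + mean(amp_alpha) * (1 - mod_gain[reg])
      ag <- amp_gamma * mod_gain[reg] + mean(amp_gamma) * (1 - mod_gain[reg])
      sig <- base_gain[reg] *
        (aa * sin(2 * pi * stim_freqs_hz[["alpha"]] * t + phi[1]) +
           ag * sin(2 * pi * stim_freqs_hz[["gamma"]] * t + phi[2]))
      bg <- if (noise_sd > 0) noise_sd * pink_noise(n) else 0
      samples[ch, ] <- sig + bg
    }
    list(samples = samples, fs = fs, channels = channels)
  })
}

#' Generate synthetic EEG recordings for cohort participant-visits
#'
#' @param cohort A `synthetic_cohort`.
#' @param recordings Optional subset of `cohort$eeg_truth` rows; defaults to
#'   all available recordings (use with care: the full cohort at 2 kHz is
#'   large — prefer [cohort_regional_powers()] which streams).
#' @param duration_s Recording length, seconds.
#' @param noise_sd Background noise SD (uV).
#' @return A list of recordings; each carries `participant_id`,
#'   `visit_index`, `samples`, `fs`, `channels`.
#' @export
generate_eeg_signals <- function(cohort, recordings = NULL, duration_s = 8,
                                 noise_sd = 6) {
  cfg <- cohort$config
  truth <- recordings %||% cohort$eeg_truth
  channels <- channel_montage_64()[seq_len(cfg$n_eeg_channels)]
  lapply(seq_len(nrow(truth)), function(i) {
    rec <- generate_eeg_recording(
      amp_alpha = truth$amp_alpha[i], amp_gamma = truth$amp_gamma[i],
      fs = cfg$eeg_sampling_hz, duration_s = duration_s,
      noise_sd = noise_sd, channels = channels,
      stim_freqs_hz = cfg$stim_freqs_hz,
      seed = child_seed(cfg$seed, 100L + i))
    rec$participant_id <- truth$participant_id[i]
    rec$visit_index <- truth$visit_index[i]
    rec
  })
}
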