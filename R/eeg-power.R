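#' Welch power spectral density
#'
#' Averaged modified periodogram over overlapping windowed segments, with
#' one-sided Parseval-consistent density scaling: `sum(psd) * df` equals the
#' signal variance for stationary noise (up to estimation error).
#'
#' @param x Numeric signal (one channel).
#' @param fs Sampling rate, Hz.
#' @param segment_s Segment length in seconds; frequency resolution is
#'   `1/segment_s`.
#' @param overlap_frac Fractional overlap between consecutive segments.
#' @param window `"hann"` (periodic) or `"rectangular"`.
#' @return A list with `frequencies` (Hz) and `psd` (uV^2/Hz).
#' @export
welch_psd <- function(x, fs, segment_s = 2, overlap_frac = 0.5,
                      window = c("hann", "rectangular")) {
  window <- match.arg(window)
  nseg <- round(segment_s * fs)
  if (length(x) < nseg) {
    stop(sprintf("signal too short: %d samples, need at least %d",
                 length(x), nseg), call. = FALSE)
  }
  w <- if (window == "hann") {
    0.5 * (1 - cos(2 * pi * (seq_len(nseg) - 1) / nseg))
  } else {
    rep(1, nseg)
  }
  step <- max(1L, round(nseg * (1 - overlap_frac)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  nfreq <- nseg %/% 2 + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)] * w
    X <- fft(seg)
    acc <- acc + Mod(X[seq_len(nfreq)])^2
  }
  U <- sum(w^2)
  psd <- acc / (length(starts) * fs * U)
  # one-sided: double everything except DC (and Nyquist for even nseg)
  dbl <- rep(2, nfreq)
  dbl[1] <- 1
  if (nseg %% 2 == 0) dbl[nfreq] <- 1
  psd <- psd * dbl
  list(frequencies = (seq_len(nfreq) - 1) * fs / nseg, psd = psd)
}

#' Peak power near a target frequency
#'
#' @param frequencies,psd A spectrum as returned by [welch_psd()].
#' @param target_hz Stimulation frequency.
#' @param search_halfwidth_hz Half-width of the search window, Hz.
#' @return Maximum PSD value within `target_hz +/- search_halfwidth_hz`.
#' @export
peak_power_at <- function(frequencies, psd, target_hz,
                          search_halfwidth_hz = 0.5) {
  if (target_hz < min(frequencies) || target_hz > max(frequencies)) {
    stop("target frequency outside the spectrum range", call. = FALSE)
  }
  sel <- frequencies >= target_hz - search_halfwidth_hz &
    frequencies <= target_hz + search_halfwidth_hz
  if (!any(sel)) stop("search window contains no frequency bin",
                      call. = FALSE)
  max(psd[sel])
}

#' Compensate the 1/f spectral shape
#'
#' Multiplies each spectral value by its frequency, flattening a 1/f
#' background; the DC bin becomes 0.
#'
#' @param frequencies,psd A spectrum.
#' @return Compensated power values.
#' @export
compensate_1overf <- function(frequencies, psd) {
  stopifnot(all(frequencies >= 0), length(frequencies) == length(psd))
  psd * frequencies
}

#' Aggregate per-channel powers into scalp regions
#'
#' @param channel_powers Named numeric vector (names = channel labels).
#' @param region_map Named list region -> channel names; see
#'   [region_map_64()].
#' @return Named numeric vector of per-region mean powers; regions without
#'   any usable channel are dropped with a warning.
#' @export
aggregate_regions <- function(channel_powers, region_map = region_map_64()) {
  out <- vapply(region_map, function(chs) {
    v <- channel_powers[names(channel_powers) %in% chs]
    v <- v[is.finite(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  if (anyNA(out)) {
    warning("regions without usable channels dropped: ",
            paste(names(out)[is.na(out)], collapse = ", "))
    out <- out[!is.na(out)]
  }
  out
}

#' Regional SSVEP powers for one recording
#'
#' Per channel: Welch PSD, 1/f compensation, peak power at each stimulation
#' frequency; then regional averaging. Emits 5 regions x 2 bands = 10
#' values per recording.
#'
#' @param recording A recording list (`samples`, `fs`, `channels`, and
#'   optionally `participant_id`, `visit_index`).
#' @param stim_freqs_hz Named stimulation frequencies.
#' @param region_map Region -> channels map.
#' @param segment_s,search_halfwidth_hz Spectral parameters.
#' @return A tibble with columns `participant_id`, `visit_index`, `region`,
#'   `band`, `power`.
#' @export
extract_regional_power <- function(recording,
                                   stim_freqs_hz = c(alpha = 8, gamma = 36),
                                   region_map = region_map_64(),
                                   segment_s = 2,
                                   search_halfwidth_hz = 0.5) {
  ch_names <- recording$channels
  nb <- length(stim_freqs_hz)
  peaks <- matrix(NA_real_, length(ch_names), nb,
                  dimnames = list(ch_names, names(stim_freqs_hz)))
  for (i in seq_along(ch_names)) {
    sp <- welch_psd(recording$samples[i, ], recording$fs,
                    segment_s = segment_s)
    comp <- compensate_1overf(sp$frequencies, sp$psd)
    for (b in seq_len(nb)) {
      peaks[i, b] <- peak_power_at(sp$frequencies, comp,
                                   stim_freqs_hz[[b]],
                                   search_halfwidth_hz)
    }
  }
  rows <- lapply(names(stim_freqs_hz), function(band) {
    reg <- aggregate_regions(peaks[, band], region_map)
    tibble::tibble(
      participant_id = recording$participant_id %||% NA_character_,
      visit_index = recording$visit_index %||% NA_integer_,
      region = names(reg), band = band, power = unname(reg)
    )
  })
  dplyr::bind_rows(rows)
}

#' Z-score regional powers across participants
#'
#' Within each (region, band), optionally log-transforms and then centers
#' and scales across all participant-visits, giving standardized regional
#' SSVEP measures.
#'
#' @param table Output rows of [extract_regional_power()] (pooled).
#' @param log_transform Log-transform before z-scoring (default TRUE;
#'   evoked-power distributions are right-skewed).
#' @return The table with a `z_power` column replacing `power`.
#' @export
zscore_powers <- function(table, log_transform = TRUE) {
  stopifnot(all(c("region", "band", "power") %in% names(table)))
  dplyr::mutate(
    dplyr::group_by(table, .data$region, .data$band),
    z_power = {
      v <- if (log_transform) log(.data$power) else .data$power
      n_ok <- sum(is.finite(v))
      if (n_ok < 2) stop("need >= 2 participants per region-band")
      s <- sd(v[is.finite(v)])
      if (!is.finite(s) || s == 0) stop("zero SD in a region-band")
      (v - mean(v[is.finite(v)])) / s
    }
  ) |>
    dplyr::ungroup() |>
    dplyr::select(-"power")
}

#' Regional SSVEP power table for a whole cohort
#'
#' Streams over the cohort's available EEG recordings: synthesizes each
#' recording, reduces it to 10 regional band powers, and discards the raw
#' signal, so the full cohort never resides in memory at once.
#'
#' @param cohort A `synthetic_cohort`.
#' @param duration_s,noise_sd Signal-generation parameters.
#' @param log_transform Passed to [zscore_powers()].
#' @return A long feature table with `variable = region_band` and z-scored
#'   values, plus `age`.
#' @export
cohort_regional_powers <- function(cohort, duration_s = 8, noise_sd = 6,
                                   log_transform = TRUE) {
  cfg <- cohort$config
  truth <- cohort$eeg_truth
  channels <- channel_montage_64()[seq_len(cfg$n_eeg_channels)]
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    rec <- generate_eeg_recording(
      amp_alpha = truth$amp_alpha[i], amp_gamma = truth$amp_gamma[i],
      fs = cfg$eeg_sampling_hz, duration_s = duration_s,
      noise_sd = noise_sd, channels = channels,
      stim_freqs_hz = cfg$stim_freqs_hz,
      seed = child_seed(cfg$seed, 100L + i))
    rec$participant_id <- truth$participant_id[i]
    rec$visit_index <- truth$visit_index[i]
    extract_regional_power(rec, stim_freqs_hz = cfg$stim_freqs_hz)
  })
  tab <- zscore_powers(dplyr::bind_rows(rows), log_transform = log_transform)
  ages <- cohort$visits
  tibble::tibble(
    participant_id = tab$participant_id,
    visit_index = tab$visit_index,
    age = ages$age[match(paste(tab$participant_id, tab$visit_index),
                         paste(ages$participant_id, ages$visit_index))],
    variable = paste(tab$region, tab$band, sep = "_"),
    value = tab$z_power
  )
}
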