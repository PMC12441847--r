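# shared, cheap fixtures: short low-rate configs keep most tests fast; the
# desk-scale 4 kHz profile only appears in the heavier end-to-end checks

quiet_config <- function(...) {
  # colored noise only: no spikes, so spectral statistics are clean
  base <- list(sampling_rate = 500, blank_min = 0, medium_min = 4,
               drug_min = 4,
               noise = list(white_sigma = 1, pink_amplitude = 0.3),
               resonance = list(freq_hz = 180, q_factor = 15,
                                amplitude = 0.4),
               spikes = list(rate_hz = 0),
               effect = list(band_lo_hz = 10, band_hi_hz = 50))
  do.call(simulation_config, utils::modifyList(base, list(...)))
}

white_config <- function(duration_min = 1, fs = 4000, seed = 1L,
                         label = "negative") {
  simulation_config(sampling_rate = fs, blank_min = 0,
                    medium_min = duration_min / 2,
                    drug_min = duration_min / 2,
                    noise = list(white_sigma = 1, pink_amplitude = 0),
                    resonance = list(amplitude = 0),
                    spikes = list(rate_hz = 0),
                    effect = list(band_lo_hz = 10, band_hi_hz = 100),
                    label = label, seed = seed)
}

# hand-built quantile spectrogram with fully controlled values, for feature
# arithmetic tests: values[level, freq, window]
toy_spectrogram <- function(values, levels, freqs_hz, window_starts_min,
                            window_min) {
  structure(
    list(values = values, levels = levels, freqs_hz = freqs_hz,
         window_starts_min = window_starts_min, window_min = window_min,
         welch = welch_params()),
    class = "quantile_spectrogram"
  )
}

# spectrogram whose band_power over band [0, 2) Hz at level 0.5 equals
# `powers[j]` in window j (bins at 1 Hz carry the value; DC excluded)
powers_spectrogram <- function(powers, window_starts_min = NULL,
                               window_min = 5) {
  n_win <- length(powers)
  if (is.null(window_starts_min)) {
    window_starts_min <- (seq_len(n_win) - 1L) * window_min
  }
  vals <- array(1, dim = c(1L, 2L, n_win))
  vals[1L, 2L, ] <- powers
  toy_spectrogram(vals, levels = 0.5, freqs_hz = c(0, 1),
                  window_starts_min = window_starts_min,
                  window_min = window_min)
}

# feature matrix built directly from a value matrix (bypasses spectrograms)
toy_feature_matrix <- function(values, labels,
                               sample_ids = as.character(seq_len(nrow(values)))) {
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("f%02d", seq_len(ncol(values)))
  }
  structure(list(values = values, descriptors = NULL,
                 sample_ids = sample_ids, labels = labels,
                 concentrations_uM = rep(0, nrow(values))),
            class = "feature_matrix")
}
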