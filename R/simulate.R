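#' Configuration for the synthetic nanomotion-signal generator
#'
#' Builds the parameter set for [simulate_recording()]. The generator emits a
#' unit-scale, phase-annotated deflection signal with the statistical
#' structure the downstream analysis assumes: stationary colored noise
#' (white + 1/f^alpha + a cantilever-resonance peak), intermittent spikes,
#' and — for positive labels only, during the drug phase only — a
#' band-limited multiplicative change in power with an exponential onset.
#'
#' The default profile is desk-scale: 4 kHz sampling (Nyquist 2 kHz) with the
#' resonance at 1700 Hz. A high-rate profile (e.g. `sampling_rate = 18000`,
#' `resonance$freq_hz = 8500`) supports bands up to 8 kHz just below a
#' cantilever resonance. Any resonance frequency or effect band above Nyquist
#' is a configuration error.
#'
#' @param sampling_rate Sampling rate in Hz.
#' @param blank_min,medium_min,drug_min Phase durations in minutes.
#' @param noise List: `white_sigma` (sd of the white floor, deflection
#'   units), `pink_amplitude` (1/f component amplitude at 1 Hz),
#'   `pink_exponent` (alpha in 1/f^alpha).
#' @param resonance List: `freq_hz`, `q_factor`, `amplitude` (peak sd
#'   contribution of the resonator-shaped component).
#' @param spikes List: `rate_hz` (Poisson event rate), `amp_scale`
#'   (exponential amplitude scale), `width_s` (half-sine pulse width).
#' @param effect List: `band_lo_hz`, `band_hi_hz` (half-open band),
#'   `power_ratio` (asymptotic multiplicative band-power factor after drug
#'   onset), `spike_rate_ratio`, `tau_min` (exponential onset time
#'   constant).
#' @param label `"positive"` (responds to the drug) or `"negative"`.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(sampling_rate = 4000,
                              blank_min = 5, medium_min = 120, drug_min = 120,
                              noise = list(),
                              resonance = list(),
                              spikes = list(),
                              effect = list(),
                              label = c("negative", "positive"),
                              seed = 1L) {
  label <- match.arg(label)
  noise <- utils::modifyList(
    list(white_sigma = 1, pink_amplitude = 0.5, pink_exponent = 1), noise)
  resonance <- utils::modifyList(
    list(freq_hz = 1700, q_factor = 20, amplitude = 0.5), resonance)
  spikes <- utils::modifyList(
    list(rate_hz = 0.02, amp_scale = 5, width_s = 0.01), spikes)
  effect <- utils::modifyList(
    list(band_lo_hz = 10, band_hi_hz = 100, power_ratio = 1,
         spike_rate_ratio = 1, tau_min = 10), effect)
  cfg <- list(sampling_rate = sampling_rate, blank_min = blank_min,
              medium_min = medium_min, drug_min = drug_min, noise = noise,
              resonance = resonance, spikes = spikes, effect = effect,
              label = label, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_sim_config <- function(cfg) {
  nyq <- cfg$sampling_rate / 2
  stopifnot(cfg$sampling_rate > 0, cfg$medium_min > 0, cfg$drug_min > 0,
            cfg$blank_min >= 0, cfg$noise$white_sigma >= 0,
            cfg$noise$pink_amplitude >= 0, cfg$resonance$amplitude >= 0,
            cfg$spikes$rate_hz >= 0, cfg$effect$power_ratio > 0,
            cfg$effect$spike_rate_ratio >= 0, cfg$effect$tau_min > 0,
            cfg$effect$band_lo_hz < cfg$effect$band_hi_hz)
  if (cfg$effect$band_hi_hz > nyq) {
    stop("simulation_config: effect band [", cfg$effect$band_lo_hz, ", ",
         cfg$effect$band_hi_hz, ") Hz exceeds Nyquist (", nyq, " Hz)")
  }
  if (cfg$resonance$amplitude > 0 && cfg$resonance$freq_hz >= nyq) {
    stop("simulation_config: resonance frequency ", cfg$resonance$freq_hz,
         " Hz is at or above Nyquist (", nyq, " Hz)")
  }
  invisible(cfg)
}

# |H(f)|^2 of an RBJ constant-peak-gain biquad resonator, peak normalized to 1
resonator_gain2 <- function(f, fs, f0, q) {
  w <- 2 * pi * f / fs
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  z1 <- exp(-1i * w)
  num <- alpha * (1 - z1^2)
  den <- (1 + alpha) + (-2 * cos(w0)) * z1 + (1 - alpha) * z1^2
  g2 <- Mod(num / den)^2
  g2 / max(g2)
}

# onset profile: multiplicative band-power factor at time t (seconds past
# drug onset); 1 before onset, relaxing to `ratio` with time constant tau
effect_factor <- function(t_s, ratio, tau_s) {
  out <- rep(1, length(t_s))
  on <- t_s > 0
  out[on] <- 1 + (ratio - 1) * (1 - exp(-t_s[on] / tau_s))
  out
}

#' Simulate one nanomotion recording
#'
#' Frequency-domain synthesis: a white-noise draw is shaped by the summed
#' power spectral density of the white floor, the 1/f^alpha component and
#' the resonator peak (sums of independent Gaussian processes are equivalent
#' to one process with the summed PSD). The shaped spectrum is split into
#' in-band and out-of-band parts at the effect band edges, so the injected
#' class effect is exactly band-localized: for positive labels the in-band
#' part is scaled by the square root of the onset profile (reaching
#' `power_ratio` with time constant `tau_min` after drug onset) while the
#' out-of-band part is untouched. A Poisson spike train (half-sine pulses,
#' exponential amplitudes, random sign) is added last; for positive labels
#' its rate relaxes toward `rate_hz * spike_rate_ratio` with the same onset
#' profile.
#'
#' Synthesis proceeds in independent blocks (`block_s`, default 60 s) to
#' bound the FFT working set on hour-scale recordings; each block is an
#' exact stationary draw from the configured PSD, and the rare analysis
#' segment straddling a block splice still sees the same marginal spectrum.
#'
#' @param cfg A `simulation_config`.
#' @param block_s Synthesis block length in seconds.
#' @return A `deflection_recording` with phases annotated per `cfg` and
#'   metadata recording the label and seed.
#' @export
simulate_recording <- function(cfg, block_s = 60) {
  validate_sim_config(cfg)
  fs <- cfg$sampling_rate
  n_blank <- round(cfg$blank_min * 60 * fs)
  n_medium <- round(cfg$medium_min * 60 * fs)
  n_drug <- round(cfg$drug_min * 60 * fs)
  n <- n_blank + n_medium + n_drug
  drug_onset_s <- (cfg$blank_min + cfg$medium_min) * 60
  apply_effect <- cfg$label == "positive" && cfg$effect$power_ratio != 1
  set.seed(cfg$seed)

  block_shape <- function(nb) {
    k <- 0:(nb - 1)
    f <- fs * pmin(k, nb - k) / nb
    psd <- rep(cfg$noise$white_sigma^2, nb)
    if (cfg$noise$pink_amplitude > 0) {
      psd <- psd + cfg$noise$pink_amplitude^2 *
        pmax(f, 0.1)^(-cfg$noise$pink_exponent)
    }
    if (cfg$resonance$amplitude > 0) {
      psd <- psd + cfg$resonance$amplitude^2 *
        resonator_gain2(f, fs, cfg$resonance$freq_hz, cfg$resonance$q_factor)
    }
    list(shape = sqrt(psd),
         in_band = f >= cfg$effect$band_lo_hz & f < cfg$effect$band_hi_hz)
  }

  nb_full <- min(n, round(block_s * fs))
  sh_full <- block_shape(nb_full)
  x <- numeric(n)
  i0 <- 1L
  while (i0 <= n) {
    nb <- min(nb_full, n - i0 + 1L)
    sh <- if (nb == nb_full) sh_full else block_shape(nb)
    W <- hermitian_gaussian_spectrum(nb) * sh$shape
    if (apply_effect) {
      x_full <- Re(stats::fft(W, inverse = TRUE)) / nb
      x_in <- Re(stats::fft(W * sh$in_band, inverse = TRUE)) / nb
      t_s <- (i0 - 1L + 0:(nb - 1L) + 0.5) / fs - drug_onset_s
      g <- sqrt(effect_factor(t_s, cfg$effect$power_ratio,
                              cfg$effect$tau_min * 60))
      x[i0:(i0 + nb - 1L)] <- x_full + (g - 1) * x_in
    } else {
      x[i0:(i0 + nb - 1L)] <- Re(stats::fft(W, inverse = TRUE)) / nb
    }
    i0 <- i0 + nb
  }

  x <- x + simulate_spike_train(cfg, n, drug_onset_s)

  phases <- rbind(
    if (n_blank > 0) phase_span("blank", 0, n_blank / fs),
    phase_span("medium", n_blank / fs, (n_blank + n_medium) / fs),
    phase_span("drug", (n_blank + n_medium) / fs, n / fs)
  )
  deflection_recording(
    x, fs, phases = phases,
    meta = list(experiment_id = sprintf("sim-%d", cfg$seed),
                cell_line = "synthetic", drug = "synthetic",
                concentration_uM = 0, label = cfg$label, seed = cfg$seed)
  )
}

# DFT of nb iid standard normals, drawn directly in the frequency domain:
# DC (and Nyquist for even nb) are real N(0, nb); interior bins are complex
# with independent N(0, nb/2) parts and hermitian mirror images
hermitian_gaussian_spectrum <- function(nb) {
  z <- stats::rnorm(nb)
  W <- complex(nb)
  even <- nb %% 2L == 0L
  W[1L] <- z[1L] * sqrt(nb)
  if (even) W[nb %/% 2L + 1L] <- z[2L] * sqrt(nb)
  n_int <- (nb - 1L - if (even) 1L else 0L) %/% 2L
  if (n_int > 0L) {
    rest <- z[(if (even) 3L else 2L):nb]
    ki <- seq_len(n_int)
    Wi <- sqrt(nb / 2) * complex(real = rest[2L * ki - 1L],
                                 imaginary = rest[2L * ki])
    W[ki + 1L] <- Wi
    W[nb + 1L - ki] <- Conj(Wi)
  }
  W
}

# inhomogeneous Poisson spike train by thinning at the peak rate
simulate_spike_train <- function(cfg, n, drug_onset_s) {
  out <- numeric(n)
  sp <- cfg$spikes
  if (sp$rate_hz <= 0) return(out)
  fs <- cfg$sampling_rate
  dur_s <- n / fs
  rate_late <- sp$rate_hz *
    if (cfg$label == "positive") cfg$effect$spike_rate_ratio else 1
  rate_max <- max(sp$rate_hz, rate_late)
  n_ev <- stats::rpois(1, rate_max * dur_s)
  if (n_ev == 0) return(out)
  t_ev <- sort(stats::runif(n_ev, 0, dur_s))
  rate_t <- sp$rate_hz * effect_factor(
    t_ev - drug_onset_s,
    if (cfg$label == "positive") cfg$effect$spike_rate_ratio else 1,
    cfg$effect$tau_min * 60)
  keep <- stats::runif(n_ev) < rate_t / rate_max
  t_ev <- t_ev[keep]
  if (!length(t_ev)) return(out)
  amp <- stats::rexp(length(t_ev), rate = 1 / sp$amp_scale) *
    sample(c(-1, 1), length(t_ev), replace = TRUE)
  wlen <- max(2L, round(sp$width_s * fs))
  pulse <- sin(pi * seq(0, 1, length.out = wlen))
  for (j in seq_along(t_ev)) {
    i0 <- round(t_ev[j] * fs) + 1L
    i1 <- min(i0 + wlen - 1L, n)
    out[i0:i1] <- out[i0:i1] + amp[j] * pulse[seq_len(i1 - i0 + 1L)]
  }
  out
}

#' Simulate a labeled cohort of recordings
#'
#' Per-recording seeds are drawn deterministically from the master seed, so
#' the same call always yields the same cohort; positives come first.
#'
#' @param n_pos,n_neg Number of positive / negative recordings.
#' @param cfg_template A `simulation_config`; its `label` and `seed` are
#'   overridden per recording.
#' @param seed Master integer seed.
#' @param concentrations_uM Optional vector (length `n_pos + n_neg`) of
#'   per-recording drug concentrations recorded in the metadata.
#' @return A list of class `nanomotion_cohort` with elements `recordings`,
#'   `labels`, `concentrations_uM`.
#' @export
simulate_cohort <- function(n_pos, n_neg, cfg_template, seed,
                            concentrations_uM = NULL) {
  stopifnot(n_pos >= 0, n_neg >= 0, n_pos + n_neg >= 1)
  n <- n_pos + n_neg
  labels <- c(rep("positive", n_pos), rep("negative", n_neg))
  if (is.null(concentrations_uM)) concentrations_uM <- rep(0, n)
  stopifnot(length(concentrations_uM) == n)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    cfg_i <- cfg_template
    cfg_i$label <- labels[i]
    cfg_i$seed <- seeds[i]
    recs[[i]] <- simulate_recording(cfg_i)
    recs[[i]]$meta$concentration_uM <- concentrations_uM[i]
  }
  structure(list(recordings = recs, labels = labels,
                 concentrations_uM = concentrations_uM),
            class = "nanomotion_cohort")
}

#' Simulate a cohort and reduce each recording to its quantile spectrogram
#'
#' Streaming variant of [simulate_cohort()] for cohorts whose raw sample
#' arrays would not comfortably fit in memory together: each recording is
#' generated, transformed with [quantile_spectrogram()] and discarded before
#' the next is drawn. Seed derivation matches [simulate_cohort()], so the
#' i-th spectrogram here equals the spectrogram of the i-th recording there.
#'
#' @inheritParams simulate_cohort
#' @inheritParams quantile_spectrogram
#' @return A list with elements `spectrograms` (list of
#'   `quantile_spectrogram`), `labels`, `concentrations_uM`, `sample_ids`.
#' @export
cohort_spectrograms <- function(n_pos, n_neg, cfg_template, seed,
                                window_min = 5, levels = seq(0.1, 0.9, 0.1),
                                welch = welch_params(),
                                phases = c("medium", "drug"),
                                concentrations_uM = NULL) {
  n <- n_pos + n_neg
  labels <- c(rep("positive", n_pos), rep("negative", n_neg))
  if (is.null(concentrations_uM)) concentrations_uM <- rep(0, n)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  specs <- vector("list", n)
  ids <- character(n)
  for (i in seq_len(n)) {
    cfg_i <- cfg_template
    cfg_i$label <- labels[i]
    cfg_i$seed <- seeds[i]
    rec <- simulate_recording(cfg_i)
    ids[i] <- rec$meta$experiment_id
    specs[[i]] <- quantile_spectrogram(rec, window_min = window_min,
                                       levels = levels, welch = welch,
                                       phases = phases)
    rm(rec)
  }
  list(spectrograms = specs, labels = labels,
       concentrations_uM = concentrations_uM, sample_ids = ids)
}

#' Simulate a resazurin dose-response table
#'
#' Draws relative viabilities from a four-parameter logistic curve plus
#' Gaussian noise. Zero concentration returns the top asymptote (plus
#' noise).
#'
#' @param ic50_uM Half-maximal concentration, `> 0`.
#' @param hill Hill slope (positive for a decreasing viability curve in this
#'   parameterization).
#' @param top,bottom Upper / lower viability asymptotes in percent.
#' @param concentrations_uM Non-negative concentrations, one well each.
#' @param noise_sd Gaussian noise sd in viability percent.
#' @param seed Integer seed.
#' @return A `data.frame` with columns `concentration_uM`, `viability_pct`.
#' @export
simulate_dose_response <- function(ic50_uM, hill = 1, top = 100, bottom = 0,
                                   concentrations_uM, noise_sd = 0, seed = 1L) {
  stopifnot(ic50_uM > 0, all(concentrations_uM >= 0))
  set.seed(seed)
  v <- fourpl(concentrations_uM, bottom, top, ic50_uM, hill)
  if (noise_sd > 0) v <- v + stats::rnorm(length(v), sd = noise_sd)
  data.frame(concentration_uM = concentrations_uM, viability_pct = v)
}
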