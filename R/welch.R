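#' Welch segmentation parameters
#'
#' Parameters of the segment-periodogram stage shared by the standard Welch
#' power-spectral-density estimate and the quantile spectrum. Defaults (1 s
#' segments, 50% overlap, Hann taper, per-segment constant detrend) give
#' 1 Hz frequency resolution and several hundred segments per 5-minute
#' analysis window — enough for stable per-frequency quantiles.
#'
#' @param segment_s Segment length in seconds.
#' @param overlap_frac Fractional overlap between consecutive segments,
#'   in `[0, 1)`.
#' @param taper `"hann"` (periodic) or `"boxcar"`.
#' @param detrend `"constant"` (remove each segment's mean) or `"none"`.
#' @return A list of class `welch_params`.
#' @export
welch_params <- function(segment_s = 1.0, overlap_frac = 0.5,
                         taper = c("hann", "boxcar"),
                         detrend = c("constant", "none")) {
  taper <- match.arg(taper)
  detrend <- match.arg(detrend)
  stopifnot(segment_s > 0, overlap_frac >= 0, overlap_frac < 1)
  structure(list(segment_s = segment_s, overlap_frac = overlap_frac,
                 taper = taper, detrend = detrend, one_sided = TRUE),
            class = "welch_params")
}

# periodic Hann window (matches the common FFT-analysis convention)
taper_window <- function(taper, nperseg) {
  if (taper == "hann") {
    0.5 * (1 - cos(2 * pi * (0:(nperseg - 1)) / nperseg))
  } else {
    rep(1, nperseg)
  }
}

#' One-sided PSD periodograms of all Welch segments
#'
#' The raw material of both the Welch mean spectrum and the quantile
#' spectrum: the signal is cut into (possibly overlapping) segments, each
#' segment is detrended, tapered and Fourier transformed, and each squared
#' spectrum is normalized as a one-sided power spectral density
#' (units^2/Hz). Averaging the rows of the returned matrix reproduces the
#' textbook Welch estimate exactly.
#'
#' @param signal Numeric sample vector.
#' @param sampling_rate Sampling rate in Hz.
#' @param welch A [welch_params()] object.
#' @return A matrix `[n_segments x n_freq]` with attribute `freqs_hz`
#'   (frequencies `0, 1/segment_s, ..., Nyquist`).
#' @export
segment_periodograms <- function(signal, sampling_rate,
                                 welch = welch_params()) {
  nperseg <- round(welch$segment_s * sampling_rate)
  if (nperseg < 8L) stop("segment_periodograms: segment shorter than 8 samples")
  n <- length(signal)
  if (n < nperseg) stop("segment_periodograms: signal shorter than one segment")
  noverlap <- floor(nperseg * welch$overlap_frac)
  step <- nperseg - noverlap
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- taper_window(welch$taper, nperseg)

  seg <- matrix(signal[outer(0:(nperseg - 1L), starts, `+`)], nrow = nperseg)
  if (welch$detrend == "constant") {
    seg <- seg - rep(colMeans(seg), each = nperseg)
  }
  seg <- seg * w
  spec <- stats::mvfft(seg)
  n_freq <- nperseg %/% 2L + 1L
  psd <- (Mod(spec[seq_len(n_freq), , drop = FALSE])^2) /
    (sampling_rate * sum(w^2))
  # one-sided: double interior bins (DC, and Nyquist when nperseg is even,
  # have no mirror image)
  interior <- seq(2L, n_freq - if (nperseg %% 2L == 0L) 1L else 0L)
  psd[interior, ] <- 2 * psd[interior, ]
  out <- t(psd)
  attr(out, "freqs_hz") <- sampling_rate * (0:(n_freq - 1L)) / nperseg
  out
}

#' Standard Welch power spectral density
#'
#' Mean over segment periodograms — the classical estimate the quantile
#' spectrum generalizes (and the consistency anchor its tests are pinned
#' to).
#'
#' @inheritParams segment_periodograms
#' @return A `data.frame` with columns `freq_hz`, `psd`.
#' @export
welch_psd <- function(signal, sampling_rate, welch = welch_params()) {
  pg <- segment_periodograms(signal, sampling_rate, welch)
  data.frame(freq_hz = attr(pg, "freqs_hz"), psd = colMeans(pg))
}
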