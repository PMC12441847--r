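#' Per-frequency quantiles of segment periodograms
#'
#' The quantile spectrum: instead of averaging segment periodograms as
#' Welch's method does, estimate, at every frequency bin, empirical
#' quantiles of the distribution of periodogram power across segments. The
#' linear-interpolation (type 7) order-statistic estimator is used, so the
#' result is deterministic and non-decreasing in the quantile level by
#' construction.
#'
#' @param periodograms Matrix `[n_segments x n_freq]` from
#'   [segment_periodograms()].
#' @param levels Quantile fractions in (0, 1), default deciles 0.1–0.9.
#' @return Matrix `[n_levels x n_freq]`; `freqs_hz` attribute is propagated
#'   when present.
#' @export
quantile_spectrum <- function(periodograms, levels = seq(0.1, 0.9, 0.1)) {
  stopifnot(is.matrix(periodograms), all(levels > 0), all(levels < 1))
  m <- nrow(periodograms)
  if (m < 1L) stop("quantile_spectrum: no segments")
  if (m == 1L) {
    if (length(levels) > 1L) {
      warning("quantile_spectrum: single segment; all quantile levels ",
              "return the same spectrum")
    }
    out <- matrix(periodograms[1L, ], nrow = length(levels),
                  ncol = ncol(periodograms), byrow = TRUE)
  } else {
    sorted <- matrix(periodograms[order(col(periodograms), periodograms,
                                        method = "radix")],
                     nrow = m)
    h <- (m - 1) * levels + 1
    lo <- floor(h)
    frac <- h - lo
    hi <- pmin(lo + 1, m)
    out <- sorted[lo, , drop = FALSE] * (1 - frac) +
      sorted[hi, , drop = FALSE] * frac
  }
  rownames(out) <- format(levels)
  attr(out, "freqs_hz") <- attr(periodograms, "freqs_hz")
  attr(out, "levels") <- levels
  out
}

#' Quantile spectrogram of a recording
#'
#' The core transform of the nanomotion analysis: the included phases are
#' tiled with contiguous, non-overlapping analysis windows (default 5 min;
#' 15 min for the longer-exposure protocol) on the recording clock, and each
#' window is summarized independently by its quantile spectrum. The result
#' is a 3-D array spanning quantile level x frequency x time window. A
#' trailing partial window is dropped.
#'
#' @param rec A `deflection_recording`.
#' @param window_min Analysis window length in minutes.
#' @param levels Quantile fractions, default deciles 0.1–0.9.
#' @param welch A [welch_params()] object.
#' @param phases Character vector of phases to include (default medium +
#'   drug; pass `"drug"` to exclude the medium phase from all windows).
#' @return An object of class `quantile_spectrogram`: list with `values`
#'   (array `[n_levels x n_freq x n_windows]`, units^2/Hz), `levels`,
#'   `freqs_hz`, `window_starts_min` (recording-clock minutes),
#'   `window_min`, `welch`.
#' @export
quantile_spectrogram <- function(rec, window_min = 5,
                                 levels = seq(0.1, 0.9, 0.1),
                                 welch = welch_params(),
                                 phases = c("medium", "drug")) {
  stopifnot(inherits(rec, "deflection_recording"), window_min > 0)
  if (is.null(rec$phases)) stop("quantile_spectrogram: recording has no phases")
  sel <- rec$phases[rec$phases$name %in% phases, , drop = FALSE]
  if (nrow(sel) == 0L) {
    stop("quantile_spectrogram: none of the requested phases (",
         paste(phases, collapse = ", "), ") are annotated")
  }
  sel <- sel[order(sel$start_s), , drop = FALSE]
  # merge contiguous selected spans so windows tile across phase boundaries
  spans <- list(c(sel$start_s[1L], sel$end_s[1L]))
  if (nrow(sel) > 1L) {
    for (i in 2:nrow(sel)) {
      last <- spans[[length(spans)]]
      if (abs(sel$start_s[i] - last[2L]) < 1e-6) {
        spans[[length(spans)]][2L] <- sel$end_s[i]
      } else {
        spans[[length(spans) + 1L]] <- c(sel$start_s[i], sel$end_s[i])
      }
    }
  }
  fs <- rec$sampling_rate
  wlen <- round(window_min * 60 * fs)
  starts_min <- numeric(0)
  windows <- list()
  for (sp in spans) {
    t0_min <- clock_min(rec, sp[1L])
    t1_min <- clock_min(rec, sp[2L])
    ws <- seq(t0_min, by = window_min, length.out = max(
      0L, floor((t1_min - t0_min) / window_min)))
    for (w0 in ws) {
      i0 <- round((w0 * 60 + rec$clock_zero_s - rec$t0_s) * fs) + 1L
      windows[[length(windows) + 1L]] <- c(i0, i0 + wlen - 1L)
      starts_min <- c(starts_min, w0)
    }
  }
  if (!length(windows)) {
    stop("quantile_spectrogram: included phases contain no full ",
         window_min, "-min window")
  }
  vals <- NULL
  freqs <- NULL
  for (j in seq_along(windows)) {
    idx <- windows[[j]]
    pg <- segment_periodograms(rec$samples[idx[1L]:idx[2L]], fs, welch)
    qs <- quantile_spectrum(pg, levels)
    if (is.null(vals)) {
      freqs <- attr(pg, "freqs_hz")
      vals <- array(NA_real_,
                    dim = c(length(levels), length(freqs), length(windows)))
    }
    vals[, , j] <- qs
  }
  structure(
    list(values = vals, levels = levels, freqs_hz = freqs,
         window_starts_min = starts_min, window_min = window_min,
         welch = welch),
    class = "quantile_spectrogram"
  )
}

#' @export
print.quantile_spectrogram <- function(x, ...) {
  cat(sprintf(
    "<quantile_spectrogram> %d levels x %d freqs (0-%g Hz) x %d windows of %g min\n",
    dim(x$values)[1L], dim(x$values)[2L], max(x$freqs_hz),
    dim(x$values)[3L], x$window_min))
  cat(sprintf("  window starts (clock min): %s\n",
              paste(utils::head(x$window_starts_min, 6), collapse = ", ")))
  invisible(x)
}
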