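#' Phase span within a deflection recording
#'
#' A named, half-open-in-spirit time span `[start_s, end_s)` locating one of
#' the three acquisition phases (blank sensor, cells in medium, cells under
#' drug) inside a recording. Times are seconds from the start of the file.
#'
#' @param name One of `"blank"`, `"medium"`, `"drug"`.
#' @param start_s,end_s Span boundaries in seconds from file start,
#'   `start_s < end_s`.
#' @return A one-row `data.frame` with columns `name`, `start_s`, `end_s`.
#' @export
phase_span <- function(name, start_s, end_s) {
  name <- match.arg(name, c("blank", "medium", "drug"))
  stopifnot(is.numeric(start_s), is.numeric(end_s), length(start_s) == 1L,
            length(end_s) == 1L, is.finite(start_s), is.finite(end_s))
  if (start_s >= end_s) {
    stop("phase_span: start_s must be < end_s (got [", start_s, ", ", end_s, "))")
  }
  data.frame(name = name, start_s = as.numeric(start_s),
             end_s = as.numeric(end_s), stringsAsFactors = FALSE)
}

phase_order <- c(blank = 1L, medium = 2L, drug = 3L)

validate_phases <- function(phases, duration_s) {
  if (is.null(phases) || nrow(phases) == 0L) return(invisible(phases))
  stopifnot(all(c("name", "start_s", "end_s") %in% names(phases)))
  if (anyDuplicated(phases$name)) {
    stop("phases: at most one span per phase name")
  }
  if (!all(phases$name %in% names(phase_order))) {
    stop("phases: unknown phase name(s): ",
         paste(setdiff(phases$name, names(phase_order)), collapse = ", "))
  }
  phases <- phases[order(phase_order[phases$name]), , drop = FALSE]
  if (any(phases$start_s >= phases$end_s)) {
    stop("phases: every span needs start_s < end_s")
  }
  if (nrow(phases) > 1L) {
    # ordered blank -> medium -> drug, non-overlapping
    if (any(phases$end_s[-nrow(phases)] > phases$start_s[-1L] + 1e-9)) {
      stop("phases: spans overlap or are out of blank/medium/drug order")
    }
  }
  if (any(phases$start_s < -1e-9) || any(phases$end_s > duration_s + 1e-9)) {
    stop("phases: spans must lie within [0, ", duration_s, "] s")
  }
  invisible(phases)
}

#' Construct a phase-annotated deflection recording
#'
#' The raw measurement unit of a nanomotion experiment: a single-channel
#' cantilever-deflection time series (arbitrary deflection units), its
#' sampling rate, its phase annotations and per-experiment metadata.
#'
#' All downstream window times use the *recording clock*, which places t = 0
#' at the start of the medium phase; a blank phase therefore sits at negative
#' clock times and never contributes to feature intervals.
#'
#' @param samples Numeric vector of deflection samples; all values must be
#'   finite.
#' @param sampling_rate Sampling rate in Hz, `> 0`.
#' @param phases A `data.frame` of phase spans (rbind of [phase_span()]
#'   rows); spans must be ordered blank/medium/drug, non-overlapping and lie
#'   within the recording.
#' @param meta Named list of metadata; recognized entries are
#'   `experiment_id`, `cell_line`, `drug`, `concentration_uM` (non-negative)
#'   and `label` (`"positive"`, `"negative"` or `"unknown"`).
#' @param t0_s File time (seconds) of the first sample; non-zero only for
#'   sub-recordings produced by [phase_segment()].
#' @return An object of class `deflection_recording`.
#' @seealso [phase_segment()], [variance_trace()], [write_recording()]
#' @export
deflection_recording <- function(samples, sampling_rate, phases = NULL,
                                 meta = list(), t0_s = 0) {
  stopifnot(is.numeric(samples), length(samples) >= 1L)
  if (!all(is.finite(samples))) stop("samples must all be finite")
  stopifnot(is.numeric(sampling_rate), length(sampling_rate) == 1L,
            is.finite(sampling_rate))
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  duration_s <- length(samples) / sampling_rate
  if (!is.null(phases)) {
    phases <- phases[order(phase_order[phases$name]), , drop = FALSE]
    rownames(phases) <- NULL
    # spans are expressed in file time; validate against [t0, t0 + duration]
    shifted <- phases
    shifted$start_s <- shifted$start_s - t0_s
    shifted$end_s <- shifted$end_s - t0_s
    validate_phases(shifted, duration_s)
  }
  if (!is.null(meta$concentration_uM)) {
    stopifnot(is.numeric(meta$concentration_uM), meta$concentration_uM >= 0)
  }
  if (!is.null(meta$label)) {
    meta$label <- match.arg(meta$label, c("positive", "negative", "unknown"))
  }
  clock_zero_s <- if (!is.null(phases) && "medium" %in% phases$name) {
    phases$start_s[phases$name == "medium"]
  } else {
    0
  }
  structure(
    list(samples = as.numeric(samples),
         sampling_rate = as.numeric(sampling_rate),
         phases = phases, meta = meta,
         t0_s = as.numeric(t0_s),
         clock_zero_s = as.numeric(clock_zero_s)),
    class = "deflection_recording"
  )
}

#' @export
print.deflection_recording <- function(x, ...) {
  dur <- length(x$samples) / x$sampling_rate
  cat(sprintf("<deflection_recording> %d samples @ %g Hz (%.1f min)\n",
              length(x$samples), x$sampling_rate, dur / 60))
  if (!is.null(x$phases)) {
    for (i in seq_len(nrow(x$phases))) {
      cat(sprintf("  %-6s %8.1f - %8.1f s\n", x$phases$name[i],
                  x$phases$start_s[i], x$phases$end_s[i]))
    }
  }
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

rec_duration_s <- function(rec) length(rec$samples) / rec$sampling_rate

#' Convert file time to recording-clock minutes
#'
#' The recording clock places t = 0 at the start of the medium phase.
#'
#' @param rec A `deflection_recording`.
#' @param t_s File time in seconds.
#' @return Clock time in minutes.
#' @export
clock_min <- function(rec, t_s) (t_s - rec$clock_zero_s) / 60

#' Extract the sub-recording of one phase
#'
#' Returns a `deflection_recording` holding exactly the samples annotated
#' with the requested phase. The recording clock is preserved: the
#' sub-recording remembers its file-time origin and the medium-phase start,
#' so window times computed downstream agree with those computed on the full
#' recording.
#'
#' @param rec A `deflection_recording`.
#' @param phase `"blank"`, `"medium"` or `"drug"`.
#' @return A `deflection_recording` restricted to the phase.
#' @export
phase_segment <- function(rec, phase) {
  phase <- match.arg(phase, c("blank", "medium", "drug"))
  if (is.null(rec$phases) || !phase %in% rec$phases$name) {
    stop("phase_segment: phase '", phase, "' is not annotated in this recording")
  }
  row <- rec$phases[rec$phases$name == phase, ]
  i0 <- round((row$start_s - rec$t0_s) * rec$sampling_rate) + 1L
  i1 <- round((row$end_s - rec$t0_s) * rec$sampling_rate)
  i1 <- min(i1, length(rec$samples))
  out <- deflection_recording(rec$samples[i0:i1], rec$sampling_rate,
                              phases = row, meta = rec$meta,
                              t0_s = row$start_s)
  out$clock_zero_s <- rec$clock_zero_s
  out
}

#' Per-window variance trace
#'
#' Sample variance of the deflection signal in contiguous, non-overlapping
#' windows — the quick-look activity readout plotted alongside raw
#' recordings. The population (n-denominator) variance is used; at hundreds
#' of thousands of samples per window the distinction from the n-1 form is
#' negligible, but the choice is fixed for determinism.
#'
#' @param rec A `deflection_recording`.
#' @param window_s Window length in seconds (default 8). A trailing partial
#'   window is dropped.
#' @return A `data.frame` of class `variance_trace` with columns `time_s`
#'   (window start, file time) and `variance` (deflection units squared).
#' @export
variance_trace <- function(rec, window_s = 8) {
  stopifnot(window_s > 0)
  n_win <- floor(rec_duration_s(rec) / window_s)
  if (n_win < 1L) {
    stop("variance_trace: recording shorter than one window")
  }
  wlen <- round(window_s * rec$sampling_rate)
  idx <- seq_len(n_win * wlen)
  m <- matrix(rec$samples[idx], nrow = wlen)
  mu <- colMeans(m)
  v <- colMeans(m * m) - mu * mu
  v[v < 0] <- 0  # guard against tiny negative rounding
  structure(
    data.frame(time_s = rec$t0_s + (seq_len(n_win) - 1L) * window_s,
               variance = v),
    class = c("variance_trace", "data.frame")
  )
}
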