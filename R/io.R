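#' Write a deflection recording to disk
#'
#' Recordings are stored as IEEE-float mono WAV (RIFF format code 3) with a
#' JSON sidecar `<path>.json` carrying the sampling rate, phase annotations
#' and metadata. Two dialects are supported:
#' \describe{
#'   \item{`"wav"`}{32-bit float samples — compact, round-trips to float32
#'     precision.}
#'   \item{`"wav64"`}{64-bit float samples — lossless for R doubles.}
#' }
#'
#' @param rec A `deflection_recording`.
#' @param path Output path (conventionally `.wav`).
#' @param format `"wav"` or `"wav64"`.
#' @return `path`, invisibly.
#' @seealso [read_recording()]
#' @export
write_recording <- function(rec, path, format = c("wav64", "wav")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "deflection_recording"))
  bytes <- if (format == "wav") 4L else 8L
  n <- length(rec$samples)
  data_size <- n * bytes
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("write_recording: cannot open '",
                                           path, "' for writing"))
  on.exit(close(con))
  fs <- as.integer(round(rec$sampling_rate))
  # RIFF/WAVE, fmt chunk (format 3 = IEEE float, mono), data chunk
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")            # IEEE float
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(as.integer(fs * bytes), con, size = 4, endian = "little")
  writeBin(bytes, con, size = 2, endian = "little")         # block align
  writeBin(8L * bytes, con, size = 2, endian = "little")    # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  writeBin(rec$samples, con, size = bytes, endian = "little")
  sidecar <- list(
    sampling_rate_hz = rec$sampling_rate,
    t0_s = rec$t0_s,
    phases = rec$phases,
    meta = rec$meta
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a deflection recording from disk
#'
#' Reads the WAV dialect written by [write_recording()] and re-validates all
#' recording invariants; a malformed file or inconsistent annotation raises
#' rather than passing silently.
#'
#' @param path Path to a `.wav` file with a `<path>.json` sidecar.
#' @return A validated `deflection_recording`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("read_recording: no such file: ", path)
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) {
    stop("read_recording: missing sidecar ", sidecar_path)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readChar(con, 4), "RIFF")) stop("read_recording: not a RIFF file")
  readBin(con, "integer", size = 4, endian = "little")
  if (!identical(readChar(con, 4), "WAVE")) stop("read_recording: not a WAVE file")
  fmt_code <- NA_integer_; fs_header <- NA_integer_; bits <- NA_integer_
  samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      fmt_code <- readBin(con, "integer", size = 2, endian = "little")
      readBin(con, "integer", size = 2, endian = "little")
      fs_header <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 2, endian = "little")
      bits <- readBin(con, "integer", size = 2, endian = "little")
      if (size > 16L) readBin(con, "raw", n = size - 16L)
    } else if (id == "data") {
      if (is.na(fmt_code)) stop("read_recording: data chunk before fmt chunk")
      if (fmt_code != 3L) stop("read_recording: only IEEE-float WAV supported")
      if (!bits %in% c(32L, 64L)) stop("read_recording: unsupported bit depth ", bits)
      samples <- readBin(con, "double", n = size %/% (bits %/% 8L),
                         size = bits %/% 8L, endian = "little")
    } else {
      readBin(con, "raw", n = size)
    }
    if (!is.null(samples) && !is.na(fmt_code)) break
  }
  if (is.null(samples)) stop("read_recording: no data chunk found")
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(side$sampling_rate_hz)) {
    stop("read_recording: sidecar lacks sampling_rate_hz")
  }
  phases <- side$phases
  if (!is.null(phases) && length(phases) && !is.data.frame(phases)) {
    phases <- as.data.frame(phases, stringsAsFactors = FALSE)
  }
  if (is.data.frame(phases) && nrow(phases) == 0L) phases <- NULL
  meta <- side$meta
  if (is.null(meta)) meta <- list()
  deflection_recording(samples, side$sampling_rate_hz, phases = phases,
                       meta = meta,
                       t0_s = if (is.null(side$t0_s)) 0 else side$t0_s)
}
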