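#' Read a mono PCM WAV file
#'
#' Minimal RIFF/WAVE reader for the trial recordings the analysis consumes:
#' mono, integer PCM, 16- or 24-bit. Samples are mapped to `[-1, 1]` by
#' dividing by the full-scale integer; no loudness normalisation is applied
#' (power differences across trials are signal). Multi-channel files are
#' rejected rather than downmixed.
#'
#' @param path Path to a `.wav` file.
#' @return List with `samples` (numeric in `[-1, 1]`), `sample_rate` (Hz)
#'   and `bits` (bit depth of the source).
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stopf("WAV file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stopf("%s: not a RIFF file", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stopf("%s: not a WAVE file", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, endian = "little",
                               signed = FALSE),
        channels     = readBin(con, "integer", 1, 2, endian = "little",
                               signed = FALSE),
        sample_rate  = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate    = readBin(con, "integer", 1, 4, endian = "little"),
        block_align  = readBin(con, "integer", 1, 2, endian = "little",
                               signed = FALSE),
        bits         = readBin(con, "integer", 1, 2, endian = "little",
                               signed = FALSE))
      if (sz > 16) invisible(readBin(con, "raw", sz - 16))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stopf("%s: missing fmt/data chunk", path)
  if (fmt$audio_format != 1L) stopf("%s: only integer PCM supported", path)
  if (fmt$channels != 1L)
    stopf("%s: expected mono, got %d channels (downmixing is not performed)",
          path, fmt$channels)
  if (fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", length(data_raw) / 2L, 2,
                 signed = TRUE, endian = "little")
    samples <- x / 32768
  } else if (fmt$bits == 24L) {
    n <- length(data_raw) %/% 3L
    b <- matrix(as.integer(data_raw[seq_len(n * 3L)]), nrow = 3L)
    x <- b[1, ] + 256L * b[2, ] + 65536L * b[3, ]
    x <- ifelse(x >= 8388608, x - 16777216, x)
    samples <- x / 8388608
  } else stopf("%s: unsupported bit depth %d (16/24 only)", path, fmt$bits)
  list(samples = samples, sample_rate = fmt$sample_rate, bits = fmt$bits)
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param samples Numeric vector in `[-1, 1]`; values outside are clipped.
#' @param path Output path.
#' @param sample_rate Sampling rate in Hz.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate = 44100) {
  stopifnot(is.numeric(samples), length(samples) > 0, sample_rate > 0)
  if (any(!is.finite(samples))) stopf("non-finite samples")
  x <- as.integer(round(pmin(1, pmax(-1, samples)) * 32767))
  n_bytes <- length(x) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(x, con, size = 2, endian = "little")
  invisible(path)
}
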