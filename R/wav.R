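# Minimal RIFF/WAVE I/O for mono PCM recordings.
#
# Ultrasonic recording rigs in this workflow produce single-channel WAV files
# at 250 kHz / 16-bit. Only what those files need is implemented: mono,
# 16-bit integer PCM (format 1) or 32-bit IEEE float (format 3).

#' Read a mono WAV file
#'
#' Reads a single-channel PCM WAV file and scales samples to `[-1, 1)`.
#' 16-bit integer samples are divided by 32768; 32-bit float samples are
#' passed through unchanged.
#'
#' @param path Path to a WAV file (mono, 16-bit integer PCM or 32-bit float).
#' @param expected_rate Sampling rate (Hz) the recording protocol calls for;
#'   a warning is emitted when the file's rate differs. Default 250000.
#' @return An object of class `usv_waveform`: a list with `samples`
#'   (numeric vector in `[-1, 1)`), `fs` (sampling rate, Hz) and `bits`.
#' @seealso [write_waveform()], [compute_spectrogram()]
#' @export
read_waveform <- function(path, expected_rate = 250000) {
  if (!file.exists(path)) stop("cannot read WAV file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))

  read_tag <- function() rawToChar(readBin(con, "raw", 4L))
  read_u32 <- function() readBin(con, "integer", 1L, size = 4L, endian = "little")
  read_u16 <- function() readBin(con, "integer", 1L, size = 2L, signed = FALSE,
                                 endian = "little")

  riff <- read_tag()
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  read_u32() # overall chunk size, unused
  wave <- read_tag()
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path, call. = FALSE)

  fmt <- NULL
  samples <- NULL
  repeat {
    tag_raw <- readBin(con, "raw", 4L)
    if (length(tag_raw) < 4L) break
    tag <- rawToChar(tag_raw)
    size <- read_u32()
    if (length(size) < 1L) stop("truncated WAV header: ", path, call. = FALSE)
    if (identical(tag, "fmt ")) {
      fmt <- list(
        format   = read_u16(),
        channels = read_u16(),
        rate     = read_u32()
      )
      read_u32() # byte rate
      read_u16() # block align
      fmt$bits <- read_u16()
      if (size > 16L) readBin(con, "raw", size - 16L)
    } else if (identical(tag, "data")) {
      if (is.null(fmt)) stop("WAV data chunk precedes fmt chunk: ", path, call. = FALSE)
      if (fmt$channels != 1L) {
        stop("only mono WAV files are supported (got ", fmt$channels,
             " channels)", call. = FALSE)
      }
      if (fmt$format == 1L && fmt$bits == 16L) {
        n <- size %/% 2L
        raw <- readBin(con, "integer", n, size = 2L, signed = TRUE,
                       endian = "little")
        if (length(raw) < n) stop("truncated WAV data: ", path, call. = FALSE)
        samples <- raw / 32768
      } else if (fmt$format == 3L && fmt$bits == 32L) {
        n <- size %/% 4L
        samples <- readBin(con, "double", n, size = 4L, endian = "little")
        if (length(samples) < n) stop("truncated WAV data: ", path, call. = FALSE)
      } else {
        stop("unsupported WAV encoding (format ", fmt$format, ", ",
             fmt$bits, " bits)", call. = FALSE)
      }
    } else {
      skipped <- readBin(con, "raw", size + (size %% 2L))
      if (length(skipped) < size) stop("truncated WAV chunk: ", path, call. = FALSE)
    }
  }

  if (is.null(fmt) || is.null(samples)) {
    stop("truncated or malformed WAV file: ", path, call. = FALSE)
  }
  if (length(samples) == 0L) stop("WAV file contains no samples: ", path, call. = FALSE)
  if (!is.null(expected_rate) && fmt$rate != expected_rate) {
    warning(sprintf("sampling rate is %d Hz, expected %d Hz", fmt$rate,
                    as.integer(expected_rate)), call. = FALSE)
  }
  structure(list(samples = samples, fs = fmt$rate, bits = fmt$bits),
            class = "usv_waveform")
}

#' Write a mono 16-bit PCM WAV file
#'
#' Samples are clipped to `[-1, 1 - 1/32768]` and quantized to 16 bits.
#'
#' @param samples Numeric vector of samples in `[-1, 1)`, or a `usv_waveform`.
#' @param fs Sampling rate in Hz (ignored when `samples` is a `usv_waveform`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(samples, fs, path) {
  if (inherits(samples, "usv_waveform")) {
    fs <- samples$fs
    samples <- samples$samples
  }
  if (length(samples) == 0L) stop("no samples to write", call. = FALSE)
  q <- as.integer(pmax(-32768, pmin(32767, round(samples * 32768))))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- length(q) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_size, con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")             # PCM
  writeBin(1L, con, size = 2L, endian = "little")             # mono
  writeBin(as.integer(fs), con, size = 4L, endian = "little")
  writeBin(as.integer(fs) * 2L, con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")             # block align
  writeBin(16L, con, size = 2L, endian = "little")            # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4L, endian = "little")
  writeBin(q, con, size = 2L, endian = "little")
  invisible(path)
}
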