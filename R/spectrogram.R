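# Short-time Fourier transform with fixed conventions:
#   - one-sided magnitude in dB relative to full scale (a full-scale sine
#     lands at ~0 dB in its bin),
#   - frame times at window centers, seconds from file start,
#   - frequency bins in kHz spanning 0 to Nyquist.

stft_window <- function(name, n) {
  switch(name,
    hann = 0.5 - 0.5 * cos(2 * pi * seq_len(n) / n),
    rect = ,
    rectangular = rep(1, n),
    stop("unknown window function: ", name, call. = FALSE)
  )
}

#' Compute a dB spectrogram
#'
#' Computes a one-sided short-time Fourier magnitude spectrogram. Magnitudes
#' are normalized by half the window sum, so a full-scale sine wave
#' (amplitude 1) peaks near 0 dB; an event rendered at -20 dB relative to
#' full scale peaks near -20 dB.
#'
#' @param waveform A `usv_waveform` (from [read_waveform()] or
#'   [render_audio_pair()]), or a plain numeric vector of samples (then `fs`
#'   is required).
#' @param fs Sampling rate in Hz; ignored when `waveform` is a `usv_waveform`.
#' @param window_length Window length in samples (default 512, i.e. 2.048 ms
#'   at 250 kHz; about 0.49 kHz bin spacing).
#' @param hop Hop between frame starts in samples (default 256, 50% overlap).
#' @param window Window function: `"hann"` (default) or `"rect"`.
#' @param db_floor Magnitude floor in dB; all-zero frames sit at this value.
#' @return An object of class `usv_spectrogram`: list with `times` (s, frame
#'   centers), `freqs` (kHz, bin centers), `magnitude` (dB matrix,
#'   frequency x time), `fs`, and `stft_params`.
#' @examples
#' fs <- 250000
#' tone <- 0.5 * sin(2 * pi * 70000 * seq(0, 0.02, by = 1 / fs))
#' sp <- compute_spectrogram(tone, fs = fs)
#' sp$freqs[which.max(sp$magnitude[, 5])] # ~70 kHz
#' @export
compute_spectrogram <- function(waveform, fs = NULL, window_length = 512,
                                hop = 256, window = "hann", db_floor = -200) {
  if (inherits(waveform, "usv_waveform")) {
    fs <- waveform$fs
    x <- waveform$samples
  } else {
    x <- as.numeric(waveform)
    if (is.null(fs)) stop("fs is required for plain sample vectors", call. = FALSE)
  }
  window_length <- as.integer(window_length)
  hop <- as.integer(hop)
  if (hop <= 0L || window_length < hop) {
    stop("window length must be >= hop > 0", call. = FALSE)
  }
  if (length(x) < window_length) {
    stop("signal shorter than the analysis window", call. = FALSE)
  }

  w <- stft_window(window, window_length)
  norm <- sum(w) / 2
  starts <- seq.int(1L, length(x) - window_length + 1L, by = hop)
  n_bins <- window_length %/% 2L + 1L
  floor_mag <- 10^(db_floor / 20)

  magnitude <- matrix(0, nrow = n_bins, ncol = length(starts))
  # chunked so a multi-minute 250 kHz file does not materialize one huge matrix
  chunk <- 4096L
  for (i0 in seq.int(1L, length(starts), by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, length(starts))
    frames <- matrix(0, nrow = window_length, ncol = length(idx))
    for (j in seq_along(idx)) {
      s <- starts[idx[j]]
      frames[, j] <- x[s:(s + window_length - 1L)]
    }
    spec <- mvfft(frames * w)[seq_len(n_bins), , drop = FALSE]
    magnitude[, idx] <- 20 * log10(pmax(abs(spec) / norm, floor_mag))
  }

  structure(list(
    times = (starts - 1 + window_length / 2) / fs,
    freqs = (seq_len(n_bins) - 1) * fs / window_length / 1000,
    magnitude = magnitude,
    fs = fs,
    stft_params = list(window_length = window_length, hop = hop,
                       window = window, db_floor = db_floor)
  ), class = "usv_spectrogram")
}
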