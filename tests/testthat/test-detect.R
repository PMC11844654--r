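# Waveform I/O, spectrogram conventions, and call detection.

test_that("16-bit WAV samples round-trip scaled to [-1, 1)", {
  path <- withr::local_tempfile(fileext = ".wav")
  x <- c(32767, -32768, 0, 16384) / 32768
  write_waveform(x, 250000, path)
  wf <- read_waveform(path)
  expect_equal(wf$fs, 250000)
  expect_equal(wf$samples[1], 32767 / 32768, tolerance = 1e-12) # ~0.99997
  expect_equal(wf$samples[2], -1)
  expect_equal(wf$samples, x, tolerance = 1e-12)
})

test_that("duration and sampling-rate bookkeeping are exact", {
  path <- withr::local_tempfile(fileext = ".wav")
  write_waveform(rep(0.1, 250000), 250000, path)
  wf <- read_waveform(path)
  expect_equal(length(wf$samples) / wf$fs, 1.0)
  # off-protocol sampling rate warns
  path2 <- withr::local_tempfile(fileext = ".wav")
  write_waveform(rep(0.1, 1000), 192000, path2)
  expect_warning(read_waveform(path2), "sampling rate")
})

test_that("unreadable or truncated files raise I/O errors", {
  expect_error(read_waveform(file.path(tempdir(), "absent.wav")), "cannot read")
  bad <- withr::local_tempfile(fileext = ".wav")
  writeBin(charToRaw("RIFF"), bad)
  expect_error(read_waveform(bad), "truncated|malformed|RIFF")
  notwav <- withr::local_tempfile(fileext = ".wav")
  writeBin(as.raw(1:64), notwav)
  expect_error(read_waveform(notwav), "RIFF")
})

test_that("a pure tone concentrates in one frequency bin per frame", {
  fs <- 250000
  x <- sin(2 * pi * 70000 * seq_len(fs / 10) / fs)
  sp <- compute_spectrogram(x, fs = fs)
  bin_khz <- diff(sp$freqs[1:2])
  argmax <- apply(sp$magnitude, 2L, which.max)
  expect_true(all(abs(sp$freqs[argmax] - 70) <= bin_khz + 1e-9))
  # full-scale sine peaks near 0 dB under the full-scale normalization
  expect_lt(abs(max(sp$magnitude)), 1.5)
})

test_that("all-zero signals sit at the dB floor", {
  sp <- compute_spectrogram(numeric(5000), fs = 250000, db_floor = -200)
  expect_true(all(sp$magnitude == -200))
})

test_that("rectangular-window frames satisfy Parseval's identity", {
  set.seed(99)
  fs <- 250000
  x <- rnorm(4096, 0, 0.1)
  n <- 512
  sp <- compute_spectrogram(x, fs = fs, window_length = n, hop = n,
                            window = "rect", db_floor = -400)
  lin_power <- 10^(sp$magnitude / 10)
  weights <- c(1, rep(2, n / 2 - 1), 1) # one-sided doubling, DC/Nyquist once
  for (j in seq_along(sp$times)) {
    frame <- x[((j - 1) * n + 1):(j * n)]
    # |X_norm|^2 * (N/2)^2 summed with one-sided weights equals N * sum(x^2)
    total <- sum(weights * lin_power[, j]) * (n / 2)^2
    expect_equal(total, n * sum(frame^2), tolerance = 0.01)
  }
})

test_that("window longer than the signal is refused", {
  expect_error(compute_spectrogram(numeric(100), fs = 250000,
                                   window_length = 512), "shorter")
  expect_error(compute_spectrogram(numeric(5000), fs = 250000, hop = 0),
               "hop")
})

test_that("noise-only audio produces no detections at default threshold", {
  cfg <- dyad_config(seed = 41, session_s = 4, rate_wt = 0, rate_as = 0)
  aud <- render_audio_pair(generate_cohort(cfg)$events, cfg)
  sp <- compute_spectrogram(aud$left)
  expect_equal(nrow(detect_calls(sp)), 0L)
})

test_that("a single sweep is detected once with accurate boundaries", {
  cfg <- dyad_config(seed = 42, session_s = 2, rate_wt = 0, rate_as = 0)
  ct <- synthesize_contour("simple_positive", 60, 20, 50, amplitude_db = -20)
  ct$time <- ct$time + 0.9
  ev <- data.frame(event_id = "e1", mouse_id = "WT01", genotype = "WT",
                   dyad = 1L, mic = "left", channel = "near",
                   t_start = 0.9, t_end = 0.95, duration_ms = 50,
                   category = "USV", shape = "simple_positive",
                   true_inflections = 0L, true_slope_sign = "+",
                   f_low = 60, f_high = 80, amplitude_db = -20,
                   stringsAsFactors = FALSE)
  ev$contour <- list(ct)
  aud <- render_audio_pair(ev, cfg)
  sp <- compute_spectrogram(aud$left)
  det <- detect_calls(sp)
  expect_equal(nrow(det), 1L)
  # onset/offset within the STFT smear: half a window plus one hop
  smear <- (sp$stft_params$window_length / 2 + sp$stft_params$hop) / sp$fs
  expect_lt(abs(det$t_start - 0.9), smear)
  expect_lt(abs(det$t_end - 0.95), smear)
  # contour frequencies stay inside the detection band
  p <- detect_params()
  expect_true(all(det$contour[[1]]$freq >= p$band[1] &
                    det$contour[[1]]$freq <= p$band[2]))
})

test_that("max_gap bridges short dropouts but not real silences", {
  # constructed spectrogram: 1 ms frames, two 30 ms tones
  n_frames <- 400
  freqs <- seq(0, 125, by = 0.5)
  mag <- matrix(-80, nrow = length(freqs), ncol = n_frames)
  tone_row <- which.min(abs(freqs - 60))
  burst <- function(t0_ms, len_ms) seq(t0_ms + 1, t0_ms + len_ms)
  sep100 <- c(burst(50, 30), burst(180, 30))   # 100 ms apart
  sep5 <- c(burst(250, 30), burst(285, 30))    # 5 ms apart
  mag[tone_row, c(sep100, sep5)] <- -20
  sp <- structure(list(times = (seq_len(n_frames) - 0.5) / 1000,
                       freqs = freqs, magnitude = mag, fs = 250000,
                       stft_params = list(window_length = 500, hop = 250,
                                          window = "hann", db_floor = -200)),
                  class = "usv_spectrogram")
  det10 <- detect_calls(sp, detect_params(max_gap_ms = 10))
  # the 100 ms gap separates calls; the 5 ms gap is bridged
  expect_equal(nrow(det10), 3L)
  det0 <- detect_calls(sp, detect_params(max_gap_ms = 0))
  expect_equal(nrow(det0), 4L)
})

test_that("detection is invariant to global gain changes", {
  cfg <- dyad_config(seed = 43, session_s = 8, rate_wt = 6, rate_as = 0)
  ev <- generate_cohort(cfg)$events
  aud <- render_audio_pair(ev, cfg)
  sp1 <- compute_spectrogram(aud$left)
  sp2 <- compute_spectrogram(aud$left$samples * 0.25, fs = aud$left$fs)
  d1 <- detect_calls(sp1)
  d2 <- detect_calls(sp2)
  expect_equal(nrow(d1), nrow(d2))
  expect_equal(d1$t_start, d2$t_start)
})

test_that("a band outside the spectrogram is refused", {
  sp <- compute_spectrogram(rnorm(5000, 0, 0.01), fs = 20000)
  expect_error(detect_calls(sp, detect_params(band = c(5, 125))), "band")
})
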