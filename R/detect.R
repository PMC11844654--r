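# Band-limited call detection on a dB spectrogram.
#
# A call is a maximal run of frames whose in-band peak magnitude exceeds a
# noise-relative threshold; sub-threshold gaps up to max_gap are bridged and
# runs shorter than min_duration are discarded. Each call carries a contour:
# the per-frame in-band argmax frequency with its magnitude.

#' Detection parameters
#'
#' @param band Detection band `c(f_lo, f_hi)` in kHz. Default `c(5, 125)`
#'   covers audible squeaks through high USVs below Nyquist.
#' @param threshold_db Threshold in dB above the per-frequency-bin median
#'   magnitude (a robust noise reference when calls are sparse). Default 15.
#' @param min_duration_ms Minimum call duration in ms; shorter runs are
#'   dropped. Default 10.
#' @param max_gap_ms Sub-threshold gaps up to this length (ms) are bridged
#'   within a call. Default 5.
#' @param min_bandwidth_khz Calls whose contour spans less than this (kHz)
#'   are dropped; 0 disables the filter. Default 0.
#' @return A validated list of class `usv_detect_params`.
#' @export
detect_params <- function(band = c(5, 125), threshold_db = 15,
                          min_duration_ms = 10, max_gap_ms = 5,
                          min_bandwidth_khz = 0) {
  if (length(band) != 2L || !all(is.finite(band)) || band[1] >= band[2]) {
    fail_field("band", "must be c(f_lo, f_hi) with f_lo < f_hi")
  }
  if (!is.finite(min_duration_ms) || min_duration_ms <= 0) {
    fail_field("min_duration_ms", "must be > 0")
  }
  if (!is.finite(max_gap_ms) || max_gap_ms < 0) {
    fail_field("max_gap_ms", "must be >= 0")
  }
  if (!is.finite(min_bandwidth_khz) || min_bandwidth_khz < 0) {
    fail_field("min_bandwidth_khz", "must be >= 0")
  }
  structure(list(band = as.numeric(band), threshold_db = threshold_db,
                 min_duration_ms = min_duration_ms, max_gap_ms = max_gap_ms,
                 min_bandwidth_khz = min_bandwidth_khz),
            class = "usv_detect_params")
}

#' Detect calls in a spectrogram
#'
#' @param spect A `usv_spectrogram` from [compute_spectrogram()].
#' @param params A `usv_detect_params` object; see [detect_params()].
#' @param channel Channel label stored on the detected calls
#'   (e.g. `"left"`, `"right"`, `"single"`). Default `"single"`.
#' @return A data.frame of detected calls: `call_id`, `channel`, `t_start`,
#'   `t_end` (seconds, half-open interval), `duration_ms`, `peak_db`, and a
#'   `contour` list-column of data.frames with `time` (s), `freq` (kHz),
#'   `mag` (dB).
#' @details Detection is invariant to global gain changes because the
#'   threshold is relative to the per-bin median noise magnitude. Onset and
#'   offset are quantized to the STFT frame grid and smeared by up to half a
#'   window length.
#' @export
detect_calls <- function(spect, params = detect_params(), channel = "single") {
  stopifnot(inherits(spect, "usv_spectrogram"))
  if (!inherits(params, "usv_detect_params")) {
    params <- do.call(detect_params, params)
  }
  freqs <- spect$freqs
  if (params$band[1] < min(freqs) - 1e-9 || params$band[2] > max(freqs) + 1e-9) {
    stop("detection band lies outside the spectrogram frequency range",
         call. = FALSE)
  }
  rows <- which(freqs >= params$band[1] & freqs <= params$band[2])
  if (length(rows) < 2L) {
    stop("detection band covers fewer than two frequency bins", call. = FALSE)
  }

  mag <- spect$magnitude[rows, , drop = FALSE]
  noise_ref <- apply(mag, 1L, median)
  excess <- mag - noise_ref
  frame_peak <- apply(excess, 2L, max)
  active <- which(frame_peak >= params$threshold_db)

  frame_dt <- spect$stft_params$hop / spect$fs
  empty <- data.frame(call_id = character(), channel = character(),
                      t_start = numeric(), t_end = numeric(),
                      duration_ms = numeric(), peak_db = numeric(),
                      stringsAsFactors = FALSE)
  empty$contour <- list()
  if (length(active) == 0L) return(empty)

  max_gap_frames <- floor(params$max_gap_ms / 1000 / frame_dt)
  run_id <- cumsum(c(1L, diff(active) > max_gap_frames + 1L))
  runs <- split(active, run_id)

  out <- list()
  band_freqs <- freqs[rows]
  for (r in runs) {
    f0 <- r[1L]
    f1 <- r[length(r)]
    t_start <- spect$times[f0] - frame_dt / 2
    t_end <- spect$times[f1] + frame_dt / 2
    duration_ms <- (t_end - t_start) * 1000
    if (duration_ms < params$min_duration_ms) next
    cols <- f0:f1
    peak_rows <- max.col(t(mag[, cols, drop = FALSE]), ties.method = "first")
    contour <- data.frame(
      time = spect$times[cols],
      freq = band_freqs[peak_rows],
      mag = mag[cbind(peak_rows, seq_along(cols))]
    )
    if (params$min_bandwidth_khz > 0 &&
        diff(range(contour$freq)) < params$min_bandwidth_khz) next
    out[[length(out) + 1L]] <- list(t_start = t_start, t_end = t_end,
                                    duration_ms = duration_ms,
                                    peak_db = max(contour$mag),
                                    contour = contour)
  }
  if (length(out) == 0L) return(empty)

  calls <- data.frame(
    call_id = sprintf("%s_%04d", channel, seq_along(out)),
    channel = channel,
    t_start = vapply(out, `[[`, numeric(1), "t_start"),
    t_end = vapply(out, `[[`, numeric(1), "t_end"),
    duration_ms = vapply(out, `[[`, numeric(1), "duration_ms"),
    peak_db = vapply(out, `[[`, numeric(1), "peak_db"),
    stringsAsFactors = FALSE
  )
  calls$contour <- lapply(out, `[[`, "contour")
  calls
}

#' Match detected calls against ground truth
#'
#' Greedy one-to-one matching of detected calls to ground-truth events by
#' onset proximity with required interval overlap, then recall and precision.
#'
#' @param detected Data.frame of detected calls (needs `t_start`, `t_end`).
#' @param truth Data.frame of ground-truth events (needs `t_start`, `t_end`).
#' @param tol_s Maximum onset discrepancy for a match, seconds. Default 0.01.
#' @return List with `recall`, `precision`, `n_matched`, and `matches`
#'   (data.frame of matched row indices `truth_row`, `detected_row`).
#' @export
evaluate_detection <- function(detected, truth, tol_s = 0.01) {
  n_d <- nrow(detected)
  n_t <- nrow(truth)
  if (n_t == 0L) {
    return(list(recall = NA_real_, precision = if (n_d) 0 else NA_real_,
                n_matched = 0L,
                matches = data.frame(truth_row = integer(), detected_row = integer())))
  }
  used <- rep(FALSE, n_d)
  t_rows <- integer()
  d_rows <- integer()
  ord <- order(truth$t_start)
  for (i in ord) {
    if (n_d == 0L) break
    onset_diff <- abs(detected$t_start - truth$t_start[i])
    overlap <- pmin(detected$t_end, truth$t_end[i]) -
      pmax(detected$t_start, truth$t_start[i])
    cand <- which(!used & onset_diff <= tol_s & overlap > 0)
    if (length(cand) == 0L) next
    j <- cand[which.min(onset_diff[cand])]
    used[j] <- TRUE
    t_rows <- c(t_rows, i)
    d_rows <- c(d_rows, j)
  }
  list(recall = length(t_rows) / n_t,
       precision = if (n_d) length(d_rows) / n_d else NA_real_,
       n_matched = length(t_rows),
       matches = data.frame(truth_row = t_rows, detected_row = d_rows))
}
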