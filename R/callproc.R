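# Call-level computations: band taxonomies, inflection-based complexity,
# slope statistics, spectral properties, and cross-microphone deduplication.

#' Frequency-band taxonomy for a test type
#'
#' Courtship calls are either syllable vocalizations (SVs, audible
#' 5-15 kHz) or ultrasonic vocalizations (USVs, 25-130 kHz); the 15-25 kHz
#' boundary zone is flagged. Distress calls are USVs (25-130 kHz), squeaks
#' (5-20 kHz), or ranging vocalizations spanning both audible and
#' ultrasonic ranges (5-130 kHz).
#'
#' @param test_type `"courtship"` or `"distress"`.
#' @param usv Ultrasonic band, kHz. Default `c(25, 130)`.
#' @param sv Courtship syllable band, kHz. Default `c(5, 15)`.
#' @param squeak Distress squeak band, kHz. Default `c(5, 20)`.
#' @return A list of class `usv_band_scheme`.
#' @export
band_scheme <- function(test_type = c("courtship", "distress"),
                        usv = c(25, 130), sv = c(5, 15), squeak = c(5, 20)) {
  test_type <- match.arg(test_type)
  for (b in list(usv = usv, sv = sv, squeak = squeak)) {
    if (length(b) != 2L || b[1] >= b[2]) {
      stop("band edges must be ordered pairs", call. = FALSE)
    }
  }
  bands <- if (test_type == "courtship") {
    list(SV = sv, USV = usv)
  } else {
    list(squeak = squeak, USV = usv, ranging = c(sv[1], usv[2]))
  }
  structure(list(test_type = test_type, bands = bands),
            class = "usv_band_scheme")
}

#' Classify a call's frequency extent into a category
#'
#' Courtship: USV when `[f_min, f_max]` lies within the USV band, SV when
#' within the SV band, otherwise `"boundary"` (flagged; excluded from
#' USV/SV-specific statistics but retained in total counts). Distress:
#' `"ranging"` when the call spans both ranges (`f_min` below the squeak
#' ceiling and `f_max` above the USV floor), else USV, else squeak;
#' residual cases are `"boundary"`.
#'
#' @param f_min,f_max Lowest and highest contour frequency, kHz (vectorized).
#' @param scheme A `usv_band_scheme`.
#' @return Character vector of categories.
#' @export
classify_band <- function(f_min, f_max, scheme) {
  stopifnot(inherits(scheme, "usv_band_scheme"))
  if (any(f_max < f_min)) stop("f_max < f_min", call. = FALSE)
  b <- scheme$bands
  if (scheme$test_type == "courtship") {
    ifelse(f_min >= b$USV[1] & f_max <= b$USV[2], "USV",
      ifelse(f_min >= b$SV[1] & f_max <= b$SV[2], "SV", "boundary"))
  } else {
    ifelse(f_min < b$squeak[2] & f_max > b$USV[1], "ranging",
      ifelse(f_min >= b$USV[1] & f_max <= b$USV[2], "USV",
        ifelse(f_max <= b$squeak[2] & f_min >= b$ranging[1], "squeak",
               "boundary")))
  }
}

# moving-average smoothing with partial windows at the edges
smooth_ma <- function(x, halfwidth) {
  if (halfwidth <= 0) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - halfwidth, 1L)
  hi <- pmin(seq_len(n) + halfwidth, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Count inflection points in a frequency contour
#'
#' An inflection point is an interior extremum of the call's frequency
#' trajectory: a sign change of the first difference after moving-average
#' smoothing. Zero differences inherit the preceding nonzero sign, so
#' plateaus do not create spurious extrema. A call with zero inflection
#' points is "simple"; one or more make it "complex".
#'
#' @param contour A contour data.frame (column `freq`) or a numeric vector
#'   of frequencies; at least 3 samples.
#' @param smooth_halfwidth Moving-average half-width in frames (window
#'   `2 * halfwidth + 1`). Default 2, which suppresses single-bin argmax
#'   jitter in detected contours; use 0 for exact sampled trajectories.
#' @return Integer count of interior extrema.
#' @export
count_inflections <- function(contour, smooth_halfwidth = 2) {
  freq <- if (is.data.frame(contour)) contour$freq else as.numeric(contour)
  if (length(freq) < 3L) {
    stop("contour must have at least 3 samples", call. = FALSE)
  }
  s <- sign(diff(smooth_ma(freq, smooth_halfwidth)))
  # zeros inherit the previous nonzero sign; leading zeros carry no sign
  last <- 0
  for (i in seq_along(s)) {
    if (s[i] == 0) s[i] <- last else last <- s[i]
  }
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(s[-1L] != s[-length(s)])
}

#' Signed slope of a call contour
#'
#' Least-squares linear fit of frequency against time over the whole
#' contour (default), or the endpoints-only chord slope for sensitivity
#' checks. The sign of the fit defines positive- vs negative-sloped calls.
#'
#' @param contour A contour data.frame (`time` in s, `freq` in kHz), or a
#'   numeric vector of frequencies with `time` supplied separately.
#' @param time Optional time vector (s) when `contour` is a plain vector.
#' @param method `"ls"` (default) or `"endpoints"`.
#' @return Slope in kHz/s (signed).
#' @export
call_slope <- function(contour, time = NULL, method = c("ls", "endpoints")) {
  method <- match.arg(method)
  if (is.data.frame(contour)) {
    time <- contour$time
    freq <- contour$freq
  } else {
    freq <- as.numeric(contour)
  }
  if (length(freq) < 2L || is.null(time) || diff(range(time)) <= 0) {
    stop("contour needs >= 2 samples spanning a positive duration",
         call. = FALSE)
  }
  if (method == "endpoints") {
    (freq[length(freq)] - freq[1L]) / (time[length(time)] - time[1L])
  } else {
    tc <- time - mean(time)
    sum(tc * (freq - mean(freq))) / sum(tc^2)
  }
}

#' Sign of a slope for +/- ratio purposes
#'
#' @param slope Slope in kHz/s (vectorized).
#' @param tol Magnitudes at or below `tol` count as zero-sloped (neither
#'   positive nor negative). Default 1e-6.
#' @return Character vector in `"+"`, `"-"`, `"0"`.
#' @export
slope_sign <- function(slope, tol = 1e-6) {
  ifelse(slope > tol, "+", ifelse(slope < -tol, "-", "0"))
}

#' Spectral properties of a call
#'
#' The four call characteristics: mean frequency is the average of the
#' call's lowest and highest frequency points; range is the distance
#' between them; duration is the call's length in time; power is the
#' summed squared linear magnitude over the call's time-frequency support,
#' in dB (relative). Doubling a call's amplitude raises power by ~6.02 dB.
#'
#' @param contour Contour data.frame with `time` (s), `freq` (kHz), and
#'   `mag` (dB) columns; nonempty.
#' @param t_start,t_end Optional call interval (s); defaults to the contour
#'   time extent.
#' @return List with `f_min`, `f_max`, `f_mean`, `f_range` (kHz),
#'   `duration_ms`, `power_db`, `peak_db`.
#' @export
spectral_properties <- function(contour, t_start = NULL, t_end = NULL) {
  if (!is.data.frame(contour) || nrow(contour) == 0L) {
    stop("contour is empty", call. = FALSE)
  }
  t_start <- t_start %||% min(contour$time)
  t_end <- t_end %||% max(contour$time)
  f_min <- min(contour$freq)
  f_max <- max(contour$freq)
  list(f_min = f_min, f_max = f_max,
       f_mean = (f_min + f_max) / 2, f_range = f_max - f_min,
       duration_ms = (t_end - t_start) * 1000,
       power_db = 10 * log10(sum(10^(contour$mag / 10))),
       peak_db = max(contour$mag))
}

# Pearson correlation between two contours resampled to a common relative
# time grid. Near-constant contours (flat calls) have no defined
# correlation; they are treated as similar when their mean frequencies are
# within 2 kHz.
contour_similarity <- function(c1, c2, n_points = 50) {
  grid <- seq(0, 1, length.out = n_points)
  r1 <- approx((c1$time - min(c1$time)) / diff(range(c1$time)), c1$freq,
               xout = grid, rule = 2)$y
  r2 <- approx((c2$time - min(c2$time)) / diff(range(c2$time)), c2$freq,
               xout = grid, rule = 2)$y
  if (sd(r1) < 1e-9 || sd(r2) < 1e-9) {
    return(if (abs(mean(r1) - mean(r2)) < 2) 1 else 0)
  }
  cor(r1, r2)
}

#' Cross-microphone deduplication
#'
#' A call emitted near one microphone can bleed onto the other. Left/right
#' call pairs whose start times differ by at most `window_s`, whose
#' time-aligned contours correlate at least `similarity_min`, and whose mean
#' contour frequencies agree within `f_tol_khz` are treated as one physical
#' call, and only the louder copy (greater peak magnitude) is retained; all
#' other calls pass through unchanged. The frequency gate matters because
#' contour correlation alone cannot distinguish two different monotone
#' sweeps: a bleed copy shares the emitter's frequencies, a coincident call
#' from the other mouse generally does not.
#'
#' @param calls_left,calls_right Call data.frames (from [detect_calls()] or
#'   [annotate_calls()]) sorted by `t_start`, with `contour` list-columns
#'   and `peak_db`.
#' @param window_s Maximum onset difference for a candidate pair, seconds.
#'   Default 0.2.
#' @param similarity_min Minimum contour correlation. Default 0.6.
#' @param f_tol_khz Maximum mean-frequency difference for a candidate pair,
#'   kHz. Default 5.
#' @return The deduplicated call data.frame (sorted by `t_start`) with an
#'   attribute `n_matched` (number of removed far copies). Conservation:
#'   `nrow(out) == nrow(left) + nrow(right) - n_matched`.
#' @export
deduplicate_channels <- function(calls_left, calls_right, window_s = 0.2,
                                 similarity_min = 0.6, f_tol_khz = 5) {
  n_l <- nrow(calls_left) %||% 0L
  n_r <- nrow(calls_right) %||% 0L
  if (n_l == 0L && n_r == 0L) {
    out <- calls_left %||% calls_right
    attr(out, "n_matched") <- 0L
    return(out)
  }
  if (n_l == 0L || n_r == 0L) {
    out <- if (n_l == 0L) calls_right else calls_left
    out <- out[order(out$t_start), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "n_matched") <- 0L
    return(out)
  }

  right_used <- rep(FALSE, n_r)
  drop_left <- rep(FALSE, n_l)
  drop_right <- rep(FALSE, n_r)
  mean_freq <- function(calls) {
    vapply(calls$contour, function(ct) mean(ct$freq), numeric(1))
  }
  mf_l <- mean_freq(calls_left)
  mf_r <- mean_freq(calls_right)
  for (i in seq_len(n_l)) {
    dt <- abs(calls_right$t_start - calls_left$t_start[i])
    cand <- which(!right_used & dt <= window_s &
                    abs(mf_r - mf_l[i]) <= f_tol_khz)
    if (length(cand) == 0L) next
    sims <- vapply(cand, function(j) {
      contour_similarity(calls_left$contour[[i]], calls_right$contour[[j]])
    }, numeric(1))
    ok <- sims >= similarity_min
    if (!any(ok)) next
    j <- cand[ok][which.max(sims[ok])]
    right_used[j] <- TRUE
    if (calls_left$peak_db[i] >= calls_right$peak_db[j]) {
      drop_right[j] <- TRUE
    } else {
      drop_left[i] <- TRUE
    }
  }

  out <- rbind(calls_left[!drop_left, , drop = FALSE],
               calls_right[!drop_right, , drop = FALSE])
  out <- out[order(out$t_start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_matched") <- sum(drop_left) + sum(drop_right)
  out
}

#' Annotate calls with derived call-level fields
#'
#' Computes, for each call in a table with contours: the four spectral
#' properties, signed slope and its sign, inflection count, band category,
#' and (for USVs) simple/complex status.
#'
#' @param calls Call data.frame with `t_start`, `t_end` and a `contour`
#'   list-column.
#' @param scheme A `usv_band_scheme`; see [band_scheme()].
#' @param smooth_halfwidth Passed to [count_inflections()]. Default 2.
#' @param slope_method Passed to [call_slope()]. Default `"ls"`.
#' @return `calls` with columns `f_min`, `f_max`, `f_mean`, `f_range`,
#'   `duration_ms`, `power_db`, `peak_db`, `slope`, `slope_sign`,
#'   `n_inflections`, `category`, `complexity` added.
#' @export
annotate_calls <- function(calls, scheme, smooth_halfwidth = 2,
                           slope_method = "ls") {
  stopifnot(inherits(scheme, "usv_band_scheme"))
  n <- nrow(calls)
  props <- lapply(seq_len(n), function(i) {
    spectral_properties(calls$contour[[i]], calls$t_start[i], calls$t_end[i])
  })
  for (f in c("f_min", "f_max", "f_mean", "f_range", "duration_ms",
              "power_db", "peak_db")) {
    calls[[f]] <- vapply(props, `[[`, numeric(1), f)
  }
  calls$slope <- vapply(seq_len(n), function(i) {
    call_slope(calls$contour[[i]], method = slope_method)
  }, numeric(1))
  calls$slope_sign <- slope_sign(calls$slope)
  calls$n_inflections <- vapply(seq_len(n), function(i) {
    count_inflections(calls$contour[[i]], smooth_halfwidth)
  }, integer(1))
  calls$category <- if (n) classify_band(calls$f_min, calls$f_max, scheme) else character()
  calls$complexity <- ifelse(calls$category == "USV",
                             ifelse(calls$n_inflections >= 1, "complex", "simple"),
                             NA_character_)
  calls
}
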