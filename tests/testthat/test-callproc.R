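# Call-level computations: band taxonomy, inflection counting, slope,
# spectral properties, and cross-microphone deduplication.

test_that("courtship calls classify into USV, SV, or flagged boundary", {
  scheme <- band_scheme("courtship")
  expect_equal(classify_band(60, 75, scheme), "USV")
  expect_equal(classify_band(8, 12, scheme), "SV")
  expect_equal(classify_band(17, 19, scheme), "boundary") # 15-25 kHz zone
  expect_equal(classify_band(12, 30, scheme), "boundary") # straddles bands
  expect_error(classify_band(30, 20, scheme), "f_max")
})

test_that("distress calls classify with ranging taking precedence", {
  scheme <- band_scheme("distress")
  expect_equal(classify_band(10, 70, scheme), "ranging")
  expect_equal(classify_band(8, 15, scheme), "squeak")
  expect_equal(classify_band(60, 80, scheme), "USV")
  # spans both ranges even though it would also fit neither band alone
  expect_equal(classify_band(18, 40, scheme), "ranging")
  expect_equal(classify_band(21, 24, scheme), "boundary")
})

test_that("inflection counting matches brute-force extrema enumeration", {
  expect_equal(count_inflections(c(1, 2, 3, 4, 5), 0), 0L)
  expect_equal(count_inflections(c(1, 3, 5, 3, 1), 0), 1L)
  s <- sin(seq(0, 3 * pi, length.out = 31))  # three interior extrema
  expect_equal(count_inflections(s, 0), 3L)
  expect_equal(count_inflections(s, 0), oracle_count_extrema(s))
  # plateaus inherit the previous sign and create no extremum
  expect_equal(count_inflections(c(1, 2, 2, 3), 0), 0L)
  expect_equal(count_inflections(c(1, 2, 2, 1), 0), 1L)
  expect_error(count_inflections(c(1, 2), 0), "3 samples")
})

test_that("smoothing suppresses single-frame jitter without losing shape", {
  set.seed(8)
  base <- synthesize_contour("complex", 60, 20, 60, n_inflections = 1,
                             frame_step_ms = 1)
  jitter <- base$freq + sample(c(-0.5, 0, 0.5), nrow(base), replace = TRUE)
  expect_gte(count_inflections(jitter, 0), 2L)    # jitter inflates raw count
  expect_equal(count_inflections(jitter, 2), 1L)  # smoothing recovers truth
})

test_that("slope fits are signed and symmetric arches are zero-sloped", {
  up <- synthesize_contour("simple_positive", 60, 20, 50)
  down <- synthesize_contour("simple_negative", 80, 20, 50)
  expect_equal(call_slope(up), 400, tolerance = 1e-9)
  expect_equal(call_slope(down), -400, tolerance = 1e-9)
  expect_equal(call_slope(up, method = "endpoints"), 400, tolerance = 1e-9)
  arch <- synthesize_contour("complex", 60, 20, 50, n_inflections = 1)
  expect_equal(call_slope(arch), 0, tolerance = 1e-6)
  expect_equal(slope_sign(call_slope(arch)), "0")
  expect_error(call_slope(data.frame(time = 1, freq = 60)), "2 samples")
})

test_that("spectral properties follow the lowest/highest point definitions", {
  ct <- synthesize_contour("simple_positive", 60, 20, 50, amplitude_db = -25)
  p <- spectral_properties(ct, t_start = 1.0, t_end = 1.05)
  expect_equal(p$f_mean, 70)
  expect_equal(p$f_range, 20)
  expect_equal(p$duration_ms, 50)
  # doubling amplitude raises summed power by 20*log10(2) dB
  ct2 <- ct
  ct2$mag <- ct$mag + 20 * log10(2)
  p2 <- spectral_properties(ct2)
  expect_equal(p2$power_db - p$power_db, 6.02, tolerance = 0.01)
  expect_error(spectral_properties(data.frame()), "empty")
})

test_that("rendered amplitude doubling raises measured call power ~6 dB", {
  cfg <- dyad_config(seed = 51, session_s = 1, rate_wt = 0, rate_as = 0)
  ct <- synthesize_contour("simple_positive", 60, 15, 40, amplitude_db = -26)
  ct$time <- ct$time + 0.4
  ev <- data.frame(event_id = "e1", mouse_id = "WT01", genotype = "WT",
                   dyad = 1L, mic = "left", channel = "near",
                   t_start = 0.4, t_end = 0.44, duration_ms = 40,
                   category = "USV", shape = "simple_positive",
                   true_inflections = 0L, true_slope_sign = "+",
                   f_low = 60, f_high = 75, amplitude_db = -26,
                   stringsAsFactors = FALSE)
  ev$contour <- list(ct)
  aud <- render_audio_pair(ev, cfg)
  powers <- sapply(c(1, 2), function(gain) {
    det <- detect_calls(compute_spectrogram(aud$left$samples * gain,
                                            fs = aud$left$fs))
    expect_equal(nrow(det), 1L)
    spectral_properties(det$contour[[1]])$power_db
  })
  expect_equal(powers[2] - powers[1], 20 * log10(2), tolerance = 0.1)
})

test_that("louder-microphone copies win deduplication within the window", {
  left <- make_call("WT01", t_start = 1.00, mag = -20, channel = "left")
  right <- make_call("WT01", t_start = 1.05, mag = -35, channel = "right")
  out <- deduplicate_channels(left, right)
  expect_equal(nrow(out), 1L)
  expect_equal(out$channel, "left")
  expect_equal(attr(out, "n_matched"), 1L)

  # louder copy on the right is the one retained
  out2 <- deduplicate_channels(make_call(t_start = 1, mag = -35, channel = "left"),
                               make_call(t_start = 1.02, mag = -18, channel = "right"))
  expect_equal(out2$channel, "right")
})

test_that("calls outside the window or with dissimilar contours both survive", {
  left <- make_call("WT01", t_start = 1.0, channel = "left")
  far_apart <- make_call("WT01", t_start = 1.5, channel = "right")
  out <- deduplicate_channels(left, far_apart)
  expect_equal(nrow(out), 2L)
  expect_equal(attr(out, "n_matched"), 0L)

  # same onset but opposite sweep direction: not the same call
  down <- make_call("AS01", t_start = 1.1, f0 = 80, f1 = 60, channel = "right")
  out2 <- deduplicate_channels(left, down)
  expect_equal(nrow(out2), 2L)
})

test_that("deduplication conserves calls: |out| = |L| + |R| - matched", {
  set.seed(61)
  lefts <- do.call(rbind, lapply(seq(0.5, 4, by = 0.5), function(t0) {
    make_call("WT01", t_start = t0, mag = -20, channel = "left")
  }))
  rights <- do.call(rbind, lapply(c(0.55, 2.05, 3.55, 5), function(t0) {
    make_call("AS01", t_start = t0, mag = -32, channel = "right")
  }))
  out <- deduplicate_channels(lefts, rights)
  m <- attr(out, "n_matched")
  expect_equal(nrow(out), nrow(lefts) + nrow(rights) - m)
  expect_equal(m, 3L)
  expect_false(any(duplicated(out$call_id)))
})

test_that("annotation reproduces truth labels on generated cohorts", {
  for (tt in c("courtship", "distress")) {
    cfg <- generator_config(tt, n_per_genotype = 2, seed = 17,
                            call_rate_mean = c(WT = 25, AS = 12),
                            session_s = 120)
    ev <- generate_cohort(cfg)$events
    ann <- annotate_calls(ev, band_scheme(tt), smooth_halfwidth = 0)
    expect_equal(ann$category, ev$category)
    usv <- ann[ann$category == "USV", ]
    # complexity is complex iff at least one inflection point
    expect_equal(usv$complexity == "complex", usv$n_inflections >= 1)
    expect_equal(usv$complexity == "complex", usv$shape == "complex")
    # simple-call slope signs match the generator's draw
    simple <- ann[ann$shape %in% c("simple_positive", "simple_negative"), ]
    expect_equal(simple$slope_sign,
                 ifelse(simple$shape == "simple_positive", "+", "-"))
  }
})
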