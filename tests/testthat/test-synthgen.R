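# Synthetic cohort generator: configuration, determinism, count model,
# contour geometry, and audio rendering.

test_that("config validation names the offending field", {
  expect_error(generator_config(n_per_genotype = 0), "n_per_genotype")
  expect_error(generator_config(call_rate_mean = c(WT = -1, AS = 10)),
               "call_rate_mean")
  expect_error(
    generator_config(category_mix = list(WT = c(USV = 0.7, SV = 0.2),
                                         AS = c(USV = 0.5, SV = 0.5))),
    "category_mix"
  )
  expect_error(generator_config(call_rate_dispersion = -0.5),
               "call_rate_dispersion")
  expect_error(generator_config(complexity_prob = c(WT = 1.2, AS = 0.2)),
               "complexity_prob")
})

test_that("zero call rate yields an empty event list but a full battery", {
  cfg <- generator_config(call_rate_mean = c(WT = 0, AS = 0), seed = 4)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh$events), 0L)
  expect_equal(nrow(coh$battery), 26L)
  expect_true(all(measure_set("battery7") %in% names(coh$battery)))
})

test_that("identical config and seed reproduce the cohort bit-for-bit", {
  cfg <- generator_config(n_per_genotype = 3,
                          call_rate_mean = c(WT = 20, AS = 8),
                          session_s = 60, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$battery, b$battery)
  expect_identical(a$events, b$events)
  cfg2 <- cfg
  cfg2$seed <- 8L
  c <- generate_cohort(cfg2)
  expect_false(identical(a$events$t_start, c$events$t_start))
})

test_that("Poisson call totals land near the configured genotype rates", {
  cfg <- generator_config("courtship", call_rate_dispersion = 0, seed = 21)
  ev <- generate_cohort(cfg, include_contours = FALSE)$events
  total_wt <- sum(ev$genotype == "WT")
  total_as <- sum(ev$genotype == "AS")
  # one draw of 13 Poisson(700) mice: total within 4 sd of 13 * 700
  expect_lt(abs(total_wt - 13 * 700), 4 * sqrt(13 * 700))
  expect_lt(abs(total_as - 13 * 93), 4 * sqrt(13 * 93))
})

test_that("contour shapes obey their defining geometry", {
  up <- synthesize_contour("simple_positive", 60, 20, 50)
  expect_true(all(diff(up$freq) > 0))
  expect_equal(call_slope(up), 400, tolerance = 1e-9)
  expect_equal(count_inflections(up, smooth_halfwidth = 0), 0L)
  expect_equal(range(up$freq), c(60, 80))

  down <- synthesize_contour("simple_negative", 80, 20, 50)
  expect_true(all(diff(down$freq) < 0))
  expect_equal(call_slope(down), -400, tolerance = 1e-9)

  flat <- synthesize_contour("flat", 70, 0, 30)
  expect_equal(unique(flat$freq), 70)
  expect_equal(slope_sign(call_slope(flat)), "0")

  for (m in 1:5) {
    cx <- synthesize_contour("complex", 60, 20, 60, n_inflections = m,
                             frame_step_ms = 1)
    expect_equal(count_inflections(cx, smooth_halfwidth = 0),
                 oracle_count_extrema(cx$freq))
    expect_equal(count_inflections(cx, smooth_halfwidth = 0), m)
  }

  expect_error(synthesize_contour("simple_positive", 60, 20, 0), "duration")
  expect_error(synthesize_contour("complex", 60, 20, 50, n_inflections = 0),
               "n_inflections")
})

test_that("generated events satisfy the ground-truth invariants", {
  for (tt in c("courtship", "distress")) {
    cfg <- generator_config(tt, n_per_genotype = 3, seed = 13)
    ev <- generate_cohort(cfg)$events
    expect_true(all(ev$t_end > ev$t_start))
    expect_equal(ev$duration_ms, (ev$t_end - ev$t_start) * 1000,
                 tolerance = 1e-9)
    for (k in seq_len(nrow(ev))) {
      ct <- ev$contour[[k]]
      expect_true(all(diff(ct$time) > 0))
      expect_gte(min(ct$time), ev$t_start[k] - 1e-9)
      expect_lte(max(ct$time), ev$t_end[k] + 1e-9)
      expect_true(all(ct$freq >= 1 & ct$freq <= 125))
    }
    # truth labels agree with the band taxonomy by construction
    expect_equal(classify_band(ev$f_low, ev$f_high, band_scheme(tt)),
                 ev$category)
    # complexity labels agree with the inflection definition
    usv <- ev[ev$category == "USV", ]
    expect_equal(usv$true_inflections >= 1, usv$shape == "complex")
  }
})

test_that("event-free audio sits at the configured noise floor", {
  cfg <- dyad_config(seed = 31, session_s = 2, rate_wt = 0, rate_as = 0)
  ev <- generate_cohort(cfg)$events
  aud <- render_audio_pair(ev, cfg)
  for (ch in aud) {
    rms_db <- 20 * log10(sqrt(mean(ch$samples^2)))
    expect_lt(abs(rms_db - cfg$noise_floor_db), 1)
  }
})

test_that("a rendered tone peaks at its frequency, and bleed is attenuated", {
  cfg <- dyad_config(seed = 32, session_s = 1, rate_wt = 0, rate_as = 0)
  ct <- synthesize_contour("flat", 70, 0, 50, amplitude_db = -20)
  ct$time <- ct$time + 0.4
  ev <- data.frame(event_id = "e1", mouse_id = "WT01", genotype = "WT",
                   dyad = 1L, mic = "left", channel = "both",
                   t_start = 0.4, t_end = 0.45, duration_ms = 50,
                   category = "USV", shape = "flat", true_inflections = 0L,
                   true_slope_sign = "0", f_low = 70, f_high = 70,
                   amplitude_db = -20, stringsAsFactors = FALSE)
  ev$contour <- list(ct)
  aud <- render_audio_pair(ev, cfg)
  sp_near <- compute_spectrogram(aud$left)
  sp_far <- compute_spectrogram(aud$right)
  bin_khz <- diff(sp_near$freqs[1:2])

  mid <- which.min(abs(sp_near$times - 0.425))
  peak_bin <- which.max(sp_near$magnitude[, mid])
  expect_lt(abs(sp_near$freqs[peak_bin] - 70), bin_khz + 1e-9)

  near_peak <- max(sp_near$magnitude[peak_bin, ])
  far_peak <- max(sp_far$magnitude[peak_bin, ])
  expect_lt(abs((near_peak - far_peak) - cfg$mic_model$attenuation_db), 1.5)

  # contour frequencies at or above Nyquist are refused
  ev_bad <- ev
  bad_ct <- ct
  bad_ct$freq <- 126
  ev_bad$contour <- list(bad_ct)
  expect_error(render_audio_pair(ev_bad, cfg), "Nyquist")
})

test_that("severity cohorts carry the requested standardized effect", {
  tab <- simulate_severity_cohort(n_per_genotype = 13,
                                  measure_set = "battery_distress9",
                                  effect_sd = 2, seed = 5)
  expect_equal(nrow(tab), 26L)
  expect_setequal(setdiff(names(tab), c("mouse_id", "genotype")),
                  measure_set("battery_distress9"))
  expect_true(all(tab$distress_usv >= 0))
  expect_true(all(tab$distress_usv == round(tab$distress_usv)))
  # calibrated count effect: standardized WT-AS gap near 2 SD on average
  gaps <- sapply(1:40, function(i) {
    t2 <- simulate_severity_cohort(13, "battery_distress9", 2,
                                   seed = 1000 + i)
    x <- t2$distress_usv
    g <- t2$genotype
    (mean(x[g == "WT"]) - mean(x[g == "AS"])) /
      sqrt((var(x[g == "WT"]) + var(x[g == "AS"])) / 2)
  })
  expect_equal(mean(gaps), 2, tolerance = 0.25)
})
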