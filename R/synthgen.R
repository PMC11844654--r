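# Seeded synthetic cohorts: behavior-battery measures, call events with
# frequency contours, and (optionally, via render_audio_pair) two-channel
# 250 kHz audio. The generator encodes the genotype structure the analyses
# assume: wild-type (WT) mice call far more than Ube3a-deficient (AS)
# littermates, category mixes differ, and AS spectral parameters are shifted
# toward lower frequencies, smaller excursions, flatter slopes, and fewer
# inflections.

CATEGORIES <- list(courtship = c("USV", "SV"),
                   distress = c("USV", "squeak", "ranging"))

# Frequency envelope each category is generated inside (kHz); kept strictly
# inside the classification bands so ground-truth labels are unambiguous.
category_freq_limits <- function(category) {
  switch(category,
    USV = c(25, 124),
    SV = c(5, 15),
    squeak = c(5, 20),
    ranging = c(5, 124),
    stop("unknown category: ", category, call. = FALSE)
  )
}

default_spectral_params <- function(test_type) {
  # means/SDs for onset frequency (kHz), excursion magnitude (kHz),
  # duration (ms), amplitude (dB re full scale), per genotype and category.
  sp <- function(f_onset, f_sd, exc, exc_sd, dur, dur_sd, amp, amp_sd) {
    list(f_onset = c(mean = f_onset, sd = f_sd),
         excursion = c(mean = exc, sd = exc_sd),
         duration_ms = c(mean = dur, sd = dur_sd),
         amplitude_db = c(mean = amp, sd = amp_sd))
  }
  if (test_type == "courtship") {
    list(
      WT = list(USV = sp(68, 8, 25, 8, 50, 15, -25, 4),
                SV = sp(9, 1.5, 3, 1, 80, 20, -22, 4)),
      AS = list(USV = sp(60, 8, 14, 5, 45, 15, -25, 4),
                SV = sp(9, 1.5, 3, 1, 80, 20, -22, 4))
    )
  } else {
    list(
      WT = list(USV = sp(66, 7, 20, 7, 45, 12, -24, 4),
                squeak = sp(11, 2, 4, 1.5, 90, 25, -20, 4),
                ranging = sp(14, 2, 55, 15, 70, 20, -22, 4)),
      AS = list(USV = sp(58, 7, 13, 5, 42, 12, -24, 4),
                squeak = sp(11, 2, 4, 1.5, 90, 25, -20, 4),
                ranging = sp(14, 2, 45, 12, 65, 20, -22, 4))
    )
  }
}

#' Synthetic-cohort generator configuration
#'
#' Builds and validates the configuration driving [generate_cohort()] and
#' [render_audio_pair()]. Defaults encode the study conditions of a
#' courtship (20 min, two-microphone) or distress (60 s, single-microphone)
#' session with 13 mice per genotype: WT call rates greatly exceed AS rates
#' (defaults echo per-genotype call totals of roughly 9100 vs 1200 calls for
#' 13 courtship mice each), AS mice produce relatively more audible calls,
#' and AS spectral parameters are shifted down.
#'
#' @param test_type `"courtship"` (categories USV/SV) or `"distress"`
#'   (USV/squeak/ranging).
#' @param n_per_genotype Mice per genotype (>= 1). Default 13.
#' @param call_rate_mean Named vector `c(WT=, AS=)`: mean calls per session.
#' @param call_rate_dispersion Negative-binomial dispersion `phi` so that
#'   `var = mu * (1 + phi * mu)`; 0 degrades to Poisson. Default 0.1
#'   (per-mouse call counts are overdispersed).
#' @param category_mix Per-genotype probability vectors over the test's
#'   categories (each must sum to 1).
#' @param spectral_params Per-genotype, per-category list of `mean`/`sd`
#'   pairs for `f_onset` (kHz), `excursion` (kHz), `duration_ms`,
#'   `amplitude_db`. See `usvseverity:::default_spectral_params`.
#' @param complexity_prob Named vector: probability a USV has >= 1
#'   inflection point, per genotype.
#' @param slope_sign_prob Named vector: probability a simple call rises
#'   (positive slope), per genotype.
#' @param battery_effects Named vector of per-measure genotype shifts in SD
#'   units applied (downward) to AS mice; measures are unit-variance.
#'   Default: 2 SD on each of the seven battery measures.
#' @param session_s Session length in seconds. Default 1200 (courtship) or
#'   60 (distress).
#' @param mic_model List with `attenuation_db` (far-channel attenuation of
#'   bleed-through, default 15) and `bleed_prob` (probability a call is also
#'   picked up on the far microphone, default 0.02; courtship only).
#' @param noise_floor_db Microphone noise floor in dB re full scale
#'   (RMS). Default -60.
#' @param frame_step_ms Ground-truth contour sampling step, ms. Default 2.
#' @param seed Integer seed; every draw in [generate_cohort()] and
#'   [render_audio_pair()] derives from it.
#' @return A validated list of class `usv_generator_config`.
#' @export
generator_config <- function(test_type = c("courtship", "distress"),
                             n_per_genotype = 13,
                             call_rate_mean = NULL,
                             call_rate_dispersion = 0.1,
                             category_mix = NULL,
                             spectral_params = NULL,
                             complexity_prob = c(WT = 0.5, AS = 0.2),
                             slope_sign_prob = c(WT = 0.6, AS = 0.4),
                             battery_effects = NULL,
                             session_s = NULL,
                             mic_model = list(attenuation_db = 15, bleed_prob = 0.02),
                             noise_floor_db = -60,
                             frame_step_ms = 2,
                             seed = 1) {
  test_type <- match.arg(test_type)
  cats <- CATEGORIES[[test_type]]

  if (is.null(call_rate_mean)) {
    call_rate_mean <- if (test_type == "courtship") {
      c(WT = 700, AS = 93)     # ~9100 and ~1200 calls across 13 mice each
    } else {
      c(WT = 125, AS = 31)     # ~1630 and ~400 calls across 13 mice each
    }
  }
  if (is.null(category_mix)) {
    category_mix <- if (test_type == "courtship") {
      list(WT = c(USV = 0.92, SV = 0.08), AS = c(USV = 0.55, SV = 0.45))
    } else {
      list(WT = c(USV = 0.45, squeak = 0.25, ranging = 0.30),
           AS = c(USV = 0.25, squeak = 0.50, ranging = 0.25))
    }
  }
  if (is.null(spectral_params)) spectral_params <- default_spectral_params(test_type)
  if (is.null(battery_effects)) {
    battery_effects <- c(weight = 2, rotarod_d1 = 2, rotarod_d5 = 2,
                         of_distance = 2, of_center_time = 2,
                         marbles_buried = 2, nest_d5 = 2)
  }
  if (is.null(session_s)) session_s <- if (test_type == "courtship") 1200 else 60

  if (!is.numeric(n_per_genotype) || n_per_genotype < 1) {
    fail_field("n_per_genotype", "must be >= 1")
  }
  for (g in c("WT", "AS")) {
    if (is.na(call_rate_mean[g]) || call_rate_mean[g] < 0) {
      fail_field("call_rate_mean", paste0("rate for ", g, " must be >= 0"))
    }
    check_prob_vector(category_mix[[g]], paste0("category_mix$", g))
    if (!setequal(names(category_mix[[g]]), cats)) {
      fail_field(paste0("category_mix$", g),
                 paste0("must name the categories ", paste(cats, collapse = ", ")))
    }
    for (p in c("complexity_prob", "slope_sign_prob")) {
      v <- get(p)[g]
      if (is.na(v) || v < 0 || v > 1) fail_field(p, paste0(g, " must be in [0, 1]"))
    }
    for (cat in cats) {
      par <- spectral_params[[g]][[cat]]
      if (is.null(par)) {
        fail_field("spectral_params", paste0("missing ", g, "$", cat))
      }
      sds <- vapply(par, function(x) x[["sd"]], numeric(1))
      if (any(sds < 0)) fail_field("spectral_params", "SDs must be >= 0")
    }
  }
  if (!is.numeric(call_rate_dispersion) || call_rate_dispersion < 0) {
    fail_field("call_rate_dispersion", "must be >= 0")
  }
  if (!is.numeric(session_s) || session_s <= 0) {
    fail_field("session_s", "must be > 0")
  }
  if (is.null(mic_model$attenuation_db) || is.null(mic_model$bleed_prob) ||
      mic_model$bleed_prob < 0 || mic_model$bleed_prob > 1) {
    fail_field("mic_model", "needs attenuation_db and bleed_prob in [0, 1]")
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    fail_field("seed", "must be a single integer")
  }

  structure(list(
    test_type = test_type, n_per_genotype = as.integer(n_per_genotype),
    call_rate_mean = call_rate_mean,
    call_rate_dispersion = call_rate_dispersion,
    category_mix = category_mix, spectral_params = spectral_params,
    complexity_prob = complexity_prob, slope_sign_prob = slope_sign_prob,
    battery_effects = battery_effects, session_s = session_s,
    mic_model = mic_model, noise_floor_db = noise_floor_db,
    frame_step_ms = frame_step_ms, seed = as.integer(seed)
  ), class = "usv_generator_config")
}

# Draw per-mouse call counts: negative binomial (mean mu, var mu(1+phi*mu));
# phi = 0 degrades to Poisson.
draw_call_counts <- function(n, mu, phi) {
  if (mu == 0) return(rep(0L, n))
  if (phi == 0) rpois(n, mu) else rnbinom(n, size = 1 / phi, mu = mu)
}

#' Synthesize a single call contour
#'
#' Frequency trajectories by shape: `simple_positive` / `simple_negative`
#' are monotone linear ramps, `flat` is constant, and `complex` is a
#' raised-cosine trajectory with exactly `n_inflections` interior extrema.
#'
#' @param shape One of `"simple_positive"`, `"simple_negative"`, `"flat"`,
#'   `"complex"`.
#' @param f_onset Onset frequency, kHz.
#' @param excursion Frequency excursion magnitude, kHz (its absolute value
#'   is used; direction comes from `shape`; ignored for `flat`).
#' @param duration_ms Call duration in ms (> 0).
#' @param n_inflections Number of interior extrema; required >= 1 iff
#'   `shape = "complex"`.
#' @param frame_step_ms Contour sampling step, ms. Default 2.
#' @param amplitude_db Constant magnitude stored on the contour, dB. Default -25.
#' @return A contour data.frame with `time` (s, starting at 0), `freq`
#'   (kHz), `mag` (dB).
#' @examples
#' k <- synthesize_contour("simple_positive", 60, 20, 50)
#' range(k$freq) # 60 to 80 kHz
#' @export
synthesize_contour <- function(shape = c("simple_positive", "simple_negative",
                                         "flat", "complex"),
                               f_onset, excursion = 0, duration_ms,
                               n_inflections = 0, frame_step_ms = 2,
                               amplitude_db = -25) {
  shape <- match.arg(shape)
  f_onset <- unname(f_onset)
  excursion <- unname(excursion)
  duration_ms <- unname(duration_ms)
  amplitude_db <- unname(amplitude_db)
  if (!is.finite(duration_ms) || duration_ms <= 0) {
    stop("duration_ms: must be > 0", call. = FALSE)
  }
  if (shape == "complex" && n_inflections < 1) {
    stop("n_inflections: complex contours require n_inflections >= 1",
         call. = FALSE)
  }
  exc <- abs(excursion)
  n <- max(3L, as.integer(ceiling(duration_ms / frame_step_ms)) + 1L)
  tt <- seq(0, duration_ms / 1000, length.out = n)
  u <- tt / max(tt)
  freq <- switch(shape,
    simple_positive = f_onset + exc * u,
    simple_negative = f_onset - exc * u,
    flat = rep(f_onset, n),
    complex = f_onset + exc / 2 * (1 - cos(pi * (n_inflections + 1) * u))
  )
  data.frame(time = tt, freq = freq, mag = amplitude_db)
}

# Draw spectral parameters for a block of calls, vectorized per category.
draw_spectral_block <- function(category, params) {
  spec <- matrix(NA_real_, length(category), 4,
                 dimnames = list(NULL, c("f_onset", "excursion",
                                         "duration_ms", "amplitude_db")))
  for (cat in unique(category)) {
    idx <- which(category == cat)
    par <- params[[cat]]
    spec[idx, "f_onset"] <- rnorm(length(idx), par$f_onset[["mean"]],
                                  par$f_onset[["sd"]])
    spec[idx, "excursion"] <- abs(rnorm(length(idx), par$excursion[["mean"]],
                                        par$excursion[["sd"]]))
    spec[idx, "duration_ms"] <- pmax(15, rnorm(length(idx),
                                               par$duration_ms[["mean"]],
                                               par$duration_ms[["sd"]]))
    spec[idx, "amplitude_db"] <- rnorm(length(idx), par$amplitude_db[["mean"]],
                                       par$amplitude_db[["sd"]])
  }
  spec
}

# Keep each call's [f_low, f_high] strictly inside its category's
# generation band; shifts/shrinks drawn onsets and excursions as needed.
confine_to_band <- function(spec, category, shape) {
  lims <- vapply(c("USV", "SV", "squeak", "ranging"), category_freq_limits,
                 numeric(2))
  # tiny interior margin so round-off cannot push a call across a band edge
  lo <- lims[1L, category] + 1e-6
  hi <- lims[2L, category] - 1e-6
  exc <- pmin(spec[, "excursion"], hi - lo)
  neg <- shape == "simple_negative"
  spec[, "f_onset"] <- ifelse(neg,
    pmin(pmax(spec[, "f_onset"], lo + exc), hi),
    pmin(pmax(spec[, "f_onset"], lo), hi - exc))
  spec[, "excursion"] <- exc
  spec
}

#' Generate a synthetic cohort
#'
#' Draws the behavior-battery table and the ground-truth call events for a
#' cohort of `n_per_genotype` WT and AS mice, fully reproducibly from
#' `config$seed`. Per-mouse call counts are negative-binomial (Poisson when
#' dispersion is 0); categories, spectral parameters, complexity and slope
#' signs follow the per-genotype configuration; battery measures are
#' unit-variance Gaussians with the configured genotype shift subtracted for
#' AS mice. Within a mouse, call onsets are spaced at least 50 ms apart
#' (one vocal tract: calls do not overlap).
#'
#' @param config A `usv_generator_config` from [generator_config()].
#' @param include_contours If `TRUE` (default) each event carries a sampled
#'   frequency contour; set `FALSE` for count-level studies where contours
#'   would dominate runtime.
#' @return List with `battery` (data.frame: `mouse_id`, `genotype`, one
#'   column per battery measure) and `events` (data.frame of ground-truth
#'   events: `event_id`, `mouse_id`, `genotype`, `dyad` (courtship pairs
#'   WT*k* with AS*k*; each dyad is a separate recording), `mic` (left/right),
#'   `channel` (near/both), `t_start`, `t_end`, `duration_ms`, `category`,
#'   `shape`, `true_inflections`, `true_slope_sign`, `f_low`, `f_high`,
#'   `amplitude_db`, and a `contour` list-column when requested).
#' @export
generate_cohort <- function(config, include_contours = TRUE) {
  stopifnot(inherits(config, "usv_generator_config"))
  with_seed(config$seed, {
    n <- config$n_per_genotype
    genotypes <- rep(c("WT", "AS"), each = n)
    mouse_id <- sprintf("%s%02d", genotypes, c(seq_len(n), seq_len(n)))

    battery <- data.frame(mouse_id = mouse_id, genotype = genotypes,
                          stringsAsFactors = FALSE)
    for (m in names(config$battery_effects)) {
      shift <- ifelse(genotypes == "AS", -config$battery_effects[[m]], 0)
      battery[[m]] <- rnorm(2L * n) + shift
    }

    cats <- CATEGORIES[[config$test_type]]
    rows <- list()
    for (i in seq_along(mouse_id)) {
      g <- genotypes[i]
      n_calls <- draw_call_counts(1L, config$call_rate_mean[[g]],
                                  config$call_rate_dispersion)
      if (n_calls == 0L) next
      category <- sample(cats, n_calls, replace = TRUE,
                         prob = config$category_mix[[g]][cats])
      is_usv <- category == "USV"
      complex_call <- is_usv & rbinom(n_calls, 1L, config$complexity_prob[[g]]) == 1L
      n_infl <- ifelse(complex_call, 1L + rpois(n_calls, 0.8), 0L)
      up <- rbinom(n_calls, 1L, config$slope_sign_prob[[g]]) == 1L
      shape <- ifelse(complex_call, "complex",
                      ifelse(up, "simple_positive", "simple_negative"))

      spec <- draw_spectral_block(category, config$spectral_params[[g]])
      # ranging calls must span audible and ultrasonic ranges
      ranging <- category == "ranging"
      if (any(ranging)) {
        spec[ranging, "f_onset"] <- pmin(spec[ranging, "f_onset"], 18)
        spec[ranging, "excursion"] <- pmax(spec[ranging, "excursion"],
                                           32 - spec[ranging, "f_onset"])
        shape[ranging & !complex_call] <- "simple_positive"
        up[ranging] <- TRUE
      }
      spec <- confine_to_band(spec, category, shape)

      # onsets: uniform then pushed apart so calls never overlap in a mouse
      dur_s <- spec[, "duration_ms"] / 1000
      onset <- sort(runif(n_calls, 0, max(config$session_s - max(dur_s), 1e-3)))
      if (n_calls > 1L) {
        for (k in 2:n_calls) {
          onset[k] <- max(onset[k], onset[k - 1L] + dur_s[k - 1L] + 0.05)
        }
      }

      bleed <- config$test_type == "courtship" &
        rbinom(n_calls, 1L, config$mic_model$bleed_prob) == 1L
      f_low <- ifelse(shape == "simple_negative",
                      spec[, "f_onset"] - spec[, "excursion"], spec[, "f_onset"])
      f_high <- ifelse(shape == "simple_negative", spec[, "f_onset"],
                       spec[, "f_onset"] + spec[, "excursion"])
      f_high[shape == "flat"] <- spec[shape == "flat", "f_onset"]

      mouse_events <- data.frame(
        event_id = sprintf("%s_e%04d", mouse_id[i], seq_len(n_calls)),
        mouse_id = mouse_id[i], genotype = g,
        dyad = ((i - 1L) %% n) + 1L,
        mic = if (config$test_type == "courtship" && g == "AS") "right" else "left",
        channel = ifelse(bleed, "both", "near"),
        t_start = onset, t_end = onset + dur_s,
        duration_ms = spec[, "duration_ms"],
        category = category, shape = shape,
        true_inflections = n_infl,
        true_slope_sign = ifelse(shape == "complex", "0", ifelse(up, "+", "-")),
        f_low = f_low, f_high = f_high,
        amplitude_db = spec[, "amplitude_db"],
        stringsAsFactors = FALSE
      )
      if (include_contours) {
        mouse_events$contour <- lapply(seq_len(n_calls), function(k) {
          ct <- synthesize_contour(shape[k], spec[k, "f_onset"],
                                   spec[k, "excursion"], spec[k, "duration_ms"],
                                   n_inflections = n_infl[k],
                                   frame_step_ms = config$frame_step_ms,
                                   amplitude_db = spec[k, "amplitude_db"])
          ct$time <- ct$time + onset[k]
          ct
        })
      }
      rows[[length(rows) + 1L]] <- mouse_events
    }

    events <- if (length(rows)) do.call(rbind, rows) else {
      ev <- data.frame(event_id = character(), mouse_id = character(),
                       genotype = character(), dyad = integer(),
                       mic = character(),
                       channel = character(), t_start = numeric(),
                       t_end = numeric(), duration_ms = numeric(),
                       category = character(), shape = character(),
                       true_inflections = integer(),
                       true_slope_sign = character(), f_low = numeric(),
                       f_high = numeric(), amplitude_db = numeric(),
                       stringsAsFactors = FALSE)
      if (include_contours) ev$contour <- list()
      ev
    }
    rownames(events) <- NULL
    list(battery = battery, events = events)
  })
}

#' Render a two-channel audio pair from ground-truth events
#'
#' Each event becomes a frequency-modulated tone following its contour at
#' constant amplitude, added to Gaussian noise at the configured noise
#' floor. Events are placed on their own (near) microphone channel; events
#' with `channel = "both"` additionally appear on the far channel attenuated
#' by `mic_model$attenuation_db`. Output is quantized to 16-bit precision at
#' 250 kHz.
#'
#' @param events Events data.frame from [generate_cohort()] (contours
#'   required). Pass the events of a single recording — one courtship dyad
#'   (`events$dyad`) or one distress mouse — since each dyad/mouse is a
#'   separate recording session.
#' @param config The `usv_generator_config` used to generate the events.
#' @param fs Sampling rate, Hz. Default 250000.
#' @return List of two `usv_waveform` objects, `left` and `right`.
#' @export
render_audio_pair <- function(events, config, fs = 250000) {
  stopifnot(inherits(config, "usv_generator_config"))
  if (nrow(events) > 0 && is.null(events$contour)) {
    stop("events must carry contours (generate_cohort(include_contours = TRUE))",
         call. = FALSE)
  }
  if (nrow(events) > 0) {
    fmax <- max(vapply(events$contour, function(ct) max(ct$freq), numeric(1)))
    if (fmax >= fs / 2000) {
      stop(sprintf("contour frequency %.1f kHz is at or above Nyquist (%.1f kHz)",
                   fmax, fs / 2000), call. = FALSE)
    }
  }
  with_seed(config$seed + 104729L, {
    n_samp <- as.integer(round(config$session_s * fs))
    noise_amp <- 10^(config$noise_floor_db / 20)
    chan <- list(left = rnorm(n_samp, 0, noise_amp),
                 right = rnorm(n_samp, 0, noise_amp))
    atten <- 10^(-config$mic_model$attenuation_db / 20)

    for (k in seq_len(nrow(events))) {
      ct <- events$contour[[k]]
      i0 <- max(1L, as.integer(round(ct$time[1] * fs)) + 1L)
      i1 <- min(n_samp, as.integer(round(ct$time[nrow(ct)] * fs)))
      if (i1 <= i0) next
      tt <- (seq.int(i0, i1) - 1) / fs
      f_hz <- approx(ct$time, ct$freq * 1000, xout = tt, rule = 2)$y
      phase <- 2 * pi * cumsum(f_hz) / fs
      amp <- 10^(events$amplitude_db[k] / 20)
      tone <- amp * sin(phase)
      near <- events$mic[k]
      far <- if (near == "left") "right" else "left"
      chan[[near]][i0:i1] <- chan[[near]][i0:i1] + tone
      if (events$channel[k] == "both") {
        chan[[far]][i0:i1] <- chan[[far]][i0:i1] + tone * atten
      }
    }

    quantize <- function(x) {
      structure(list(samples = pmax(-1, pmin(32767 / 32768,
                                             round(x * 32768) / 32768)),
                     fs = fs, bits = 16L), class = "usv_waveform")
    }
    list(left = quantize(chan$left), right = quantize(chan$right))
  })
}

# Solve for the AS negative-binomial mean giving a target standardized
# genotype effect: (mu_wt - mu_as) / sqrt((var_wt + var_as) / 2) = effect.
nb_mean_for_effect <- function(mu_wt, dispersion, effect) {
  nb_var <- function(mu) mu * (1 + dispersion * mu)
  f <- function(mu_as) {
    (mu_wt - mu_as) / sqrt((nb_var(mu_wt) + nb_var(mu_as)) / 2) - effect
  }
  if (f(1e-9) < 0) {
    stop("effect_sd too large for the configured WT count mean", call. = FALSE)
  }
  uniroot(f, c(1e-9, mu_wt), tol = 1e-10)$root
}

#' Simulate a cohort table for severity analysis
#'
#' Draws a mice-by-measures table with genotype labels, matching the three
#' measure sets used in the severity analysis (see [measure_set()]).
#' Battery measures are unit-variance Gaussians shifted down by `effect_sd`
#' SD in AS mice. Call-count measures are negative-binomial with the WT mean
#' taken from the generator's per-category defaults and the AS mean
#' calibrated so the standardized genotype effect equals `effect_sd`.
#'
#' @param n_per_genotype Mice per genotype. Default 13.
#' @param measure_set `"battery7"`, `"battery_distress9"`, or
#'   `"battery_usv12"`. Default `"battery7"`.
#' @param effect_sd Genotype effect per measure in pooled-SD units. Default 2.
#' @param dispersion Negative-binomial dispersion for count measures.
#'   Default 0.1.
#' @param seed Integer seed.
#' @return A cohort data.frame: `mouse_id`, `genotype`, measure columns.
#' @export
simulate_severity_cohort <- function(n_per_genotype = 13,
                                     measure_set = "battery7",
                                     effect_sd = 2, dispersion = 0.1,
                                     seed = 1) {
  measures <- measure_set(measure_set)
  wt_count_means <- c(distress_usv = 56, distress_squeak = 31,
                      distress_ranging = 38, courtship_usv = 644,
                      courtship_sv = 56)
  with_seed(seed, {
    n <- as.integer(n_per_genotype)
    genotypes <- rep(c("WT", "AS"), each = n)
    out <- data.frame(mouse_id = sprintf("%s%02d", genotypes,
                                         c(seq_len(n), seq_len(n))),
                      genotype = genotypes, stringsAsFactors = FALSE)
    for (m in measures) {
      if (m %in% names(wt_count_means)) {
        mu_wt <- wt_count_means[[m]]
        mu_as <- if (effect_sd > 0) {
          nb_mean_for_effect(mu_wt, dispersion, effect_sd)
        } else mu_wt
        mu <- ifelse(genotypes == "AS", mu_as, mu_wt)
        out[[m]] <- if (dispersion == 0) rpois(2L * n, mu) else {
          rnbinom(2L * n, size = 1 / dispersion, mu = mu)
        }
      } else {
        shift <- ifelse(genotypes == "AS", -effect_sd, 0)
        out[[m]] <- rnorm(2L * n) + shift
      }
    }
    out
  })
}
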