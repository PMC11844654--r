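# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately written as plain enumerations/loops, not via the
# package's own code paths.

# Count interior extrema of a sampled trajectory by scanning its first
# differences with an explicit loop; zero differences inherit the previous
# nonzero sign.
oracle_count_extrema <- function(freq) {
  d <- diff(freq)
  last <- 0
  count <- 0L
  for (i in seq_along(d)) {
    s <- sign(d[i])
    if (s == 0) next
    if (last != 0 && s != last) count <- count + 1L
    last <- s
  }
  count
}

# Two-sided Fisher p for a 2x2 table by full hypergeometric enumeration,
# with probabilities computed from binomial coefficients (lchoose), summing
# all tables whose probability does not exceed the observed one.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  ks <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, ks) + lchoose(r2, c1 - ks) - lchoose(n, c1)
  probs <- exp(logp)
  p_obs <- probs[ks == a]
  total <- 0
  for (i in seq_along(ks)) {
    if (probs[i] <= p_obs * (1 + 1e-7)) total <- total + probs[i]
  }
  min(1, total)
}

# Pooled-variance two-sample t statistic from the textbook formula.
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = na + nb - 2, p = 2 * pt(-abs(t), na + nb - 2))
}

# A minimal annotated call row with a linear-ramp contour.
make_call <- function(mouse_id = "WT01", t_start = 1, duration_ms = 50,
                      f0 = 60, f1 = 80, mag = -25, channel = "single",
                      genotype = "WT") {
  tt <- seq(0, duration_ms / 1000, by = 0.002)
  contour <- data.frame(time = t_start + tt,
                        freq = f0 + (f1 - f0) * tt / max(tt),
                        mag = mag)
  calls <- data.frame(call_id = paste0(mouse_id, "_", round(1000 * t_start)),
                      mouse_id = mouse_id, genotype = genotype,
                      channel = channel, t_start = t_start,
                      t_end = t_start + duration_ms / 1000,
                      peak_db = mag, stringsAsFactors = FALSE)
  calls$contour <- list(contour)
  calls
}

# Small, fast generator configuration for audio-level tests: one courtship
# dyad, short session.
dyad_config <- function(seed, session_s = 20, rate_wt = 12, rate_as = 6,
                        bleed = 0.02) {
  generator_config("courtship", n_per_genotype = 1,
                   call_rate_mean = c(WT = rate_wt, AS = rate_as),
                   session_s = session_s,
                   mic_model = list(attenuation_db = 15, bleed_prob = bleed),
                   seed = seed)
}

# Ground-truth call lists per physical channel (near calls plus bleed
# copies from the opposite microphone).
channel_truth <- function(events, mic) {
  other <- if (mic == "left") "right" else "left"
  events[events$mic == mic | (events$mic == other & events$channel == "both"), ,
         drop = FALSE]
}
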