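---
title: "Methods: vocalization quantification and behavioral severity scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vocalization quantification and behavioral severity scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usvseverity)
```

This vignette documents the models, parameter choices, numerical
conventions, and known limitations of the pipeline. The package analyzes
mouse vocalizations recorded during courtship (social) and tail-suspension
distress (nonsocial) testing in the *Ube3a*-deficient Angelman-syndrome
model, and summarizes overall behavioral performance as a severity score
in principal component space.

## The synthetic cohort generator

No public recordings accompany this kind of study, so the generator is a
first-class, tested component: it defines the conditions under which every
claim about the pipeline is verified.

**Cohort structure.** The default cohort is 13 WT + 13 AS mice, the
longitudinal-cohort size typical of this battery. Per-mouse call counts
are negative binomial with mean $\mu$ per genotype and dispersion $\phi$
($\mathrm{var} = \mu(1 + \phi\mu)$; $\phi = 0$ degrades to Poisson).
The negative binomial is used because per-mouse call counts are strongly
overdispersed across animals. Defaults: courtship 700 (WT) vs 93 (AS)
calls per 20-min session — echoing per-genotype totals of roughly 9100 vs
1200 calls over 13 mice each — and distress 125 vs 31 calls per 60-s
session, with $\phi = 0.1$.

**Categories and spectra.** Each call draws a category from the
genotype's mix (courtship: USV/SV; distress: USV/squeak/ranging), then
onset frequency, excursion, duration, and amplitude from per-genotype,
per-category Gaussians. The published group contrasts fix the *direction*
of the defaults — AS mice: lower USV mean frequency, smaller excursion,
flatter slopes, fewer inflections, relatively more audible calls — but no
distributions are printed anywhere, so the numeric values are package
choices, loosely anchored to the reported group means and fully
configurable via `generator_config()`. Where figure legends and the
results text disagree on the direction of the USV mean-frequency effect,
the results text (AS lower) is followed.

**Contour shapes.** Simple calls are monotone linear ramps (positive or
negative slope per the genotype's `slope_sign_prob`); complex calls are
raised-cosine trajectories
$f(t) = f_0 + \tfrac{E}{2}\,(1 - \cos(\pi (m + 1) t / T))$ with exactly
$m$ interior extrema, so the ground-truth inflection count is exact by
construction. Calls are confined strictly inside their category's band
(with a 1e-6 kHz interior margin so rounding cannot push a call across a
band edge), amplitude is constant within a call, and no harmonics are
rendered — this keeps the detector's ground truth unambiguous. Contours
are sampled every 2 ms. Within a mouse, onsets are spaced at least 50 ms
apart: one vocal tract, no overlapping self-calls.

**Audio.** `render_audio_pair()` renders each call as a
frequency-modulated tone (phase = cumulative trapezoid of the contour)
over Gaussian noise at the −60 dB (re full scale, RMS) microphone noise
floor, quantized to 16-bit at 250 kHz. Courtship uses two microphones
(one per chamber); a call bleeds onto the far channel with probability
0.02, attenuated by 15 dB. The bleed probability is calibrated so that
under defaults fewer than 3% of retained USVs can originate from the far
microphone — a generator-calibration choice mirroring the reported
bleed-through rate, not a biological claim. Each courtship dyad (one WT +
one AS mouse) is a separate recording; the generator's `dyad` column
groups them.

**What the generator does *not* emulate:** mouse movement relative to the
microphone, reverberation, directional gain, harmonics and nonlinear call
elements ("noisy" calls), jitter within a call's amplitude, overlapping
calls from a single mouse, and background transients. Passing tests
therefore demonstrate correctness of the *computations* under controlled
conditions, not detector robustness to all real-world recording
artifacts.

## Detection

The spectrogram uses a 512-sample Hann window with 50% hop at 250 kHz
(2.048 ms window, ~0.49 kHz bin spacing, ~1 ms frame step) — fine enough
in frequency to resolve 5 kHz squeaks and in time to track fast USV
sweeps. Magnitudes are dB re full scale: a full-scale sine peaks near
0 dB, so rendered amplitudes read out directly. Frame times are window
centers; intervals are half-open `[t_start, t_end)` in seconds from file
start.

A call is a maximal run of frames whose in-band peak exceeds the per-bin
median magnitude by `threshold_db`; sub-threshold gaps up to `max_gap_ms`
are bridged; runs shorter than `min_duration_ms` are dropped. Defaults:
threshold 15 dB, band 5–125 kHz, minimum duration 10 ms, gap 5 ms. The
per-bin median over the file is a robust noise reference when calls are
sparse, and makes detection invariant to global gain. The 15 dB threshold
is set so that, with ~200 in-band bins and Rayleigh-distributed noise
magnitudes, the chance of a noise frame crossing threshold is negligible
(~1e-7 per frame), while synthetic calls sit ≥ 25 dB above the floor.

The contour is the per-frame in-band argmax with its magnitude — no
Viterbi smoothing; smoothing happens later, before inflection counting.
Onsets/offsets are quantized to the frame grid and smeared by up to half
a window, so boundary accuracy is asserted to half a window plus one hop
(~2 ms), the resolution the STFT actually affords.

## Call-level analysis

**Taxonomy.** Courtship: USV if the call's `[f_min, f_max]` lies within
25–130 kHz, SV if within 5–15 kHz, otherwise flagged `boundary`
(retained in total counts, excluded from USV/SV statistics — none are
expected, but the pipeline must stay deterministic if they occur).
Distress: `ranging` takes precedence when a call spans both ranges
(f_min below 20 kHz and f_max above 25 kHz) because it is *defined* as
spanning both; otherwise USV, otherwise squeak. Band edges are
configurable in `band_scheme()`; the implementation follows the methods
definitions (USV floor 25 kHz, ranging 5–130 kHz) where other passages
print variant edges.

**Complexity.** An inflection point is an interior extremum of the
frequency trajectory: a sign change of the first difference after
moving-average smoothing. Zero differences inherit the previous nonzero
sign, so plateaus are not extrema. A USV is *simple* iff it has zero
inflection points. The smoothing half-width default of 2 frames (~4 ms)
suppresses single-bin argmax jitter which would otherwise inflate counts
on detected contours; for exactly sampled synthetic trajectories use 0.

**Slope.** Signed least-squares fit of frequency on time over the whole
contour. The estimator is not prescribed anywhere, so the fit is the
package's choice; an endpoints-only chord slope is available
(`method = "endpoints"`) for sensitivity checks. Slopes within ±1e-6
kHz/s count as zero — a symmetric arch is neither positive- nor
negative-sloped. The +/− ratio is implemented as the *count* ratio
$n_+ / n_-$ over simple USVs (missing when $n_- = 0$); whether the ratio
is of counts or of mean slopes is ambiguous in prose, so the mean-slope
ratio is available as an option (`ratio = "mean_slope"`).

**Spectral properties.** Mean frequency is the average of the call's
lowest and highest frequency points; range is their difference; duration
the call's length in ms. The printed power formula is ambiguous; power is
implemented as $10\log_{10}\sum |X|^2$ over the call's contour support
(dB, relative), under which doubling the waveform amplitude raises power
by 6.02 dB — the property the tests verify.

**Deduplication.** Left/right pairs within 0.2 s whose resampled contours
correlate ≥ 0.6 *and* whose mean frequencies agree within 5 kHz are one
physical call; the louder copy (greater peak magnitude) is retained.
The frequency gate is a deliberate addition to the correlation criterion:
any two monotone sweeps correlate near 1 regardless of their bands, so
correlation alone merges coincident but distinct calls; requiring
frequency agreement reproduces the manual judgment of "same spectral
properties" while staying reproducible. Flat contours have no defined
correlation and are matched on mean frequency alone. Deduplication can
still merge two truly coincident same-band calls (observed roughly once
per ~50 calls at the default densities in the stage-2 analysis script);
that residual is inherent to any similarity criterion.

## Cohort statistics

Call properties are averaged mouse-by-mouse; category proportions are
pooled per call within genotype — not averaged across mice — so a mouse
making one or two calls is not over-weighted. Mice with zero calls of a
category contribute a count of 0 and *missing* (not zero) spectral means,
and missing per-mouse values are dropped listwise per comparison, which
is why group sizes can differ across tests.

The t-test is the classical pooled-variance Student test
(df $= n_1 + n_2 - 2$, matching the reported df pattern, e.g. t(24) for
13 + 13 mice), not Welch. Zero pooled variance with equal means returns
t = 0, p = 1. The Fisher exact p is two-sided by probability ordering
(sum of hypergeometric probabilities ≤ the observed table's, with a
1e-7 relative tie tolerance) — the dominant convention, stated here
because alternatives exist; it is implemented directly on the
hypergeometric pmf and cross-checked in the tests both against
`stats::fisher.test` and against full enumeration of every 2×2 table with
margins up to 30.

## Severity analysis

Measures are z-scored with the *whole-cohort* mean and sample SD. The
printed formula says "group means", read here as the full sample:
standardizing within genotype would erase exactly the effect being
measured. Zero-variance measures are dropped with a warning. PCA is
`prcomp` on the z-table; explained variances sum to 100% and
reconstruction from all PCs is exact to 1e-9, which the tests assert.
PC1 is oriented so the WT centroid is negative — a display convention
only; accuracies and distances are sign-invariant.

k-means uses k = 2 on the first two PCs (the centroid-distance
validation is explicitly two-dimensional), 50 restarts with the lowest
within-cluster sum of squares winning, under a fixed seed; `n_pcs` is
configurable. Genotype accuracy takes the better of the two
cluster-to-genotype mappings, so it is ≥ 0.5 by construction. Centroids
are per-genotype means of (PC1, PC2) computed from *actual genotypes*,
never from cluster labels.

Three named measure sets mirror the three severity models:

```{r measure-sets}
measure_set("battery7")
measure_set("battery_distress9")
measure_set("battery_usv12")
```

The source description of the 9-measure model is internally inconsistent
(it says "six measures as above" plus three distress counts, while the
battery list has seven entries). `battery_distress9` therefore uses the
first six battery measures — dropping nest building day 5, the
last-listed measure — plus the three distress counts, so the total
matches the stated nine; any other reading is runnable by passing an
explicit measure vector to `severity_analysis()`.

For count measures in `simulate_severity_cohort()`, the AS
negative-binomial mean is calibrated by root-finding so the standardized
genotype effect equals the requested `effect_sd` exactly, rather than
inheriting whatever effect the default rates imply.

## Problem sizes and numerical conventions

The test suite and acceptance script run everything at desk scale, chosen
as the smallest sizes at which each property is identifiable: severity
accuracy over 20 seeded cohorts of 26 mice; type-I error over 1000
simulated null cohorts at $\alpha = 0.05$ (expected band 5% ± 1.5%);
rate recovery over 50 seeded cohorts (tolerance 5%, pooled mixes inside
the binomial 99% CI); detector fidelity on one rendered 40-s dyad at
~45 calls (recall and precision ≥ 0.95); Fisher agreement over all
164,176 tables with margins ≤ 30 (exact to 1e-12); centroid-distance
agreement on 100 random configurations (1e-12). Audio is rendered at the
full 250 kHz so the STFT path is exercised at protocol resolution.

Other conventions: units are fixed at seconds / kHz / ms / dB; intervals
half-open; WAV I/O is mono 16-bit PCM (or 32-bit float on read) with
samples scaled to $[-1, 1)$ by 32768; the dB floor is −200 dB;
probability vectors must sum to 1 within 1e-9; all randomness flows from
explicit integer seeds and the generator restores the caller's RNG state.

## Limitations

- The detector is a transparent threshold detector, not a learned one;
  its parameters have no published counterpart to copy, and it is
  validated only on synthetic audio.
- Ground-truth complexity and slope labels are exact by construction;
  real calls have graded, noisy contours where the smoothing half-width
  matters more than it does here.
- Repeated-measures and two-way ANOVA post hoc analyses of the original
  battery are out of scope; the package implements the bespoke pipeline
  (taxonomies, dedup, severity scoring), not routine omnibus tests.
- Accuracy and centroid-distance figures computed on synthetic cohorts
  depend on the configured effect sizes (2 SD per measure by default) and
  should not be read as predictions for any particular real cohort.
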