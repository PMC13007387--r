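---
title: "Methods: exercise-fNIRS oxygenation-decline analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exercise-fNIRS oxygenation-decline analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxydrift)
```

## The measurement problem

Continuous-wave fNIRS tracks relative changes of oxygenated (HbO~2~) and
deoxygenated (HHb) hemoglobin under the optodes. During constant-load
exercise slightly above the first ventilatory threshold, prefrontal HbO~2~
typically rises, plateaus, and then declines some time before volitional
exhaustion. Two scalar summaries of that trajectory carry the scientific
questions:

* the **decline point** `D`, the moment the ROI-averaged HbO~2~ curve stops
  rising, expressed as a percentage of the supra-threshold phase so that
  participants with different endurance are comparable; and
* the **activation slope** `beta`, the average rate of oxygenation increase
  from phase onset up to `D`.

Both are latency measures on a slow (< 0.1 Hz) trend buried under cardiac
(1.7–4 Hz), respiratory (0.2–0.7 Hz) and Mayer-band (~0.1 Hz) oscillations,
broadband measurement noise, motion artifacts, and extracerebral systemic
physiology. The pipeline is therefore: channel quality control, artifact
and nuisance removal, trend summarization, then cohort inference.

## Quality gates

**Cardiac-peak validation.** A channel that sees the scalp must carry the
heart beat. The Welch power-spectral density (Hann taper, 60-s segments, 50%
overlap — resolution 1/60 Hz = 1 bpm) of the raw HbO~2~ series is searched
for its maximal peak in the 100–250 bpm band (inclusive); the channel fails
when no peak stands out or when the detected rate disagrees with the
reference heart-rate monitor by more than 10 bpm. "No peak" needs an
explicit criterion: the band argmax must exceed 3 times the median in-band
power (`prominence_min`, configurable). With white noise the band maximum
stays well below that multiple at these averaging depths, while a genuine
cardiac component at the default amplitudes exceeds it by orders of
magnitude, so the gate is insensitive to the exact value. The reference
value is the mean of the supplied heart-rate series over the analyzed phase.

**Scalp-coupling index.** Both raw wavelength intensities (805/830 nm) are
band-passed to the cardiac band (2.5–4 Hz, 3rd-order Butterworth applied
forward–backward) and correlated within non-overlapping 5-s windows after
per-window standardization. Good optode contact gives SCI near 1. A channel
fails when SCI < 0.7 in at least 10% of windows — the boundary is inclusive
(exactly 10% already fails). Windows with zero variance get SCI 0 and a
degenerate flag. Non-overlapping windows were chosen since overlap only
correlates adjacent window decisions without changing the fraction estimate
materially. When an export carries no raw intensities the SCI stage is
skipped with a warning rather than failing the session.

**Headset shift.** With one motion-capture marker on the temple (M0) and two
on the headset (M1, M2), the per-frame quantity `s(t) = (M1−M0)·(M2−M0)`
(dot product of the edge vectors) is averaged over a 30-s window at the
session start and one just before exhaustion; the session fails when the
percent variation between the two means exceeds 15%. The dot product is the
printed definition of the published metric; a true triangle-area variant
(half cross-product norm) is available via `method = "area"`. For a radial
displacement of the headset markers by factor `alpha` both variants scale by
exactly `alpha^2`, giving the closed form `(alpha^2 − 1)·100` used in the
tests. A zero baseline mean (orthogonal edge vectors) makes the percent
variation undefined and raises an error.

## Preprocessing

The stage order is fixed: wavelet motion correction, then lowpass, then
systemic regression.

**Wavelet motion correction.** Multi-level periodized Daubechies-4
decomposition; within each detail level, coefficients outside
`[Q1 − 0.5·IQR, Q3 + 0.5·IQR]` are zeroed before reconstruction. Motion
spikes and baseline jumps load a few large detail coefficients and are
suppressed (spike peaks by more than 90% in the test conditions); smooth
hemodynamics live mostly in the approximation band and pass through. The
0.5 multiplier is deliberately aggressive (1.5 is the generic outlier
convention) and is exposed in the configuration. Three numerical choices
matter:

* *Boundary handling.* The endpoint-connecting line is removed, the series
  is extended to a dyadic length by odd (point-symmetric) reflection with a
  linear correction that closes the periodic wrap, and the extension is
  discarded afterwards. This keeps both the value and the slope continuous
  across the periodization seam; naive even reflection leaves a derivative
  kink whose broadband coefficients get fenced, visibly distorting the
  first/last minute of the record.
* *Coarse-level guard.* Levels with fewer than 64 coefficients are left
  untouched — quartiles of a handful of numbers are meaningless and fencing
  them removes genuine slow content.
* *Known limitation.* Oscillations falling exactly on a dyadic band edge
  (e.g. ~0.078 Hz at 10 Hz sampling) split across two detail levels with
  strongly modulated coefficient envelopes, and the aggressive fence can
  attenuate them by tens of percent. This is intrinsic to decimated-wavelet
  thresholding at IQR 0.5; content away from band edges (such as the 0.05 Hz
  probe used in the tests) is preserved to better than 5% RMS.

**Lowpass.** 4th-order Butterworth at 0.1 Hz applied forward–backward
(zero phase), with odd-reflection padding of three filter time constants at
each end so the IIR transient falls outside the data. Zero-phase filtering
matters because `D` and `beta` are latency measures; the test suite checks
that the peak of a slow Gaussian bump moves by at most one sample. The
cutoff removes cardiac and respiratory oscillations completely and part of
the Mayer band.

**Systemic regression.** Scalp and skin hemodynamics contaminate fNIRS
channels with systemic physiology that also drives the finger
photoplethysmogram (PPG). The PPG trace (native 128 Hz) is linearly
interpolated onto the fNIRS time grid, lowpassed with the same filter so
both series share a bandwidth, and regressed out of each channel by OLS; the
residual is returned with the channel mean restored, and the pre-regression
Pearson correlation is reported per channel (its median across channels is
the conventional cohort summary). A constant (degenerate) regressor leaves
the channel untouched and flags `r` as undefined. Regression runs after the
lowpass because the shared physiology of interest here is the slow
component; the pulse-rate component is already gone at that point.

Residual-artifact inspection is automated: the per-channel count of samples
beyond 5 robust SDs (MAD-based) of the cleaned series is emitted as
provenance instead of a manual visual check.

## Oxygenation metrics

**Decline point.** A polynomial of degree 3 (default) is least-squares
fitted to the ROI-mean HRF on normalized time `u ∈ [0, 1]` and its maximum
located on a 1001-point grid (0.1% resolution), ties breaking toward the
earliest time; `D = 100·u*`. A maximum on the right edge means the curve
never turns down inside the phase; it is flagged monotonic and reported as
`D = 100`, mirroring how monotonic mean curves are reported in practice.
Degree 3 is the lowest degree able to represent a single arch with an
asymmetric interior maximum. The choice was originally degree 5, but the
variance of a quintic at the interval boundary is large enough that, at
signal-to-noise ratio 3, late declines (peak at 90% of the phase, where the
post-peak drop is ~1% of the trend range) were misclassified as monotonic in
about 40% of synthetic runs; the cubic eliminates that failure mode while
remaining unbiased for arch-shaped trends (degree is configurable 2–9 and
logged with every fit). Grid argmax is used instead of root-finding on the
derivative because it is robust to repeated extrema and exactly
reproducible.

**Activation slope.** OLS slope of the HRF against time in seconds from
phase onset to `D` (at least 3 samples). Seconds — not samples — keep `beta`
comparable across sampling rates.

**Delta.** Mean over the last 5 s minus mean over the first 5 s of the
phase. The baseline window is the first 5 s of the supra-threshold phase by
default; a pre-warm-up rest window can be supplied instead where a protocol
provides one. This is an interpretation choice: "baseline" is often left
undefined in exercise protocols, and the first seconds of the phase are the
only window guaranteed to exist for every participant.

**Two-segment model.** `y = a + b₁·t + b₂·max(0, t − s)` is exactly
continuous at the breakpoint `s`. The RSS profile over `s` is piecewise
smooth with many local minima, so `s` is chosen on a 100-point grid of
interior candidates — excluding a 5% margin at each end, where the short arm
makes the fit degenerate — and refined by a bounded golden-section search in
the best grid cell. Deterministic, derivative-free, and oracle-testable: an
exact planted kink is recovered to within one grid step with RSS ≈ 0, and
the fitted RSS can never exceed the single-line RSS because the line is
nested in the model.

**Model comparison.** `AIC = n·ln(RSS/n) + 2k`, `BIC` analogous, with `k`
counting mean-function parameters plus one for the noise variance:
polynomial degree + 2, two-segment 5 (the breakpoint counts as a
parameter). The convention matters only for internal consistency; both
models are scored identically. Zero RSS yields a `−Inf` sentinel with a
degeneracy flag rather than a numeric error. Cohort level: paired t tests on
per-trial AIC (and BIC) differences with Cohen's d of the paired difference.

## The synthetic-data generator

Every synthetic channel is built as *trend + cardiac sinusoid + respiratory
sinusoid + Mayer-band component + shared systemic component + white noise +
artifacts*, with HHb as the trend scaled by −1/3 plus its own noise, and raw
intensity traces carrying the cardiac component with channel-specific gain
(so a healthy channel has SCI ≈ 1, and setting `cardiac_amp = 0` produces a
channel that fails both the cardiac and SCI gates). Within a full session
the Mayer-band oscillation travels in the systemic component shared with the
simulated PPG — Mayer waves are arterial-pressure oscillations, which is
precisely what PPG regression is meant to remove — while channel-local noise
is white.

Trend shapes over the supra-threshold phase (normalized time `u`):

* `quadratic_peak` — the parabola `f(u) = s·T·(u − u²/(2p))`, rising with
  initial slope `s` and peaking exactly at `u = p`. A kinked
  two-half-parabola variant was considered and rejected: a derivative
  discontinuity at the peak biases any smooth-polynomial argmax estimator
  (about 5 points at `p = 0.9`), which would conflate estimator bias with
  pipeline error in recovery studies.
* `piecewise_linear` — slope `s_pre` to the kink at `p`, slope `s_post`
  after it; the planted truth for breakpoint-recovery studies, because the
  best two-segment fit to a smooth arch does *not* put its breakpoint at the
  arch maximum (simulation places it 15–30 points early), whereas a planted
  kink is exactly the two-segment model's own construct.
* `monotonic` — a straight line; the case the decline point must flag.

Sessions follow the protocol plan 5-min warm-up, 1-min transition,
configurable supra-threshold phase (default 10 min), 2-min warm-down; the
trend is held at its boundary values outside the phase. The warm-down is not
cosmetic: it keeps the zero-phase filter's boundary away from the phase end,
where edge effects would otherwise bias `D` for late peaks. Amplitude
defaults (cardiac 0.5, respiratory 0.25, systemic weight 1, noise SD 0.5
concentration units against a trend range of ~1.5–2.5) are chosen so that a
default channel passes QC with a raw PSD showing distinct cardiac and
respiratory peaks; the signal-to-noise ratio of a planted trend is defined
as trend range over the phase divided by white-noise SD. Motion artifacts
are 0.5-s spikes of 5 times the trend range (and/or explicit step
artifacts), one per channel by default at a uniformly random location away
from the recording edges.

What the generator does **not** emulate: 1/f optical noise and slow
instrument drift, heterogeneous per-channel coupling gains and partial
pathlength effects, physiologically structured HHb dynamics (HHb here is a
scaled mirror of the trend), respiratory-rate drift toward exhaustion, or
autocorrelated cohort outcomes. Passing recovery tests therefore shows the
chain is correct and well-calibrated under plausible spectral content and
artifact structure — not that real recordings meet these assumptions.

## Inferential layer

For each outcome the pipeline is: z-score screening (|z| > 3.29) with
iterative winsorization — the most extreme value is replaced by the nearest
boundary `mean ± 3.29·SD` recomputed each iteration, clamped so the sample
order is never reversed, until all scores are inside the limit — then
Shapiro–Wilk per condition cell at α = .05; on violation, ordered quantile
normalization (mid-ranks mapped through `qnorm(r/(n+1))`, strictly
rank-preserving, with an interpolated inverse); if a cell still violates
normality the Friedman test is used, otherwise the repeated-measures ANOVA.
All branch decisions are logged. The two α levels are deliberately separate
configuration keys: .05 gates assumption checks, .02 decides hypotheses.

The RM ANOVA is the balanced one-way within-subject F with partial eta
squared; Mauchly's sphericity test (on the orthonormalized contrast
covariance) at .05 gates the Greenhouse–Geisser epsilon correction of the
degrees of freedom (Huynh–Feldt is intentionally not offered); pairwise
paired t tests carry Bonferroni-adjusted p values and Cohen's d of the
paired differences. The implementation is computed directly from the wide
data matrix — the test suite verifies F, p, Mauchly's W and epsilon against
`stats::aov`, `stats::mauchly.test` and `anova.mlm` — because the
calibration studies run it tens of thousands of times. The Friedman
statistic comes from `stats::friedman.test` with Kendall's
`W = chi2 / (n(k−1))`; for tie-free designs with at most 6 blocks and 3
conditions the p value is computed exactly by enumerating all `6^n`
within-block rank assignments (fully tied blocks are reported as `chi2 = 0`,
`W = 0`, `p = 1`).

Equivalence testing uses paired TOST: bounds are given in Cohen's d units
and converted to raw units through the SD of the paired differences; both
one-sided t tests must be significant at α (default .02) to claim
equivalence, and Hedges' g (small-sample-corrected d) is reported.
Monte-Carlo calibration at the cohort's conditions (n = 36, k = 3, bounds
±0.62) puts the type-I error of both omnibus tests inside [0.016, 0.024] at
the nominal .02, the TOST equivalence rate near 88% at a true effect of
zero, and essentially zero at a true effect of twice the bound.

Power planning distinguishes two designs. `required_n_paired` inverts the
exact noncentral-t power of an ordinary paired test (noncentrality `d·√n`,
`n − 1` df) and yields, e.g., n = 30 at d = 0.64 and n = 9 at d = 1.38
(α = .02, 90% power, one-tailed). `required_n_tost` plans a paired
*equivalence* design via the standard normal approximation
`⌈((z₁₋α + z₁₋₍₁₋power₎/₂)/d)²⌉`, yielding n = 36 at bounds ±0.62 — note
this is *not* the noncentral-t answer for an ordinary two-tailed test at the
same d (which is 37); the two planners answer different questions.
`sesoi_small_telescopes` inverts the forward power function at 33% power to
give the smallest effect size an original study could credibly have
detected; it is the exact inverse of the power function (to 1e-6) and
monotone decreasing in the original sample size.

## Problem sizes and determinism

All generators are pure functions of (specification, seed); the package
never disturbs the caller's RNG stream. The validation studies use: 60
full-pipeline recovery runs per metric (20 seeds × peak fractions 0.5, 0.7,
0.9) on 18-minute sessions with four mPFC channels at SNR 3; 10,000-replicate
null calibrations of each omnibus test at n = 36, k = 3; 5,000-replicate
TOST operating-point estimates; and 200-sample transform-contract sweeps.
These sizes keep Monte-Carlo standard errors a few times smaller than the
tolerance bands they are checked against (e.g. SE ≈ 0.0014 on a 0.02
rejection rate versus a ±0.004 band).

## Known limitations

* No SNIRF/HDF5 reader: recordings enter via the long-CSV dialect
  (`time_s, channel_id, hbo2, hhb, intensity_805, intensity_830`) plus a
  channel→ROI sidecar table; phase annotations via `phase,onset_s` CSV.
* No optical-density→concentration conversion, optode-geometry solving,
  short-separation-channel modeling, or automatic repair of failed channels.
* The wavelet stage can attenuate oscillations at dyadic band edges (above).
* The decline point of a genuinely monotonic or extremely late-peaking curve
  is a boundary decision; `D` near 100 should be interpreted together with
  the monotonic flag and, where the distinction matters, the two-segment
  breakpoint.
* The exact-enumeration Friedman p value is limited to n ≤ 6, k = 3; larger
  designs use the asymptotic chi-squared approximation, whose .02-level
  calibration was verified at n = 36 but not for very small n with ties.
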