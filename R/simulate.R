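#' Slow hemodynamic trend specification
#'
#' Shapes available for the planted oxygenation trend, parametrized over the
#' analyzed phase on normalized time `u` in `[0, 1]`:
#' * `quadratic_peak` — the single parabola
#'   `f(u) = slope_pre * T * (u - u^2 / (2 p))`, rising with initial slope
#'   `slope_pre` (units/s) and attaining its maximum exactly at
#'   `u = peak_fraction`; `slope_post` is unused.
#' * `piecewise_linear` — slope `slope_pre` up to the kink at
#'   `peak_fraction`, slope `slope_post` after it.
#' * `monotonic` — a straight line of slope `slope_pre`
#'   (`peak_fraction` is forced to 1).
#'
#' @param kind Trend shape.
#' @param peak_fraction Location of the maximum as a fraction of the phase,
#'   in `(0, 1]`.
#' @param slope_pre,slope_post Slopes in concentration units per second.
#' @return Object of class `oxy_trend`.
#' @export
trend_spec <- function(kind = c("quadratic_peak", "piecewise_linear", "monotonic"),
                       peak_fraction = 0.7, slope_pre = 0.01,
                       slope_post = -0.01) {
  kind <- match.arg(kind)
  if (kind == "monotonic") peak_fraction <- 1
  stopifnot(peak_fraction > 0, peak_fraction <= 1)
  structure(list(kind = kind, peak_fraction = peak_fraction,
                 slope_pre = slope_pre, slope_post = slope_post),
            class = "oxy_trend")
}

# Trend evaluated at times t (s); the shape spans `window` = c(t0, t1) and is
# held at its boundary values outside it (baseline before the phase, plateau
# through the warm-down).
trend_series <- function(trend, t, window) {
  Tph <- diff(window)
  u <- pmin(pmax((t - window[1]) / Tph, 0), 1)
  p <- trend$peak_fraction
  s <- trend$slope_pre
  switch(trend$kind,
    quadratic_peak = s * Tph * (u - u^2 / (2 * p)),
    piecewise_linear = ifelse(u <= p, s * Tph * u,
                              s * Tph * p + trend$slope_post * Tph * (u - p)),
    monotonic = s * Tph * u)
}

#' Single-channel signal specification
#'
#' Everything needed to synthesize one fNIRS channel: the physiological
#' oscillations seen in raw spectra (cardiac, respiratory, Mayer band), a
#' slow planted trend, white measurement noise, motion artifacts, and the
#' weight of a shared extracerebral systemic component.
#'
#' @param duration Seconds.
#' @param fs Sampling rate, Hz.
#' @param hr_bpm Cardiac rate, beats per minute (100-250 during exercise).
#' @param rr_per_min Respiratory rate, breaths per minute.
#' @param cardiac_amp,resp_amp,mayer_amp Oscillation amplitudes
#'   (concentration units). `mayer_amp` scales the channel-local Mayer-band
#'   component; in full recordings the Mayer band mostly travels in the
#'   shared systemic component instead.
#' @param mayer_freq Mayer-wave frequency, Hz (~0.1).
#' @param trend A [trend_spec()].
#' @param noise_sd White-noise SD.
#' @param artifacts List of `list(time=, amplitude=, kind=)` with kind
#'   `"spike"` (0.5-s burst) or `"step"` (baseline shift).
#' @param systemic_amp Weight of the shared systemic component.
#' @param seed Integer seed; generation is a pure function of (spec, seed).
#' @return Object of class `oxy_sigspec`.
#' @export
signal_spec <- function(duration = 960, fs = 10, hr_bpm = 150,
                        rr_per_min = 24, cardiac_amp = 0.5, resp_amp = 0.25,
                        mayer_amp = 0.1, mayer_freq = 0.095,
                        trend = trend_spec(), noise_sd = 0.5,
                        artifacts = list(), systemic_amp = 1, seed = 1) {
  stopifnot(duration > 0, fs > 0,
            cardiac_amp >= 0, resp_amp >= 0, mayer_amp >= 0, noise_sd >= 0)
  for (rate_hz in c(hr_bpm / 60, rr_per_min / 60, mayer_freq))
    if (rate_hz >= fs / 2)
      stop_oxy("oxydrift_bounds", "component at %.3g Hz >= Nyquist %.3g Hz",
               rate_hz, fs / 2)
  structure(list(duration = duration, fs = fs, hr_bpm = hr_bpm,
                 rr_per_min = rr_per_min, cardiac_amp = cardiac_amp,
                 resp_amp = resp_amp, mayer_amp = mayer_amp,
                 mayer_freq = mayer_freq, trend = trend, noise_sd = noise_sd,
                 artifacts = artifacts, systemic_amp = systemic_amp,
                 seed = seed),
            class = "oxy_sigspec")
}

add_artifacts <- function(x, fs, artifacts) {
  for (a in artifacts) {
    i0 <- floor(a$time * fs) + 1L
    if (i0 > length(x)) next
    if (a$kind == "spike") {
      i1 <- min(length(x), i0 + round(0.5 * fs))
      x[i0:i1] <- x[i0:i1] + a$amplitude
    } else {
      x[i0:length(x)] <- x[i0:length(x)] + a$amplitude
    }
  }
  x
}

#' Generate one synthetic channel
#'
#' The oxygenated-hemoglobin series is the sum of trend, cardiac,
#' respiratory and Mayer sinusoids (random phases), the shared systemic
#' component (when supplied), white noise, and artifacts. Deoxygenated
#' hemoglobin is the trend scaled by `hhb_ratio` (anticorrelated, default
#' -1/3) plus its own noise. The raw intensity traces carry the cardiac
#' component with channel-specific gain plus small independent noise, so
#' the scalp-coupling index of a healthy channel is ~1.
#'
#' @param spec An [signal_spec()].
#' @param channel_id,roi Channel metadata.
#' @param systemic Optional shared systemic series of matching length (its
#'   weight in the channel is `spec$systemic_amp`).
#' @param trend_window `c(t0, t1)` seconds over which the trend shape spans
#'   (default: the whole channel).
#' @param hhb_ratio Scaling of the trend into the HHb series.
#' @return List with `channel` ([oxy_channel()]) and `truth` (list:
#'   `peak_fraction`, `hr_bpm`, `artifact_times`, `trend`, `trend_range`).
#' @export
generate_channel <- function(spec, channel_id = "ch1", roi = "mPFC",
                             systemic = NULL, trend_window = NULL,
                             hhb_ratio = -1/3) {
  stopifnot(inherits(spec, "oxy_sigspec"))
  n <- round(spec$duration * spec$fs)
  t <- (seq_len(n) - 1) / spec$fs
  if (is.null(trend_window)) trend_window <- c(0, spec$duration)
  if (!is.null(systemic) && length(systemic) != n)
    stop_oxy("oxydrift_ragged", "systemic component length %d != %d",
             length(systemic), n)
  with_seed(spec$seed, {
    ph <- runif(4, 0, 2 * pi)
    tr <- trend_series(spec$trend, t, trend_window)
    cardiac <- sin(2 * pi * spec$hr_bpm / 60 * t + ph[1])
    hbo2 <- tr +
      spec$cardiac_amp * cardiac +
      spec$resp_amp * sin(2 * pi * spec$rr_per_min / 60 * t + ph[2]) +
      spec$mayer_amp * sin(2 * pi * spec$mayer_freq * t + ph[3]) +
      (if (is.null(systemic)) 0 else spec$systemic_amp * systemic) +
      rnorm(n, 0, spec$noise_sd)
    hbo2 <- add_artifacts(hbo2, spec$fs, spec$artifacts)
    hhb <- hhb_ratio * tr + rnorm(n, 0, spec$noise_sd / 3)
    gain <- runif(2, 0.8, 1.2)
    int_sd <- 0.02 * max(spec$cardiac_amp, 1e-3)
    i805 <- 1 + gain[1] * spec$cardiac_amp * cardiac + rnorm(n, 0, int_sd)
    i830 <- 1 + gain[2] * spec$cardiac_amp * cardiac + rnorm(n, 0, int_sd)
    ch <- oxy_channel(channel_id, roi, hbo2, hhb, i805, i830)
    list(channel = ch,
         truth = list(peak_fraction = spec$trend$peak_fraction,
                      hr_bpm = spec$hr_bpm,
                      artifact_times = vapply(spec$artifacts, `[[`, numeric(1), "time"),
                      trend = tr,
                      trend_range = diff(range(tr))))
  })
}

#' Generate a full synthetic session
#'
#' Builds a recording whose channels share one planted trend (spanning the
#' supra-threshold exercise phase), one systemic extracerebral component
#' (Mayer-band plus a slower oscillation, also carried by the simulated PPG),
#' and per-channel oscillations, noise and motion spikes. Phase annotations
#' follow the protocol plan: warm-up, transition, exercise 5% above the
#' first ventilatory threshold, warm-down.
#'
#' @param spec An [signal_spec()] used as a template for every channel
#'   (its `duration` is overridden by the phase plan).
#' @param rois Named integer vector: channels per ROI,
#'   e.g. `c(mPFC = 4, occipital = 2)`.
#' @param phase_plan List with `warmup_s`, `transition_s`, `above_vt1_s`,
#'   `warmdown_s`.
#' @param n_spikes Motion spikes per channel (amplitude 5x the trend range,
#'   placed uniformly away from the recording edges).
#' @param ppg_fs PPG sampling rate, Hz.
#' @param seed Integer seed.
#' @return List with `recording`, `annotations`, `ppg`, `truth` (list with
#'   `peak_fraction`, `hr_bpm`, `systemic`, `phase_window`, `trend_range`).
#' @export
generate_recording <- function(spec = signal_spec(),
                               rois = c(mPFC = 4),
                               phase_plan = list(warmup_s = 300,
                                                 transition_s = 60,
                                                 above_vt1_s = 600,
                                                 warmdown_s = 120),
                               n_spikes = 1, ppg_fs = 128, seed = 1) {
  stopifnot(all(rois >= 1))
  dur <- with(phase_plan, warmup_s + transition_s + above_vt1_s + warmdown_s)
  n <- round(dur * spec$fs)
  t <- (seq_len(n) - 1) / spec$fs
  ph0 <- phase_plan$warmup_s + phase_plan$transition_s
  ph1 <- ph0 + phase_plan$above_vt1_s
  with_seed(seed, {
    sysph <- runif(2, 0, 2 * pi)
    systemic <- sin(2 * pi * spec$mayer_freq * t + sysph[1]) +
      0.7 * sin(2 * pi * 0.042 * t + sysph[2])
    tr_probe <- trend_series(spec$trend, t, c(ph0, ph1))
    rng <- diff(range(tr_probe[t >= ph0 & t < ph1]))
    chans <- list()
    k <- 0L
    for (roi in names(rois)) for (j in seq_len(rois[[roi]])) {
      k <- k + 1L
      arts <- if (n_spikes > 0) lapply(seq_len(n_spikes), function(i)
        list(time = runif(1, 60, dur - 60), amplitude = 5 * max(rng, 1),
             kind = "spike")) else list()
      ch_spec <- spec
      ch_spec$duration <- dur
      ch_spec$artifacts <- arts
      # the Mayer band rides in the shared systemic component here (it is a
      # systemic blood-pressure oscillation); no extra channel-local copy
      ch_spec$mayer_amp <- 0
      ch_spec$seed <- spec$seed + 1000L * k
      gc <- generate_channel(ch_spec, channel_id = sprintf("%s_%02d", roi, j),
                             roi = roi, systemic = systemic,
                             trend_window = c(ph0, ph1))
      chans[[k]] <- gc$channel
    }
    rec <- oxy_recording(chans, spec$fs, session_id = "synthetic",
                         condition_label = "sim")
    ann <- oxy_phases(warmup_start = 0,
                      transition_start = phase_plan$warmup_s,
                      above_vt1_start = ph0, exhaustion_time = ph1,
                      warmdown_start = ph1)
    tp <- seq(0, dur - 1 / ppg_fs, by = 1 / ppg_fs)
    sys_p <- approx(t, systemic, xout = tp, rule = 2)$y
    ppg <- oxy_ppg(sys_p + 0.5 * sin(2 * pi * spec$hr_bpm / 60 * tp) +
                     rnorm(length(tp), 0, 0.05),
                   sample_rate = ppg_fs, t0_offset = 0)
    list(recording = rec, annotations = ann, ppg = ppg,
         truth = list(peak_fraction = spec$trend$peak_fraction,
                      hr_bpm = spec$hr_bpm, systemic = systemic,
                      phase_window = c(ph0, ph1), trend_range = rng))
  })
}

#' Generate a three-marker motion-capture trajectory
#'
#' A static triangle (temple marker plus two headset markers, coordinates in
#' mm); from `shift_time` on, the headset markers are displaced radially from
#' the temple marker by factor `alpha`, which scales the edge-vector dot
#' product by exactly `alpha^2`.
#'
#' @param duration Seconds.
#' @param fs Frame rate, Hz.
#' @param alpha Radial scale factor after the shift (1 = no shift).
#' @param shift_time Time of the shift, seconds.
#' @param jitter_sd Optional white positional jitter, mm.
#' @param seed Seed for the jitter.
#' @return Data frame with columns `time`, `x0..z0`, `x1..z1`, `x2..z2`.
#' @export
generate_markers <- function(duration = 960, fs = 10, alpha = 1,
                             shift_time = duration / 2, jitter_sd = 0,
                             seed = 1) {
  stopifnot(alpha > 0)
  tt <- seq(0, duration - 1 / fs, by = 1 / fs)
  m0 <- c(0, 0, 0)
  m1 <- c(80, 10, 5)
  m2 <- c(20, 90, 10)
  n <- length(tt)
  sc <- ifelse(tt >= shift_time, alpha, 1)
  df <- data.frame(time = tt,
                   x0 = m0[1], y0 = m0[2], z0 = m0[3],
                   x1 = m0[1] + sc * (m1[1] - m0[1]),
                   y1 = m0[2] + sc * (m1[2] - m0[2]),
                   z1 = m0[3] + sc * (m1[3] - m0[3]),
                   x2 = m0[1] + sc * (m2[1] - m0[1]),
                   y2 = m0[2] + sc * (m2[2] - m0[2]),
                   z2 = m0[3] + sc * (m2[3] - m0[3]))
  if (jitter_sd > 0)
    df[-1] <- with_seed(seed, df[-1] + rnorm(9 * n, 0, jitter_sd))
  df
}

#' Cohort outcome specification and generator
#'
#' Balanced complete within-subject design:
#' `y[i, j] = subject intercept + effect_d[j] * residual_sd + residual`.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param conditions Condition labels.
#' @param effect_d Standardized mean shift per condition (Cohen's d units,
#'   recycled to the number of conditions).
#' @param subject_sd SD of the random subject intercepts.
#' @param residual_sd Residual SD.
#' @param seed Integer seed.
#' @return `cohort_spec` returns a spec object; `generate_cohort` a long
#'   data frame (`participant`, `condition`, `value`).
#' @export
cohort_spec <- function(n_subjects = 36, conditions = c("music", "audiobook", "silence"),
                        effect_d = 0, subject_sd = 1, residual_sd = 1,
                        seed = 1) {
  stopifnot(n_subjects >= 2, all(is.finite(effect_d)))
  effect_d <- rep_len(effect_d, length(conditions))
  structure(list(n_subjects = n_subjects, conditions = conditions,
                 effect_d = effect_d, subject_sd = subject_sd,
                 residual_sd = residual_sd, seed = seed),
            class = "oxy_cohortspec")
}

#' @param spec A `cohort_spec`.
#' @rdname cohort_spec
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "oxy_cohortspec"))
  with_seed(spec$seed, {
    k <- length(spec$conditions)
    subj <- rnorm(spec$n_subjects, 0, spec$subject_sd)
    df <- expand.grid(participant = seq_len(spec$n_subjects),
                      condition = spec$conditions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    df$value <- subj[df$participant] +
      spec$effect_d[match(df$condition, spec$conditions)] * spec$residual_sd +
      rnorm(nrow(df), 0, spec$residual_sd)
    df
  })
}
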