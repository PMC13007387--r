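#' Cardiac-peak quality gate
#'
#' A channel passes when a cardiac peak was found in its spectrum and the
#' detected rate agrees with an independent heart-rate reference (chest-strap
#' monitor) within `tol` bpm.
#'
#' @param detected Detected rate in bpm, or `NA` when no peak was found.
#' @param reference Reference heart rate in bpm (>0).
#' @param tol Tolerance in bpm (default 10).
#' @return List with `pass` and `reason` (`NA`, `"no_cardiac_peak"` or
#'   `"hr_mismatch"`).
#' @export
cardiac_qc <- function(detected, reference, tol = 10) {
  stopifnot(reference > 0, tol >= 0)
  if (is.na(detected))
    return(list(pass = FALSE, reason = "no_cardiac_peak"))
  if (abs(detected - reference) <= tol)
    list(pass = TRUE, reason = NA_character_)
  else
    list(pass = FALSE, reason = "hr_mismatch")
}

#' Scalp-coupling index per window
#'
#' Windowed correlation between the cardiac-band content of the two raw
#' wavelength intensities: both traces are band-passed (default 2.5-4 Hz),
#' then per non-overlapping window (default 5 s) zero-meaned, scaled to unit
#' variance, and correlated. High values indicate that both wavelengths see
#' the same cardiac pulsation, i.e. good optode-scalp contact.
#'
#' @param intensity_805,intensity_830 Raw intensity traces, equal length.
#' @param fs Sampling rate, Hz.
#' @param band Cardiac band in Hz.
#' @param window_s Window length in seconds.
#' @return Numeric vector of per-window SCI values in `[-1, 1]`; windows with
#'   zero variance get SCI 0 and are marked in the `degenerate` attribute.
#' @export
scalp_coupling_index <- function(intensity_805, intensity_830, fs,
                                 band = c(2.5, 4), window_s = 5) {
  if (length(intensity_805) != length(intensity_830))
    stop_oxy("oxydrift_ragged", "intensity traces differ in length")
  L <- round(window_s * fs)
  n <- length(intensity_805)
  if (L >= n)
    stop_oxy("oxydrift_short", "window (%d samples) not shorter than trace (%d)",
             L, n)
  bf <- signal::butter(3, band / (fs / 2), type = "pass")
  b805 <- filtfilt_padded(bf, intensity_805, round(5 * fs / band[1]))
  b830 <- filtfilt_padded(bf, intensity_830, round(5 * fs / band[1]))
  nw <- floor(n / L)
  sci <- numeric(nw)
  degen <- logical(nw)
  for (k in seq_len(nw)) {
    idx <- ((k - 1L) * L + 1L):(k * L)
    a <- b805[idx]; b <- b830[idx]
    if (sd(a) == 0 || sd(b) == 0) {
      sci[k] <- 0; degen[k] <- TRUE
    } else {
      sci[k] <- cor(a, b)
    }
  }
  attr(sci, "degenerate") <- degen
  sci
}

#' Screen a channel on its per-window SCI values
#'
#' Fails when SCI falls below `threshold` in at least `max_low_fraction` of
#' the windows (boundary inclusive: exactly 10% of low windows already
#' fails).
#'
#' @param sci Per-window SCI values.
#' @param threshold SCI threshold (default 0.7).
#' @param max_low_fraction Maximal tolerated fraction of low windows
#'   (default 0.10).
#' @return List with `pass`, `fraction_low`.
#' @export
sci_screen <- function(sci, threshold = 0.7, max_low_fraction = 0.10) {
  if (length(sci) < 1) stop_oxy("oxydrift_short", "no SCI windows")
  frac <- mean(sci < threshold)
  list(pass = frac < max_low_fraction, fraction_low = frac)
}

#' Headset-shift metric from three motion-capture markers
#'
#' Per frame the dot product of the two edge vectors from the temple marker
#' to the two headset markers is computed; that quantity is averaged over a
#' window at the start of the session and a window just before exhaustion,
#' and the percent variation between the two means is reported. A variation
#' above `threshold` (default 15%) flags a headset shift. `method = "area"`
#' uses half the cross-product norm (the actual triangle area) instead of
#' the dot product.
#'
#' @param frames Data frame with columns `time`, `x0,y0,z0` (temple marker),
#'   `x1,y1,z1`, `x2,y2,z2` (headset markers), coordinates in mm.
#' @param w1,w2 Two-element vectors `c(start, end)` in seconds (half-open
#'   windows); defaults: first 30 s and the final 30 s of the trajectory.
#' @param threshold Percent variation that flags a shift.
#' @param method `"dot"` (edge-vector dot product) or `"area"`.
#' @return List with `variation_pct`, `pass`, `s_w1`, `s_w2`.
#' @export
headset_shift_variation <- function(frames, w1 = NULL, w2 = NULL,
                                    threshold = 15, method = c("dot", "area")) {
  method <- match.arg(method)
  tmax <- max(frames$time)
  if (is.null(w1)) w1 <- c(0, 30)
  if (is.null(w2)) w2 <- c(tmax - 30, tmax + 1e-9)
  e1 <- cbind(frames$x1 - frames$x0, frames$y1 - frames$y0, frames$z1 - frames$z0)
  e2 <- cbind(frames$x2 - frames$x0, frames$y2 - frames$y0, frames$z2 - frames$z0)
  s <- if (method == "dot") {
    rowSums(e1 * e2)
  } else {
    cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    0.5 * sqrt(rowSums(cr^2))
  }
  in1 <- frames$time >= w1[1] & frames$time < w1[2]
  in2 <- frames$time >= w2[1] & frames$time < w2[2]
  if (!any(in1) || !any(in2))
    stop_oxy("oxydrift_short", "empty marker window")
  s1 <- mean(s[in1]); s2 <- mean(s[in2])
  if (s1 == 0)
    stop_oxy("oxydrift_degenerate", "baseline-window metric is zero")
  variation <- abs(s2 - s1) / abs(s1) * 100
  list(variation_pct = variation, pass = variation <= threshold,
       s_w1 = s1, s_w2 = s2)
}

#' Run all channel quality gates on a recording
#'
#' Applies, per channel and on the analyzed phase: (1) Welch-PSD cardiac-peak
#' detection on the oxygenated-hemoglobin series, compared against the
#' reference heart rate when supplied; (2) scalp-coupling-index screening on
#' the raw intensities (skipped with a flag for concentration-only exports);
#' and, per session, (3) the marker-based headset-shift metric.
#'
#' @param rec An [oxy_recording()].
#' @param ann Optional [oxy_phases()]; when given, QC runs on the
#'   `above_vt1` phase (the segment of interest), otherwise on the whole
#'   recording.
#' @param reference_hr Optional reference heart-rate series (bpm); its mean
#'   over the analyzed phase is the comparison value. A scalar is used as-is.
#' @param markers Optional marker data frame (see
#'   [headset_shift_variation()]).
#' @param hr_tol Heart-rate tolerance, bpm.
#' @param sci_threshold,sci_max_low_fraction SCI screening parameters.
#' @param band_bpm,prominence_min Cardiac-peak search parameters.
#' @param segment_s Welch segment length, seconds.
#' @return An object of class `oxy_qc`: data frame `channels`
#'   (channel_id, roi, detected_bpm, cardiac_pass, sci_fraction_low,
#'   sci_pass, pass, reasons), `headset` (or `NULL`), `excluded_fraction`.
#' @export
qc_recording <- function(rec, ann = NULL, reference_hr = NULL, markers = NULL,
                         hr_tol = 10, sci_threshold = 0.7,
                         sci_max_low_fraction = 0.10,
                         band_bpm = c(100, 250), prominence_min = 3,
                         segment_s = 60) {
  seg <- if (is.null(ann)) rec else extract_phase(rec, ann, "above_vt1")
  fs <- seg$sample_rate
  ref <- if (is.null(reference_hr)) NULL else mean(reference_hr)
  rows <- lapply(seg$channels, function(ch) {
    psd <- welch_psd(ch$hbo2, fs, segment_s = min(segment_s, seg$duration / 2))
    est <- estimate_cardiac_frequency(psd, band_bpm, prominence_min)
    reasons <- character(0)
    if (is.null(ref)) {
      cpass <- est$found
      if (!cpass) reasons <- c(reasons, "no_cardiac_peak")
    } else {
      cq <- cardiac_qc(est$bpm, ref, hr_tol)
      cpass <- cq$pass
      if (!cpass) reasons <- c(reasons, cq$reason)
    }
    if (is.null(ch$intensity_805) || is.null(ch$intensity_830)) {
      warning(sprintf("channel %s: no raw intensities, SCI screen skipped",
                      ch$channel_id), call. = FALSE)
      spass <- TRUE; sfrac <- NA_real_
    } else {
      sci <- scalp_coupling_index(ch$intensity_805, ch$intensity_830, fs,
                                  window_s = 5)
      scr <- sci_screen(sci, sci_threshold, sci_max_low_fraction)
      spass <- scr$pass; sfrac <- scr$fraction_low
      if (!spass) reasons <- c(reasons, "sci_low")
    }
    data.frame(channel_id = ch$channel_id, roi = ch$roi,
               detected_bpm = est$bpm, cardiac_pass = cpass,
               sci_fraction_low = sfrac, sci_pass = spass,
               pass = cpass && spass,
               reasons = paste(reasons, collapse = ";"))
  })
  chans <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  headset <- if (!is.null(markers)) {
    hs <- headset_shift_variation(markers)
    if (!hs$pass) chans$reasons <- paste0(chans$reasons,
      ifelse(nzchar(chans$reasons), ";", ""), "headset_shift")
    hs
  }
  structure(list(channels = chans, headset = headset,
                 excluded_fraction = mean(!chans$pass)),
            class = "oxy_qc")
}

#' @export
print.oxy_qc <- function(x, ...) {
  cat(sprintf("<oxy_qc> %d channels, %.1f%% excluded\n",
              nrow(x$channels), 100 * x$excluded_fraction))
  if (!is.null(x$headset))
    cat(sprintf("  headset variation %.2f%% (%s)\n", x$headset$variation_pct,
                if (x$headset$pass) "pass" else "SHIFT"))
  print(x$channels[, c("channel_id", "roi", "detected_bpm", "pass", "reasons")],
        row.names = FALSE)
  invisible(x)
}
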