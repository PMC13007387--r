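# Forward-backward filtering with odd-reflection padding at both ends so the
# transient of the IIR filter falls on the (discarded) extension, not on the
# data. signal::filtfilt alone leaves visible edge transients at 0.1 Hz.
filtfilt_padded <- function(bf, x, np) {
  n <- length(x)
  np <- max(1L, min(n - 1L, np))
  xp <- c(2 * x[1] - x[(np + 1L):2],
          x,
          2 * x[n] - x[(n - 1L):(n - np)])
  y <- signal::filtfilt(bf, xp)
  y[(np + 1L):(np + n)]
}

#' Zero-phase lowpass filter
#'
#' 4th-order Butterworth applied forward and backward (zero phase shift, so
#' the latency of slow features is preserved — the decline-point metric is
#' latency-sensitive). The default 0.1 Hz cutoff rejects cardiac and
#' respiratory oscillations along with part of the Mayer band.
#'
#' @param x Numeric series.
#' @param fs Sampling rate, Hz.
#' @param cutoff Cutoff frequency, Hz (must be below Nyquist).
#' @param order Butterworth order (effective order doubles with the
#'   forward-backward pass).
#' @return Filtered series, same length.
#' @export
lowpass <- function(x, fs, cutoff = 0.1, order = 4) {
  if (cutoff >= fs / 2)
    stop_oxy("oxydrift_bounds", "cutoff %g Hz >= Nyquist %g Hz", cutoff, fs / 2)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  filtfilt_padded(bf, x, round(3 * fs / cutoff))
}

#' Regress the systemic (PPG) component out of an fNIRS channel
#'
#' The blood-volume-pulse trace is resampled to the fNIRS time grid by linear
#' interpolation, and the channel is regressed on it by ordinary least
#' squares. The residual is returned with the channel mean restored, so the
#' correction removes shared extracerebral fluctuations without shifting the
#' concentration scale. The pre-regression Pearson correlation is reported
#' (the conventional summary of fNIRS-PPG coupling).
#'
#' @param x fNIRS channel series.
#' @param fs fNIRS sampling rate, Hz.
#' @param ppg An [oxy_ppg()] trace overlapping the channel in time.
#' @param lowpass_ppg Lowpass the resampled PPG with the same 0.1 Hz filter
#'   first (default `TRUE`: both series then share a bandwidth, which is how
#'   the correction is applied inside the pipeline after the channel itself
#'   has been lowpassed).
#' @return List with `residual` (corrected series), `r` (Pearson correlation
#'   before regression; `NA` for a degenerate constant regressor) and
#'   `degenerate` flag.
#' @export
regress_systemic <- function(x, fs, ppg, lowpass_ppg = TRUE) {
  stopifnot(inherits(ppg, "oxy_ppg"))
  n <- length(x)
  t_f <- (seq_len(n) - 1) / fs
  t_p <- ppg$t0_offset + (seq_along(ppg$values) - 1) / ppg$sample_rate
  lo <- max(t_f[1], t_p[1])
  hi <- min(t_f[n], t_p[length(t_p)])
  if (hi - lo < 10)
    stop_oxy("oxydrift_short", "fNIRS/PPG overlap %.1f s < 10 s", hi - lo)
  p_rs <- approx(t_p, ppg$values, xout = t_f, rule = 2)$y
  if (lowpass_ppg) p_rs <- lowpass(p_rs, fs)
  if (sd(p_rs) == 0)
    return(list(residual = x, r = NA_real_, degenerate = TRUE))
  r <- cor(x, p_rs)
  fit <- stats::lm.fit(cbind(1, p_rs), x)
  list(residual = unname(fit$residuals) + mean(x), r = r, degenerate = FALSE)
}

#' Median fNIRS-PPG correlation across channels
#'
#' @param rs Numeric vector of per-channel pre-regression correlations.
#' @return Sample median.
#' @export
median_systemic_correlation <- function(rs) {
  if (length(rs) < 1) stop_oxy("oxydrift_short", "no correlations supplied")
  median(rs)
}

#' Preprocess every channel of a recording
#'
#' Fixed pipeline order: wavelet motion correction, zero-phase lowpass,
#' then (optionally) systemic PPG regression — applied to both chromophores.
#' Returns the cleaned recording together with a per-channel provenance
#' table: the pre-regression fNIRS-PPG correlation and the number of residual
#' samples beyond 5 robust SDs of the corrected series (an automated stand-in
#' for visual inspection of leftover motion artifacts).
#'
#' @param rec An [oxy_recording()].
#' @param ppg Optional [oxy_ppg()]; when `NULL` the regression stage is
#'   skipped.
#' @param wavelet_iqr IQR fence multiplier for motion correction.
#' @param lowpass_hz Lowpass cutoff, Hz.
#' @param filter_order Butterworth order.
#' @param ppg_regression Logical switch for the regression stage.
#' @return List with `recording` (cleaned), `provenance` (data frame:
#'   channel_id, chromophore, ppg_r, n_residual_outliers).
#' @export
preprocess_recording <- function(rec, ppg = NULL, wavelet_iqr = 0.5,
                                 lowpass_hz = 0.1, filter_order = 4,
                                 ppg_regression = !is.null(ppg)) {
  fs <- rec$sample_rate
  prov <- list()
  clean1 <- function(x, id, chrom) {
    y <- wavelet_motion_correct(x, iqr_mult = wavelet_iqr)
    y <- lowpass(y, fs, cutoff = lowpass_hz, order = filter_order)
    r <- NA_real_
    if (ppg_regression && !is.null(ppg)) {
      rg <- regress_systemic(y, fs, ppg)
      y <- rg$residual
      r <- rg$r
    }
    dev <- abs(y - median(y)) / (stats::mad(y) + .Machine$double.eps)
    prov[[length(prov) + 1L]] <<- data.frame(
      channel_id = id, chromophore = chrom, ppg_r = r,
      n_residual_outliers = sum(dev > 5))
    y
  }
  chans <- lapply(rec$channels, function(ch) {
    hbo2 <- clean1(ch$hbo2, ch$channel_id, "hbo2")
    hhb <- clean1(ch$hhb, ch$channel_id, "hhb")
    oxy_channel(ch$channel_id, ch$roi, hbo2, hhb,
                ch$intensity_805, ch$intensity_830,
                ch$source_id, ch$detector_id)
  })
  list(recording = oxy_recording(chans, fs, rec$session_id, rec$condition_label),
       provenance = do.call(rbind, c(prov, list(make.row.names = FALSE))))
}
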