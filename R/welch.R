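#' Welch power-spectral density estimate
#'
#' Mean of modified periodograms over Hann-tapered, overlapping segments;
#' one-sided density. Each segment has its mean removed before tapering so
#' that slow drifts do not swamp the cardiac band. Defaults (60-s segments,
#' 50% overlap) give a frequency resolution of 1/60 Hz = 1 bpm, matching the
#' 10-bpm heart-rate tolerance used downstream.
#'
#' @param x Numeric time series.
#' @param fs Sampling rate, Hz.
#' @param segment_s Segment length in seconds.
#' @param overlap Fractional overlap between consecutive segments, in `[0,1)`.
#' @return List with `freq` (Hz) and `power` (one-sided PSD, unit^2/Hz),
#'   class `oxy_psd`.
#' @export
welch_psd <- function(x, fs, segment_s = 60, overlap = 0.5) {
  stopifnot(fs > 0, segment_s > 0, overlap >= 0, overlap < 1)
  L <- round(segment_s * fs)
  if (length(x) < 2 * L)
    stop_oxy("oxydrift_short",
             "signal too short for Welch PSD: need >= %d samples (2 segments), got %d",
             2 * L, length(x))
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, length(x) - L + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))   # Hann
  scale <- fs * sum(w^2)
  nf <- floor(L / 2) + 1L
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + L - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(fft(seg))^2 / scale
    p <- p[seq_len(nf)]
    # one-sided: double everything except DC (and Nyquist when L even)
    dbl <- 2:(nf - if (L %% 2 == 0) 1L else 0L)
    p[dbl] <- 2 * p[dbl]
    acc <- acc + p
  }
  structure(list(freq = (seq_len(nf) - 1L) * fs / L,
                 power = acc / length(starts)),
            class = "oxy_psd")
}

#' Estimate the cardiac frequency from a PSD
#'
#' Finds the maximal spectral peak inside a heart-rate band (inclusive
#' boundaries, default 100-250 bpm) and converts it to beats per minute. A
#' peak counts as "found" only when its power exceeds `prominence_min` times
#' the median in-band power; otherwise the series is judged to carry no
#' cardiac signature (channel-rejection criterion).
#'
#' @param psd A PSD from [welch_psd()].
#' @param band_bpm Search band in bpm, inclusive.
#' @param prominence_min Peak power / median in-band power required to accept
#'   the peak.
#' @return List with `bpm` (or `NA` when not found), `prominence`, `found`.
#' @export
estimate_cardiac_frequency <- function(psd, band_bpm = c(100, 250),
                                       prominence_min = 3) {
  f_band <- band_bpm / 60
  if (f_band[2] > max(psd$freq) + 1e-12)
    stop_oxy("oxydrift_bounds",
             "band upper edge %.3g Hz outside PSD support (max %.3g Hz)",
             f_band[2], max(psd$freq))
  inb <- psd$freq >= f_band[1] - 1e-12 & psd$freq <= f_band[2] + 1e-12
  pw <- psd$power[inb]
  fq <- psd$freq[inb]
  i <- which.max(pw)
  med <- median(pw)
  prom <- if (med > 0) pw[i] / med else Inf
  found <- is.finite(prom) && prom >= prominence_min && pw[i] > 0
  list(bpm = if (found) fq[i] * 60 else NA_real_,
       prominence = prom, found = found)
}
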