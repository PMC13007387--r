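#' ROI-mean hemodynamic response function
#'
#' Pointwise mean across the surviving channels of one region of interest.
#'
#' @param channels Non-empty list of [oxy_channel()] objects (e.g. from
#'   [roi_channels()]).
#' @param chromophore `"hbo2"` (default) or `"hhb"`.
#' @return Numeric series.
#' @export
roi_hrf <- function(channels, chromophore = c("hbo2", "hhb")) {
  chromophore <- match.arg(chromophore)
  if (length(channels) == 0L)
    stop_oxy("oxydrift_roi_empty", "no channels supplied")
  rowMeans(vapply(channels, `[[`, numeric(length(channels[[1]][[chromophore]])),
                  chromophore))
}

#' Oxygenation decline point D
#'
#' A polynomial of the configured degree is least-squares fitted to the HRF
#' on normalized time `u` in `[0, 1]` (u = elapsed fraction of the analyzed
#' phase). D is the location of the fitted maximum, found on a dense grid
#' (1001 points, i.e. 0.1% resolution) and expressed as a percentage of the
#' phase. Ties break toward the earliest time. When the maximum sits at the
#' right edge (u = 1) the curve never turns down inside the phase and is
#' flagged monotonic with D = 100.
#'
#' @param hrf Numeric HRF covering exactly the analyzed phase.
#' @param degree Polynomial degree (>= 2; default 3, the lowest degree that
#'   can represent a single arch with an asymmetric interior maximum —
#'   higher degrees inflate the fit's variance at the phase boundaries and
#'   misclassify late declines as monotonic).
#' @param grid_n Number of grid points for the argmax search.
#' @return List with `d_pct`, `monotonic`, and `fit` (degree, coefficients on
#'   the orthogonal basis, `rss`, `n`, `k` = number of mean parameters + 1
#'   for the noise variance).
#' @export
decline_point <- function(hrf, degree = 3, grid_n = 1001) {
  stopifnot(degree >= 2)
  n <- length(hrf)
  if (n < degree + 2)
    stop_oxy("oxydrift_short", "need more than degree+1 = %d samples, got %d",
             degree + 1, n)
  u <- seq(0, 1, length.out = n)
  fit <- lm(hrf ~ stats::poly(u, degree))
  ug <- seq(0, 1, length.out = grid_n)
  yg <- predict(fit, newdata = data.frame(u = ug))
  i <- which.max(yg)                      # which.max takes the earliest tie
  monotonic <- (i == grid_n)
  list(d_pct = 100 * ug[i], monotonic = monotonic,
       fit = list(degree = degree, coefficients = coef(fit),
                  rss = sum(resid(fit)^2), n = n, k = degree + 2L))
}

#' Activation slope beta
#'
#' OLS slope (concentration units per second) of the HRF against time from
#' the start of the phase up to the decline point D.
#'
#' @param hrf Numeric HRF covering the phase.
#' @param fs Sampling rate, Hz.
#' @param d_pct Decline point as percent of the phase (> 0).
#' @return Slope (units per second).
#' @export
activation_slope <- function(hrf, fs, d_pct) {
  stopifnot(d_pct > 0)
  n_seg <- ceiling(length(hrf) * d_pct / 100)
  if (n_seg < 3)
    stop_oxy("oxydrift_short", "segment up to D has %d < 3 samples", n_seg)
  t <- (seq_len(n_seg) - 1) / fs
  y <- hrf[seq_len(n_seg)]
  unname(coef(lm(y ~ t))[2])
}

#' Baseline-to-end delta of the HRF
#'
#' Mean over the last `window_s` seconds of the phase minus mean over the
#' first `window_s` seconds.
#'
#' @param hrf Numeric HRF covering the phase.
#' @param fs Sampling rate, Hz.
#' @param window_s Averaging window, seconds (default 5).
#' @return Delta in concentration units.
#' @export
delta_value <- function(hrf, fs, window_s = 5) {
  L <- round(window_s * fs)
  if (length(hrf) < 2 * L)
    stop_oxy("oxydrift_short", "phase shorter than two %g-s windows", window_s)
  mean(hrf[(length(hrf) - L + 1L):length(hrf)]) - mean(hrf[seq_len(L)])
}

#' Continuous two-segment linear fit with breakpoint search
#'
#' Fits `y = a + b1 * t + b2 * max(0, t - s)` — two connected straight
#' lines, exactly continuous at the breakpoint `s`. The breakpoint is chosen
#' to minimize the residual sum of squares over a grid of interior
#' candidates (a 5% margin at each end is excluded) and then refined by a
#' golden-section search around the best grid cell.
#'
#' @param hrf Numeric series (>= 10 samples, non-constant).
#' @param fs Sampling rate, Hz.
#' @param margin Excluded fraction at each end of the candidate range.
#' @param n_grid Number of grid candidates.
#' @return List with `breakpoint_s` (seconds from phase start),
#'   `breakpoint_pct`, `slope_pre`, `slope_post`, `intercept`, `rss`, `n`,
#'   `k` (= 5: intercept, two slopes, breakpoint, noise variance).
#' @export
two_segment_fit <- function(hrf, fs, margin = 0.05, n_grid = 100) {
  n <- length(hrf)
  if (n < 10) stop_oxy("oxydrift_short", "need >= 10 samples, got %d", n)
  if (sd(hrf) == 0)
    stop_oxy("oxydrift_degenerate", "constant series: breakpoint undefined")
  t <- (seq_len(n) - 1) / fs
  Tn <- t[n]
  rss_at <- function(s) {
    X <- cbind(1, t, pmax(0, t - s))
    sum(stats::lm.fit(X, hrf)$residuals^2)
  }
  cand <- seq(margin * Tn, (1 - margin) * Tn, length.out = n_grid)
  rs <- vapply(cand, rss_at, numeric(1))
  i <- which.min(rs)
  step <- cand[2] - cand[1]
  lo <- max(margin * Tn, cand[i] - step)
  hi <- min((1 - margin) * Tn, cand[i] + step)
  opt <- optimize(rss_at, c(lo, hi))
  s <- if (opt$objective < rs[i]) opt$minimum else cand[i]
  fit <- stats::lm.fit(cbind(1, t, pmax(0, t - s)), hrf)
  b <- fit$coefficients
  list(breakpoint_s = s, breakpoint_pct = 100 * s / Tn,
       slope_pre = unname(b[2]), slope_post = unname(b[2] + b[3]),
       intercept = unname(b[1]), rss = sum(fit$residuals^2),
       n = n, k = 5L)
}

#' Information-criterion comparison of the polynomial and two-segment fits
#'
#' `AIC = n log(RSS/n) + 2k` and `BIC = n log(RSS/n) + k log(n)`, with `k`
#' counting the mean-function parameters plus one for the noise variance
#' (polynomial: degree + 2; two-segment: 5, the breakpoint included). Lower
#' wins. A zero RSS yields a `-Inf` sentinel with a flag.
#'
#' @param poly_fit `fit` element from [decline_point()].
#' @param seg_fit Result of [two_segment_fit()].
#' @return Data frame with one row per model: `model`, `k`, `rss`, `aic`,
#'   `bic`, `degenerate`.
#' @export
model_compare <- function(poly_fit, seg_fit) {
  stopifnot(poly_fit$n == seg_fit$n)
  ic <- function(rss, n, k) {
    if (rss <= 0) return(c(aic = -Inf, bic = -Inf))
    c(aic = n * log(rss / n) + 2 * k, bic = n * log(rss / n) + k * log(n))
  }
  rows <- list(
    data.frame(model = "polynomial", k = poly_fit$k, rss = poly_fit$rss,
               t(ic(poly_fit$rss, poly_fit$n, poly_fit$k)),
               degenerate = poly_fit$rss <= 0),
    data.frame(model = "two_segment", k = seg_fit$k, rss = seg_fit$rss,
               t(ic(seg_fit$rss, seg_fit$n, seg_fit$k)),
               degenerate = seg_fit$rss <= 0))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Cohort-level paired comparison of per-trial information criteria
#'
#' Paired t-test on per-trial AIC (and BIC) differences between the
#' polynomial and two-segment models, with Cohen's d of the paired
#' difference.
#'
#' @param aic_poly,aic_seg Per-trial AIC values (equal length).
#' @param bic_poly,bic_seg Per-trial BIC values.
#' @return Data frame: criterion, t, df, p, cohens_d, mean_poly, mean_seg.
#' @export
cohort_model_compare <- function(aic_poly, aic_seg, bic_poly, bic_seg) {
  one <- function(a, b, label) {
    d <- a - b
    tt <- t.test(a, b, paired = TRUE)
    data.frame(criterion = label,
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, cohens_d = mean(d) / sd(d),
               mean_poly = mean(a), mean_seg = mean(b))
  }
  rbind(one(aic_poly, aic_seg, "AIC"), one(bic_poly, bic_seg, "BIC"),
        make.row.names = FALSE)
}

#' Full per-recording metric extraction
#'
#' Runs the whole chain on one recording: preprocessing
#' (wavelet motion correction, 0.1-Hz zero-phase lowpass, optional PPG
#' regression), extraction of the supra-threshold exercise phase, ROI-mean
#' HRF, and the oxygenation metrics per ROI and chromophore: decline point
#' D, activation slope beta, delta, the two-segment alternative and both
#' information criteria.
#'
#' @param rec An [oxy_recording()] (raw).
#' @param ann An [oxy_phases()] with the `above_vt1` boundaries.
#' @param ppg Optional [oxy_ppg()].
#' @param qc Optional `oxy_qc` report used to drop failed channels.
#' @param rois ROI labels to analyze (default: the ROIs present).
#' @param chromophores Which chromophores to compute metrics for.
#' @param degree Polynomial degree for the decline point.
#' @param ... Passed to [preprocess_recording()].
#' @return Tidy data frame with one row per ROI x chromophore: `session_id`,
#'   `condition`, `roi`, `chromophore`, `n_channels`, `d_pct`, `monotonic`,
#'   `beta`, `delta`, `breakpoint_pct`, `aic_poly`, `aic_seg`, `bic_poly`,
#'   `bic_seg`.
#' @export
analyze_recording <- function(rec, ann, ppg = NULL, qc = NULL, rois = NULL,
                              chromophores = "hbo2", degree = 3, ...) {
  pp <- preprocess_recording(rec, ppg = ppg, ...)
  seg <- extract_phase(pp$recording, ann, "above_vt1")
  if (is.null(rois))
    rois <- intersect(ROI_LABELS,
                      unique(vapply(seg$channels, `[[`, character(1), "roi")))
  out <- list()
  for (roi in rois) {
    chans <- tryCatch(roi_channels(seg, roi, qc),
                      oxydrift_roi_empty = function(e) NULL)
    if (is.null(chans)) next
    for (chrom in chromophores) {
      hrf <- roi_hrf(chans, chrom)
      dp <- decline_point(hrf, degree = degree)
      beta <- activation_slope(hrf, seg$sample_rate, dp$d_pct)
      delta <- delta_value(hrf, seg$sample_rate)
      seg_fit <- two_segment_fit(hrf, seg$sample_rate)
      mc <- model_compare(dp$fit, seg_fit)
      out[[length(out) + 1L]] <- data.frame(
        session_id = rec$session_id, condition = rec$condition_label,
        roi = roi, chromophore = chrom, n_channels = length(chans),
        d_pct = dp$d_pct, monotonic = dp$monotonic, beta = beta,
        delta = delta, breakpoint_pct = seg_fit$breakpoint_pct,
        aic_poly = mc$aic[1], aic_seg = mc$aic[2],
        bic_poly = mc$bic[1], bic_seg = mc$bic[2])
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
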