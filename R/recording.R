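#' Construct a single fNIRS channel
#'
#' A channel holds the two chromophore concentration series (oxygenated and
#' deoxygenated hemoglobin) and, when exported by the instrument, the raw
#' optical intensity traces at 805 and 830 nm used for scalp-coupling-index
#' screening.
#'
#' @param channel_id Channel identifier (character scalar).
#' @param roi Region of interest, one of `"mPFC"`, `"dlPFC"`, `"lPC"`,
#'   `"occipital"`, `"other"`.
#' @param hbo2,hhb Numeric concentration series (arbitrary concentration
#'   units); must have equal length.
#' @param intensity_805,intensity_830 Optional raw optical intensity traces,
#'   same length as `hbo2`, or `NULL` for concentration-only exports.
#' @param source_id,detector_id Optode identifiers (optional).
#' @return An object of class `oxy_channel`.
#' @export
oxy_channel <- function(channel_id, roi, hbo2, hhb,
                        intensity_805 = NULL, intensity_830 = NULL,
                        source_id = NA_character_, detector_id = NA_character_) {
  stopifnot(is.character(channel_id), length(channel_id) == 1L)
  roi <- as.character(roi)
  if (!roi %in% ROI_LABELS) roi <- "other"
  if (length(hbo2) != length(hhb))
    stop_oxy("oxydrift_ragged", "channel '%s': hbo2 and hhb differ in length",
             channel_id)
  for (nm in c("intensity_805", "intensity_830")) {
    v <- get(nm)
    if (!is.null(v) && length(v) != length(hbo2))
      stop_oxy("oxydrift_ragged", "channel '%s': %s length mismatch",
               channel_id, nm)
  }
  structure(list(channel_id = channel_id, roi = roi,
                 hbo2 = as.numeric(hbo2), hhb = as.numeric(hhb),
                 intensity_805 = if (is.null(intensity_805)) NULL else as.numeric(intensity_805),
                 intensity_830 = if (is.null(intensity_830)) NULL else as.numeric(intensity_830),
                 source_id = source_id, detector_id = detector_id),
            class = "oxy_channel")
}

#' Construct a multi-channel fNIRS recording
#'
#' @param channels List of [oxy_channel()] objects sharing one length.
#' @param sample_rate Sampling rate in Hz (continuous-wave fNIRS default 10).
#' @param session_id,condition_label Free-text metadata.
#' @return An object of class `oxy_recording` with fields `channels`,
#'   `sample_rate`, `n_samples`, `duration` (seconds), `session_id`,
#'   `condition_label`.
#' @export
oxy_recording <- function(channels, sample_rate = 10,
                          session_id = NA_character_,
                          condition_label = NA_character_) {
  stopifnot(is.list(channels), length(channels) >= 1L, sample_rate > 0)
  lens <- vapply(channels, function(ch) length(ch$hbo2), integer(1))
  if (length(unique(lens)) != 1L)
    stop_oxy("oxydrift_ragged", "ragged channels: lengths %s",
             paste(unique(lens), collapse = ", "))
  ids <- vapply(channels, `[[`, character(1), "channel_id")
  if (anyDuplicated(ids))
    stop_oxy("oxydrift_format", "duplicate channel_id: %s",
             paste(ids[duplicated(ids)], collapse = ", "))
  names(channels) <- ids
  structure(list(channels = channels, sample_rate = sample_rate,
                 n_samples = lens[[1]], duration = lens[[1]] / sample_rate,
                 session_id = session_id, condition_label = condition_label),
            class = "oxy_recording")
}

#' @export
print.oxy_recording <- function(x, ...) {
  rois <- table(vapply(x$channels, `[[`, character(1), "roi"))
  cat(sprintf("<oxy_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              length(x$channels), x$n_samples, x$sample_rate, x$duration))
  cat("  ROIs:", paste(sprintf("%s=%d", names(rois), rois), collapse = " "), "\n")
  invisible(x)
}

#' Session phase annotations
#'
#' Timestamps (seconds from the start of the recording) delimiting the
#' protocol phases: warm-up, transition, exercise 5% above the first
#' ventilatory threshold (the analyzed trial), and warm-down. The phase of
#' interest runs from `above_vt1_start` to `exhaustion_time`.
#'
#' @param warmup_start,transition_start,above_vt1_start,exhaustion_time,warmdown_start
#'   Onsets in seconds; any may be `NA` except that analysis phases require
#'   their own boundaries. Present values must be strictly increasing.
#' @return An object of class `oxy_phases`.
#' @export
oxy_phases <- function(warmup_start = NA_real_, transition_start = NA_real_,
                       above_vt1_start = NA_real_, exhaustion_time = NA_real_,
                       warmdown_start = NA_real_) {
  v <- c(warmup_start = warmup_start, transition_start = transition_start,
         above_vt1_start = above_vt1_start, exhaustion_time = exhaustion_time,
         warmdown_start = warmdown_start)
  pres <- v[!is.na(v)]
  if (length(pres) > 1 && any(diff(pres) < 0))
    stop_oxy("oxydrift_phases", "phase onsets must be non-decreasing")
  if (!is.na(above_vt1_start) && !is.na(exhaustion_time) &&
      above_vt1_start >= exhaustion_time)
    stop_oxy("oxydrift_phases", "above_vt1_start must precede exhaustion_time")
  structure(as.list(v), class = "oxy_phases")
}

#' Photoplethysmographic blood-volume-pulse trace
#'
#' @param values Numeric blood-volume-pulse series (finite).
#' @param sample_rate Sampling rate in Hz (default 128).
#' @param t0_offset Time of the first PPG sample relative to the start of the
#'   fNIRS recording, in seconds.
#' @return An object of class `oxy_ppg`.
#' @export
oxy_ppg <- function(values, sample_rate = 128, t0_offset = 0) {
  stopifnot(sample_rate > 0)
  if (!all(is.finite(values)))
    stop_oxy("oxydrift_format", "PPG values must be finite")
  structure(list(values = as.numeric(values), sample_rate = sample_rate,
                 t0_offset = t0_offset), class = "oxy_ppg")
}

phase_window <- function(ann, phase, duration) {
  w <- switch(phase,
    warmup     = c(ann$warmup_start, ann$transition_start),
    transition = c(ann$transition_start, ann$above_vt1_start),
    above_vt1  = c(ann$above_vt1_start, ann$exhaustion_time),
    warmdown   = c(ann$warmdown_start, duration),
    stop_oxy("oxydrift_phases", "unknown phase '%s'", phase))
  if (anyNA(w))
    stop_oxy("oxydrift_phases", "phase '%s' is not annotated", phase)
  w
}

#' Extract one protocol phase as a new recording
#'
#' The returned segment covers the half-open window `[start, end)` of the
#' requested phase, aligned to the sample grid by flooring the start and
#' ceiling the end (sample index `floor(t * fs)`), so adjacent phases never
#' share a sample. Channel metadata are preserved.
#'
#' @param rec An [oxy_recording()].
#' @param ann An [oxy_phases()].
#' @param phase One of `"warmup"`, `"transition"`, `"above_vt1"`,
#'   `"warmdown"`.
#' @return An `oxy_recording` restricted to the phase.
#' @export
extract_phase <- function(rec, ann, phase = "above_vt1") {
  stopifnot(inherits(rec, "oxy_recording"), inherits(ann, "oxy_phases"))
  w <- phase_window(ann, phase, rec$duration)
  if (w[1] < 0 || w[2] > rec$duration + 1e-9)
    stop_oxy("oxydrift_bounds", "phase [%g, %g) outside recording [0, %g)",
             w[1], w[2], rec$duration)
  fs <- rec$sample_rate
  i0 <- floor(w[1] * fs) + 1L           # 1-based index of first sample
  i1 <- ceiling(w[2] * fs)              # last sample (half-open upper bound)
  if (i1 < i0)
    stop_oxy("oxydrift_bounds", "empty segment for phase '%s'", phase)
  idx <- i0:i1
  chans <- lapply(rec$channels, function(ch) {
    oxy_channel(ch$channel_id, ch$roi, ch$hbo2[idx], ch$hhb[idx],
                if (!is.null(ch$intensity_805)) ch$intensity_805[idx],
                if (!is.null(ch$intensity_830)) ch$intensity_830[idx],
                ch$source_id, ch$detector_id)
  })
  oxy_recording(chans, fs, rec$session_id, rec$condition_label)
}

#' Channels of one region of interest
#'
#' Returns the channels mapped to `roi`, ordered by channel id, excluding any
#' that a QC report flags as failed. When every channel of the ROI is
#' excluded an error of class `oxydrift_roi_empty` is raised so that the
#' caller can decide (a participant is conventionally retained as long as at
#' least one ROI survives).
#'
#' @param rec An [oxy_recording()].
#' @param roi ROI label.
#' @param qc Optional QC report from [qc_recording()]; `NULL` keeps all.
#' @return List of `oxy_channel` objects.
#' @export
roi_channels <- function(rec, roi, qc = NULL) {
  if (!roi %in% ROI_LABELS)
    stop_oxy("oxydrift_format", "unknown ROI label '%s'", roi)
  keep <- Filter(function(ch) ch$roi == roi, rec$channels)
  keep <- keep[order(vapply(keep, `[[`, character(1), "channel_id"))]
  if (!is.null(qc)) {
    failed <- qc$channels$channel_id[!qc$channels$pass]
    keep <- Filter(function(ch) !ch$channel_id %in% failed, keep)
  }
  if (length(keep) == 0L)
    stop_oxy("oxydrift_roi_empty", "ROI '%s' has no surviving channels", roi)
  keep
}
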