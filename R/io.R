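#' Write a recording to long-format CSV
#'
#' One row per (sample, channel): columns `time_s`, `channel_id`, `hbo2`,
#' `hhb`, `intensity_805`, `intensity_830` (intensity columns `NA` for
#' concentration-only channels). UTF-8, "." decimal. The channel-to-ROI map
#' travels in a sidecar table (see [write_channel_map()]).
#'
#' @param rec An [oxy_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_recording <- function(rec, path) {
  stopifnot(inherits(rec, "oxy_recording"))
  t <- (seq_len(rec$n_samples) - 1L) / rec$sample_rate
  rows <- lapply(rec$channels, function(ch) {
    data.frame(time_s = t, channel_id = ch$channel_id,
               hbo2 = ch$hbo2, hhb = ch$hhb,
               intensity_805 = if (is.null(ch$intensity_805)) NA_real_ else ch$intensity_805,
               intensity_830 = if (is.null(ch$intensity_830)) NA_real_ else ch$intensity_830)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a recording from long-format CSV
#'
#' @param path File path.
#' @param channel_map Optional data frame with columns `channel_id`, `roi`;
#'   channels absent from the map get ROI `"other"`.
#' @param sample_rate Sampling rate in Hz; `NULL` infers it from the median
#'   `time_s` step (rejecting mixed rates across channels).
#' @param session_id,condition_label Metadata to attach.
#' @return An [oxy_recording()].
#' @export
load_recording <- function(path, channel_map = NULL, sample_rate = NULL,
                           session_id = NA_character_,
                           condition_label = NA_character_) {
  if (!file.exists(path))
    stop_oxy("oxydrift_format", "file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "channel_id", "hbo2", "hhb")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_oxy("oxydrift_format", "missing column(s): %s",
             paste(miss, collapse = ", "))
  ids <- unique(df$channel_id)
  lens <- vapply(ids, function(id) sum(df$channel_id == id), integer(1))
  if (length(unique(lens)) != 1L)
    stop_oxy("oxydrift_ragged", "ragged channels: lengths %s",
             paste(unique(lens), collapse = ", "))
  if (is.null(sample_rate)) {
    steps <- vapply(ids, function(id) {
      tt <- df$time_s[df$channel_id == id]
      median(diff(sort(tt)))
    }, numeric(1))
    if (diff(range(steps)) > 1e-6 * mean(steps))
      stop_oxy("oxydrift_format", "mixed sample rates across channels")
    sample_rate <- 1 / steps[[1]]
  }
  roi_of <- function(id) {
    if (is.null(channel_map)) return("other")
    m <- match(id, channel_map$channel_id)
    if (is.na(m)) "other" else channel_map$roi[m]
  }
  has_int <- all(c("intensity_805", "intensity_830") %in% names(df))
  chans <- lapply(ids, function(id) {
    sub <- df[df$channel_id == id, ]
    sub <- sub[order(sub$time_s), ]
    i805 <- if (has_int && !anyNA(sub$intensity_805)) sub$intensity_805
    i830 <- if (has_int && !anyNA(sub$intensity_830)) sub$intensity_830
    oxy_channel(as.character(id), roi_of(id), sub$hbo2, sub$hhb, i805, i830)
  })
  oxy_recording(chans, sample_rate, session_id, condition_label)
}

#' Read/write the channel-to-ROI sidecar map
#'
#' @param path CSV path with columns `channel_id`, `roi`.
#' @return Data frame with those columns.
#' @export
read_channel_map <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("channel_id", "roi") %in% names(df)))
    stop_oxy("oxydrift_format", "channel map needs columns channel_id, roi")
  df
}

#' @param map Data frame with columns `channel_id`, `roi`.
#' @rdname read_channel_map
#' @export
write_channel_map <- function(map, path) {
  write.csv(map[c("channel_id", "roi")], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write phase annotations as CSV (`phase,onset_s`)
#'
#' @param path CSV path.
#' @return An [oxy_phases()].
#' @export
load_phases <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("phase", "onset_s") %in% names(df)))
    stop_oxy("oxydrift_format", "phase file needs columns phase, onset_s")
  get1 <- function(p) {
    i <- match(p, df$phase)
    if (is.na(i)) NA_real_ else df$onset_s[i]
  }
  oxy_phases(get1("warmup_start"), get1("transition_start"),
             get1("above_vt1_start"), get1("exhaustion_time"),
             get1("warmdown_start"))
}

#' @param ann An [oxy_phases()].
#' @rdname load_phases
#' @export
save_phases <- function(ann, path) {
  v <- unlist(ann)
  df <- data.frame(phase = names(v), onset_s = as.numeric(v))
  write.csv(df[!is.na(df$onset_s), ], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
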