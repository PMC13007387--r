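# Small deterministic fixtures used across test files.

# Recording with simple analytic channels: channel i of roi r carries
# hbo2 = i * t / duration (a clean ramp), hhb = -hbo2 / 3.
make_ramp_recording <- function(rois = c(mPFC = 2), n = 1000, fs = 10) {
  t <- (seq_len(n) - 1) / fs
  chans <- list()
  i <- 0L
  for (r in names(rois)) for (j in seq_len(rois[[r]])) {
    i <- i + 1L
    chans[[i]] <- oxy_channel(sprintf("%s_%02d", r, j), r,
                              hbo2 = i * t / max(t), hhb = -i * t / (3 * max(t)),
                              intensity_805 = 1 + 0.1 * sin(2 * pi * 3 * t),
                              intensity_830 = 1 + 0.1 * sin(2 * pi * 3 * t))
  }
  oxy_recording(chans, fs)
}

# Minimal QC stub failing the given channel ids.
fake_qc <- function(rec, fail_ids = character(0)) {
  ids <- names(rec$channels)
  structure(list(channels = data.frame(channel_id = ids,
                                       pass = !ids %in% fail_ids),
                 headset = NULL,
                 excluded_fraction = mean(ids %in% fail_ids)),
            class = "oxy_qc")
}

# Wide matrix -> long cohort table.
long_table <- function(Y, conditions = colnames(Y)) {
  if (is.null(conditions)) conditions <- paste0("c", seq_len(ncol(Y)))
  data.frame(participant = rep(seq_len(nrow(Y)), ncol(Y)),
             condition = rep(conditions, each = nrow(Y)),
             value = as.vector(Y))
}
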