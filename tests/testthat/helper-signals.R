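# Shared fixtures, built in code at test time.

# Clean ECG-like beat train: Gaussian-bump QRS templates at given beat times.
make_beat_train <- function(beat_times, fs = 100, dur_s = 60, amp = 1,
                            noise_sd = 0, qrs_sd = 0.01, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- round(dur_s * fs)
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  amp <- rep_len(amp, length(beat_times))
  for (i in seq_along(beat_times)) {
    b <- beat_times[i]
    idx <- which(abs(t - b) < 5 * qrs_sd)
    x[idx] <- x[idx] + amp[i] * exp(-(t[idx] - b)^2 / (2 * qrs_sd^2))
  }
  if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
  x
}

# Filtered epoch ready for the detector.
make_filtered_epoch <- function(beat_times, fs = 100, ...) {
  x <- make_beat_train(beat_times, fs = fs, ...)
  butter_filter(x, fs, filter_spec("bandpass", 3, c(0.05, 40)))
}

# A small cohort feature table with one planted discriminative feature and
# noise features, for selection/evaluation tests that do not need signals.
make_toy_feature_table <- function(n_patients = 5, n_per = 200,
                                   effect = 3, n_noise = 5, seed = 1,
                                   apnea_fraction = 0.35) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_patients), function(p) {
    lab <- ifelse(runif(n_per) < apnea_fraction, "A", "N")
    df <- data.frame(record_id = sprintf("p%02d", p),
                     minute = seq_len(n_per) - 1L, label = lab,
                     stringsAsFactors = FALSE)
    df$planted <- rnorm(n_per) + effect * (lab == "A")
    for (j in seq_len(n_noise)) df[[paste0("noise", j)]] <- rnorm(n_per)
    df
  }))
}
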