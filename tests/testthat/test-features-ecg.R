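test_that("the detector recovers a synthetic 1 Hz beat train", {
  fs <- 100
  truth <- seq(0.5, 59.5, by = 1)
  for (seed in 1:3) {
    ecg <- make_filtered_epoch(truth, fs, noise_sd = 0.05, seed = seed)
    b <- detect_r_peaks(ecg, fs)
    expect_true(b$usable)
    expect_true(abs(length(b$times) - 60) <= 1)
    offs <- vapply(b$times, function(x) min(abs(x - truth)), numeric(1))
    expect_lt(max(offs), 0.05)
    # amplitude scaling does not change the detections
    b10 <- detect_r_peaks(10 * ecg, fs)
    expect_equal(b10$times, b$times)
  }
})

test_that("flat-line and near-empty epochs are flagged unusable", {
  expect_false(detect_r_peaks(rep(0, 6000), 100)$usable)
  one_beat <- make_filtered_epoch(30, 100)
  expect_false(detect_r_peaks(one_beat, 100)$usable)
})

test_that("RR correction replaces non-physiological intervals", {
  expect_equal(as.numeric(correct_rr(rep(1000, 10))), rep(1000, 10))
  out <- correct_rr(c(1000, 1000, 250, 1000))
  expect_equal(as.numeric(out), rep(1000, 4))
  expect_equal(attr(out, "n_replaced"), 1L)
  # postcondition scan: corrected series within the physiological band
  set.seed(8)
  for (i in 1:10) {
    raw <- rnorm(60, 1000, 80)
    raw[sample(60, 5)] <- c(100, 2500, 150, 3000, 90)
    out <- as.numeric(correct_rr(raw))
    expect_true(all(out >= 300 & out <= 2000))
  }
  # fewer than 3 intervals: unchanged, flagged
  short <- correct_rr(c(5000, 100))
  expect_equal(as.numeric(short), c(5000, 100))
  expect_true(attr(short, "flagged"))
})

test_that("EDR is the R-wave area: linear, constant for identical beats", {
  fs <- 100
  truth <- seq(0.5, 59.5, by = 1)
  # contract check on the raw bump train: identical beats, identical areas
  raw <- make_beat_train(truth, fs)
  b0 <- list(times = truth, amps = rep(1, 60))
  edr0 <- derive_edr(raw, b0, fs)
  expect_length(edr0, 60L)
  expect_lt(sd(edr0) / mean(edr0), 1e-4)   # only window-edge tail rounding
  expect_equal(derive_edr(2 * raw, b0, fs), 2 * edr0)
  # full path: detection + the slow high-pass leave only a small wobble
  ecg <- make_filtered_epoch(truth, fs)
  b <- detect_r_peaks(ecg, fs)
  edr <- derive_edr(ecg, b, fs)
  expect_lt(sd(edr[10:50]) / mean(edr[10:50]), 0.02)
  # sinusoidally modulated beat amplitudes -> EDR oscillates at that rate
  amps <- 1 + 0.5 * sin(2 * pi * 0.3 * truth)
  ecg_m <- make_filtered_epoch(truth, fs, amp = amps)
  bm <- detect_r_peaks(ecg_m, fs)
  edr_m <- derive_edr(ecg_m, bm, fs)
  pg <- welch_psd(edr_m - mean(edr_m), fs = 1, nperseg = length(edr_m))
  sel <- pg$freq > 0.05
  expect_equal(pg$freq[sel][which.max(pg$psd[sel])], 0.3, tolerance = 0.05)
})

test_that("time-domain HRV features follow their definitions", {
  fs <- 100
  truth <- cumsum(rep(1, 60)) - 0.5
  ecg <- make_filtered_epoch(truth, fs)
  b <- detect_r_peaks(ecg, fs)
  edr <- derive_edr(ecg, b, fs)
  # constant RR: zero variability counts
  rr_const <- rep(1000, 59)
  f <- ecg_time_features(b, rr_const, ecg, edr)
  expect_equal(unname(f["NN50_RR"]), 0)
  expect_equal(unname(f["SDSD_RR"]), 0)
  expect_equal(unname(f["std_RR"]), 0)
  expect_equal(unname(f["mean_RR"]), 1000)
  # directional NN50: only the 800 -> 860 step exceeds +50 ms
  b4 <- list(times = c(0.1, 0.9, 1.76, 2.66, 3.609),
             amps = rep(1, 5))
  rr4 <- c(800, 860, 900, 949)
  f4 <- ecg_time_features(b4, rr4, ecg, edr[1:5])
  expect_equal(unname(f4["NN50_RR"]), 1)
  expect_equal(unname(f4["SDSD_RR"]), sd(diff(rr4)))
  # RMSSD of R amplitudes, brute force
  expect_equal(unname(f4["RMSSD_R_amp"]),
               sqrt(mean(diff(b4$amps)^2)))
})

test_that("ECG sample kurtosis uses the non-excess convention", {
  set.seed(10)
  ks <- replicate(5, {
    x <- rnorm(6000)
    b <- list(times = seq(0.5, 59.5), amps = rep(1, 60))
    f <- ecg_time_features(b, rep(1000, 59), x, rep(1, 60))
    unname(f["ecg_kurtosis"])
  })
  expect_true(all(abs(ks - 3) < 0.2))
})

test_that("tSD_RR is the spread of the two half-epoch RR dispersions", {
  b <- list(times = seq(0.5, 59.5, by = 1), amps = rep(1, 60))
  rr <- c(rep(c(950, 1050), 15)[1:29], rep(1000, 30))
  f <- ecg_time_features(b, rr, rnorm(6000), rep(1, 60))
  mid <- (b$times[-60] + b$times[-1]) / 2
  expected <- sd(c(sd(rr[mid < 30]), sd(rr[mid >= 30])))
  expect_equal(unname(f["tSD_RR"]), expected)
})

test_that("spectral-shape descriptors match closed forms", {
  flat <- list(freq = 1:8, psd = rep(2, 8))
  s <- spectral_shape(flat)
  expect_equal(unname(s["spectral_flatness"]), 1)
  expect_equal(unname(s["spectral_decrease"]), 0)
  expect_equal(unname(s["spectral_slope"]), 0)
  expect_equal(unname(s["spectral_centroid"]), mean(1:8))
  single <- list(freq = c(1, 2, 3), psd = c(0, 5, 0))
  s1 <- spectral_shape(single)
  expect_equal(unname(s1["spectral_centroid"]), 2)
  expect_equal(unname(s1["spectral_spread"]), 0)
  expect_equal(unname(s1["spectral_flatness"]), 0)
  two <- list(freq = c(1, 2), psd = c(1, 3))
  s2 <- spectral_shape(two)
  expect_equal(unname(s2["spectral_centroid"]), 1.75)
  expect_equal(unname(s2["spectral_spread"]), sqrt(0.1875))
  expect_true(all(is.na(spectral_shape(list(freq = 1:4, psd = rep(0, 4))))))
})

test_that("RQA separates structured from unstructured RR series", {
  # constant series: everything recurs
  f <- rqa_features(rep(1000, 60))
  expect_equal(unname(f["DET"]), 1, tolerance = 2e-3)
  expect_equal(unname(f["LAM"]), 1, tolerance = 2e-3)
  expect_equal(unname(f["V_MAX"]), 57)   # N_embedded - 1
  # bounds always hold; sine-modulated beats are more deterministic
  set.seed(11)
  det_iid <- det_sine <- numeric(10)
  for (s in 1:10) {
    iid <- runif(200, 900, 1100)
    tt <- cumsum(iid) / 1000
    sine <- 1000 + 80 * sin(2 * pi * tt / 30) + rnorm(200, 0, 10)
    fi <- rqa_features(iid)
    fsn <- rqa_features(sine)
    for (ff in list(fi, fsn)) {
      expect_true(ff["DET"] >= 0 && ff["DET"] <= 1)
      expect_true(ff["LAM"] >= 0 && ff["LAM"] <= 1)
      expect_lte(ff[["V_MAX"]], 197)
    }
    det_iid[s] <- fi[["DET"]]
    det_sine[s] <- fsn[["DET"]]
  }
  expect_lt(median(det_iid), median(det_sine))
})

test_that("serial correlations behave like Pearson lag correlations", {
  per2 <- rep(c(900, 1100), 30)
  expect_equal(serial_correlation(per2, 2), 1)
  expect_equal(serial_correlation(per2, 1), -1)
  set.seed(12)
  x <- rnorm(1000)
  expect_lt(abs(serial_correlation(x, 1)), 0.1)
  expect_equal(serial_correlation(3 * x + 7, 4), serial_correlation(x, 4))
  expect_true(is.na(serial_correlation(rep(5, 50), 1)))
  expect_true(is.na(serial_correlation(c(1, 2, 3), 2)))
})

test_that("QRS PCA features follow the eigenstructure", {
  set.seed(13)
  # identical beats: degenerate spectrum
  q0 <- matrix(rep(sin(1:12), each = 20), nrow = 20)
  f0 <- qrs_pca_features(q0)
  expect_equal(unname(f0["max_dia_PCA"]), 0, tolerance = 1e-12)
  expect_equal(unname(f0["RP_2_PC"]), 0)
  # rank-1 construction: beats = mu + a_i v
  v <- rnorm(12)
  v <- v / sqrt(sum(v^2))
  a <- rnorm(30, 0, 2)
  q1 <- matrix(5, 30, 12) + outer(a, v)
  f1 <- qrs_pca_features(q1)
  expect_equal(unname(f1["RP_2_PC"]), 0, tolerance = 1e-10)
  expect_equal(unname(f1["max_dia_PCA"]), var(a), tolerance = 1e-8)
  # trace identity: eigenvalues sum to total column variance
  q <- matrix(rnorm(50 * 12), 50)
  f <- qrs_pca_features(q)
  ev <- eigen(cov(q), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(ev), sum(apply(q, 2, var)), tolerance = 1e-9)
  expect_equal(unname(f["max_dia_PCA"]), max(ev), tolerance = 1e-9)
  expect_gt(f[["std_kPCA"]], 0)
})

test_that("extracted ECG features are finite and epoch-start invariant", {
  fs <- 100
  set.seed(14)
  jitter <- cumsum(rnorm(62, 1, 0.03))
  truth <- jitter[jitter < 59.8]
  x <- make_beat_train(truth, fs, noise_sd = 0.05, seed = 15)
  # same samples embedded at minute 0 and minute 2 of a longer trace
  long <- c(x, rnorm(6000, 0, 0.05), x)
  filt <- function(v) butter_filter(v, fs, filter_spec("bandpass", 3,
                                                       c(0.05, 40)))
  f0 <- extract_ecg_features(filt(x), fs)
  f2 <- extract_ecg_features(filt(long)[12001:18000], fs)
  expect_length(f0, 62L)
  expect_true(all(is.finite(f0)))
  # edge filtering transients differ slightly; features agree closely
  expect_equal(f2[names(f0)], f0, tolerance = 0.05)
})
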