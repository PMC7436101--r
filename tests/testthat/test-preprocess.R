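test_that("Butterworth responses match the analytic magnitude response", {
  fs <- 100
  t <- (0:5999) / fs
  # DC offset is rejected by the 0.05-40 Hz band-pass
  y <- butter_filter(rep(5, 6000), fs, filter_spec("bandpass", 3, c(0.05, 40)))
  expect_lt(max(abs(y[1000:5000])), 1e-6 * 5)
  # 10 Hz unit sinusoid passes with the squared one-pass magnitude (~1);
  # amplitude read off as sqrt(2) x RMS (the sample grid misses peaks)
  x <- sin(2 * pi * 10 * t)
  y <- butter_filter(x, fs, filter_spec("bandpass", 3, c(0.05, 40)))
  amp <- sqrt(2 * mean(y[2000:4000]^2))
  bt <- signal::butter(3, c(0.05, 40) / 50, type = "pass")
  hh <- function(b, a, f) {
    zb <- exp(-1i * 2 * pi * f / fs * (seq_along(b) - 1))
    za <- exp(-1i * 2 * pi * f / fs * (seq_along(a) - 1))
    abs(sum(b * zb) / sum(a * za))
  }
  expect_equal(amp, hh(bt$b, bt$a, 10)^2, tolerance = 0.01)
  expect_equal(amp, 1, tolerance = 0.01)
  # 10 Hz through the 3 Hz low-pass is strongly attenuated, matching the
  # analytic (squared, zero-phase) response
  y <- butter_filter(x, fs, filter_spec("lowpass", 3, 3))
  amp_lp <- sqrt(2 * mean(y[2000:4000]^2))
  expect_lt(amp_lp, 0.1)
  bl <- signal::butter(3, 3 / 50, type = "low")
  expect_equal(amp_lp, hh(bl$b, bl$a, 10)^2, tolerance = 0.02)
  # band edge at/above Nyquist is a configuration error
  expect_error(butter_filter(x, fs, filter_spec("lowpass", 3, 50)),
               "Nyquist")
})

test_that("filters are linear", {
  set.seed(4)
  fs <- 100
  x <- rnorm(2000)
  y <- rnorm(2000)
  sp <- filter_spec("bandpass", 3, c(0.05, 40))
  lhs <- butter_filter(2.5 * x - 1.3 * y, fs, sp)
  rhs <- 2.5 * butter_filter(x, fs, sp) - 1.3 * butter_filter(y, fs, sp)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("baseline correction removes a running-median trend", {
  fs <- 10
  n <- 1200
  t <- (0:(n - 1)) / fs
  expect_equal(baseline_correct(rep(7, n), fs), rep(0, n))
  # slow ramp + fast sinusoid: the sinusoid survives, the ramp goes
  ramp <- seq(0, 10, length.out = n)
  wave <- sin(2 * pi * 1.3 * t)
  out <- baseline_correct(ramp + wave, fs)
  expect_lt(max(abs(out - wave)), 0.05 * 10)
  # the residual running 10-s median is small relative to the wave
  k <- 10 * fs + 1
  res_med <- vapply(seq_len(n), function(i) {
    median(out[max(1, i - k %/% 2):min(n, i + k %/% 2)])
  }, numeric(1))
  expect_lt(max(abs(res_med)), 0.2)
  # matches direct shrunken-window running-median subtraction
  x <- rnorm(n)
  direct <- x - vapply(seq_len(n), function(i) {
    median(x[max(1, i - k %/% 2):min(n, i + k %/% 2)])
  }, numeric(1))
  expect_equal(baseline_correct(x, fs), direct, tolerance = 1e-12)
})

test_that("SpO2 repair replaces jump artifacts with the initial median", {
  fs <- 1
  clean <- rep(97, 120)
  expect_equal(as.numeric(repair_spo2(clean, fs)), clean)
  x <- clean
  x[50] <- 60    # 97 -> 60 -> 97 transient
  out <- repair_spo2(x, fs)
  expect_equal(out[50], 97)
  expect_equal(attr(out, "n_repaired"), 2L)  # both >8 steps flagged
  # post-repair: no remaining jump whose endpoints were both repaired or
  # both genuine (brute-force scan of the rule on randomized traces)
  set.seed(9)
  for (i in 1:5) {
    x <- 70 + cumsum(rnorm(300, 0, 4))
    x <- pmin(pmax(x, 0), 100)
    out <- as.numeric(repair_spo2(x, fs))
    bad <- which(c(FALSE, abs(diff(x)) > 8))
    med0 <- median(x[1:10])
    expect_true(all(out[bad] == med0))
    expect_true(all(out[-bad] == x[-bad]) || length(bad) == 0)
    # repaired values come only from the original range or the median
    expect_true(all(out %in% c(x, med0)))
  }
  # all-artifact input collapses to the initial median
  saw <- rep(c(0, 100), 30)
  out <- repair_spo2(saw, fs)
  expect_true(all(out == median(saw[1:10])))
})

test_that("block-mean down-sampling is exact", {
  expect_equal(downsample_1hz(rep(3.5, 500), 100), rep(3.5, 5))
  x <- c(0:99, rep(0, 100))
  expect_equal(downsample_1hz(x, 100)[1], 49.5)
  expect_length(downsample_1hz(rnorm(250), 100), 2L)
  expect_error(downsample_1hz(rnorm(100), 2.5), "integer")
})
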