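#' @name preprocess
#' @title Channel preprocessing
#' @description
#' Channel-specific conditioning ahead of feature extraction: zero-phase
#' Butterworth filtering (band-pass 0.05-40 Hz for ECG and effort signals,
#' 3 Hz low-pass for airflow), 10-s running-median baseline correction,
#' SpO2 artifact repair (sample-to-sample jumps above 8 percentage points
#' replaced by the initial 10-s median), and block-mean down-sampling to
#' 1 Hz. All filters are linear and zero-phase so feature timing never
#' shifts relative to the per-minute annotations.
NULL

#' Describe a Butterworth filter
#'
#' @param kind "bandpass" or "lowpass"
#' @param order filter order (>= 1)
#' @param band `c(low, high)` in Hz for a band-pass, a single cutoff in Hz
#'   for a low-pass
#' @return a `filter_spec` list
#' @export
filter_spec <- function(kind = c("bandpass", "lowpass"), order, band) {
  kind <- match.arg(kind)
  order <- as.integer(order)
  if (order < 1L) stop("filter order must be >= 1")
  if (kind == "bandpass") {
    if (length(band) != 2L || band[1] <= 0 || band[1] >= band[2]) {
      stop("bandpass needs 0 < low < high")
    }
  } else if (length(band) != 1L || band <= 0) {
    stop("lowpass needs a single positive cutoff")
  }
  structure(list(kind = kind, order = order, band = band),
            class = "filter_spec")
}

#' Zero-phase Butterworth filtering
#'
#' Designs the digital Butterworth filter described by `spec` and applies it
#' forward and backward ([signal::filtfilt()]), so the output has zero phase
#' distortion and the same length as the input. The effective magnitude
#' response is the squared one-pass response.
#'
#' @param x numeric samples
#' @param fs sampling rate in Hz
#' @param spec a [filter_spec()]
#' @return filtered samples, same length as `x`
#' @export
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 1, by = 0.01))
#' y <- butter_filter(x, 100, filter_spec("lowpass", 3, 3))
butter_filter <- function(x, fs, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  nyq <- fs / 2
  if (any(spec$band >= nyq)) {
    stop("filter band edge (", max(spec$band), " Hz) must be below Nyquist (",
         nyq, " Hz)")
  }
  if (length(x) <= 3 * spec$order) {
    stop("input too short for a stable order-", spec$order, " filter")
  }
  type <- if (spec$kind == "bandpass") "pass" else "low"
  bt <- butter_cached(spec$order, spec$band / nyq, type)
  # pad with ~3 time constants of the slowest band edge so start-up
  # transients decay inside the padding, capped by the signal length
  np <- min(length(x) - 1L, as.integer(ceiling(3 * fs / min(spec$band))))
  fast_filtfilt(bt$b, bt$a, x, np)
}

# butter() designs are reused thousands of times per record; memoize them
.filter_cache <- new.env(parent = emptyenv())
butter_cached <- function(order, w, type) {
  key <- paste(order, paste(signif(w, 12), collapse = "_"), type)
  bt <- .filter_cache[[key]]
  if (is.null(bt)) {
    bt <- signal::butter(order, w, type = type)
    .filter_cache[[key]] <- bt
  }
  bt
}

# Single-pass IIR filtering with step-matched initial conditions: the
# filter starts in the steady state it would have reached under a constant
# input x0, so a constant signal passes with exactly its steady-state gain
# (no start-up transient). MA stage via convolution, AR stage recursive.
fast_filt <- function(b, a, x, x0 = x[1]) {
  nb <- length(b)
  x1 <- stats::filter(c(rep(x0, nb - 1L), x), b / a[1], sides = 1)
  x1 <- x1[nb:length(x1)]
  if (length(a) >= 2L) {
    ys <- x0 * sum(b) / sum(a)
    x1 <- stats::filter(x1, -a[-1] / a[1], method = "recursive",
                        init = rep(ys, length(a) - 1L))
  }
  as.numeric(x1)
}

# Zero-phase forward-backward application with odd-reflection padding of
# np samples on both ends (slope-continuous extension), trimmed after.
fast_filtfilt <- function(b, a, x, np = 3L * max(length(a), length(b))) {
  n <- length(x)
  np <- min(np, n - 1L)
  z <- if (np > 0L) {
    c(2 * x[1] - x[seq(np + 1L, 2L)], x, 2 * x[n] - x[seq(n - 1L, n - np)])
  } else {
    x
  }
  y <- fast_filt(b, a, z)
  y <- rev(fast_filt(b, a, rev(y)))
  y[(np + 1L):(np + n)]
}

#' Remove a running-median baseline
#'
#' Subtracts the centered running median over a `window_s`-second window;
#' edge positions use shrunken (truncated) windows so the output has full
#' length.
#'
#' @param x numeric samples
#' @param fs sampling rate in Hz
#' @param window_s window length in seconds (default 10)
#' @return `x` minus its running median
#' @export
baseline_correct <- function(x, fs, window_s = 10) {
  n <- length(x)
  k <- as.integer(round(window_s * fs))
  if (k %% 2L == 0L) k <- k + 1L
  if (n < k) {
    return(x - running_median_shrunk(x, seq_len(n), (k - 1L) %/% 2L))
  }
  med <- as.numeric(stats::runmed(x, k, endrule = "keep"))
  h <- (k - 1L) %/% 2L
  edge <- c(seq_len(h), (n - h + 1L):n)
  med[edge] <- running_median_shrunk(x, edge, h)
  x - med
}

running_median_shrunk <- function(x, idx, h) {
  n <- length(x)
  vapply(idx, function(i) {
    stats::median(x[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

#' Repair non-physiological SpO2 jumps
#'
#' Any sample whose absolute difference from its predecessor exceeds
#' `jump` percentage points is replaced by the median of the first 10 s of
#' the trace. Comparisons are made against the original samples in a single
#' left-to-right pass, so one artifact does not mask the next.
#'
#' @param x SaO2 trace in percent saturation (values in `[0, 100]`)
#' @param fs sampling rate in Hz
#' @param jump artifact threshold in percentage points (default 8)
#' @return repaired trace; attribute `n_repaired` counts replacements
#' @export
repair_spo2 <- function(x, fs, jump = 8) {
  if (any(x < 0 | x > 100, na.rm = TRUE)) {
    stop("SaO2 values must lie in [0, 100]")
  }
  n0 <- min(length(x), as.integer(round(10 * fs)))
  med0 <- stats::median(x[seq_len(n0)])
  bad <- c(FALSE, abs(diff(x)) > jump)
  out <- x
  if (all(bad[-1])) {
    log_msg("repair_spo2: every sample-to-sample step exceeds ", jump,
            "%; returning the initial 10-s median throughout")
    out[] <- med0
    attr(out, "n_repaired") <- length(x)
    return(out)
  }
  out[bad] <- med0
  if (any(bad)) {
    log_msg("repair_spo2: replaced ", sum(bad), " artifact sample(s)")
  }
  attr(out, "n_repaired") <- sum(bad)
  out
}

#' Down-sample to 1 Hz by block averaging
#'
#' Each output sample is the mean of one non-overlapping 1-s block, which
#' doubles as the anti-alias step; trailing samples short of a full block
#' are dropped.
#'
#' @param x numeric samples
#' @param fs integer sampling rate in Hz
#' @return samples at 1 Hz, length `floor(length(x) / fs)`
#' @export
downsample_1hz <- function(x, fs) {
  if (fs < 1 || abs(fs - round(fs)) > 1e-9) {
    stop("block-mean down-sampling requires an integer sampling rate, got ",
         fs)
  }
  fs <- as.integer(round(fs))
  n_out <- length(x) %/% fs
  if (n_out == 0L) return(numeric(0))
  colMeans(matrix(x[seq_len(n_out * fs)], nrow = fs))
}
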