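#' @name spectra
#' @title Power spectral density estimators
#' @description
#' The two PSD estimators used by the feature extractors: Welch's averaged
#' modified periodogram (Hamming window, one-sided density scaling, so the
#' PSD integrates to approximately the signal variance) and a Yule-Walker
#' autoregressive estimate solved from (optionally segment-averaged)
#' autocovariances. Both return a frequency grid and density values; band
#' summaries are taken with [band_mean()] / [band_power()].
NULL

#' Welch power spectral density
#'
#' @param x numeric samples
#' @param fs sampling rate in Hz
#' @param nperseg segment length in samples (capped at `length(x)`)
#' @param noverlap overlapping samples between segments (default 50%)
#' @return list with `freq` (Hz, 0..Nyquist) and `psd` (one-sided density,
#'   units^2/Hz)
#' @export
welch_psd <- function(x, fs, nperseg = min(256L, length(x)),
                      noverlap = nperseg %/% 2L) {
  n <- length(x)
  nperseg <- min(as.integer(nperseg), n)
  noverlap <- min(as.integer(noverlap), nperseg - 1L)
  step <- nperseg - noverlap
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- hamming_window(nperseg)
  scale <- 1 / (fs * sum(w^2))
  nfreq <- nperseg %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)] * w
    sp <- abs(stats::fft(seg))^2
    acc <- acc + sp[seq_len(nfreq)]
  }
  psd <- acc / length(starts) * scale
  # one-sided: double everything except DC (and Nyquist when nperseg even)
  dbl <- rep(2, nfreq)
  dbl[1] <- 1
  if (nperseg %% 2L == 0L) dbl[nfreq] <- 1
  list(freq = (seq_len(nfreq) - 1L) * fs / nperseg, psd = psd * dbl)
}

hamming_window <- function(n) {
  if (n == 1L) return(1)
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
}

#' Yule-Walker autoregressive power spectral density
#'
#' Fits an AR(`order`) model by solving the Yule-Walker equations on
#' autocovariances, optionally averaged over non-overlapping analysis
#' segments of `seglen` samples, and evaluates the model spectrum on a
#' regular grid up to Nyquist.
#'
#' @param x numeric samples
#' @param fs sampling rate in Hz
#' @param order AR order (default 5)
#' @param nfreq grid points from 0 to Nyquist (default 512)
#' @param seglen analysis-segment length in samples, or `NULL` for a single
#'   segment spanning `x`
#' @param demean subtract the (per-segment) mean before estimating
#' @return list with `freq`, `psd`, and `degenerate` (TRUE when the signal
#'   carried no usable variance, in which case the PSD is all zero)
#' @export
ar_yw_psd <- function(x, fs, order = 5L, nfreq = 512L, seglen = NULL,
                      demean = TRUE) {
  order <- as.integer(order)
  freq <- seq(0, fs / 2, length.out = nfreq)
  if (is.null(seglen) || seglen >= length(x)) {
    sm <- matrix(x, ncol = 1L)
  } else {
    nseg <- length(x) %/% seglen
    if (nseg == 0L) {
      return(list(freq = freq, psd = numeric(nfreq), degenerate = TRUE))
    }
    sm <- matrix(x[seq_len(nseg * seglen)], nrow = seglen)
  }
  m <- nrow(sm)
  if (m <= order) {
    return(list(freq = freq, psd = numeric(nfreq), degenerate = TRUE))
  }
  if (demean) sm <- sweep(sm, 2, colMeans(sm))
  # biased autocovariance (lags 0..order) averaged over segment columns
  r <- vapply(0:order, function(k) {
    mean(colSums(sm[seq_len(m - k), , drop = FALSE] *
                   sm[(k + 1L):m, , drop = FALSE])) / m
  }, numeric(1))
  if (r[1] <= .Machine$double.eps * 100) {
    log_msg("ar_yw_psd: degenerate (constant) input; returning zero PSD")
    return(list(freq = freq, psd = numeric(nfreq), degenerate = TRUE))
  }
  Rm <- stats::toeplitz(r[seq_len(order)])
  a <- tryCatch(solve(Rm, r[2:(order + 1L)]),
                error = function(e) NULL)
  if (is.null(a)) {
    return(list(freq = freq, psd = numeric(nfreq), degenerate = TRUE))
  }
  sigma2 <- r[1] - sum(a * r[2:(order + 1L)])
  sigma2 <- max(sigma2, 0)
  om <- outer(2 * pi * freq / fs, seq_len(order))
  denom <- abs(1 - ((cos(om) - 1i * sin(om)) %*% a))^2   # |A(e^{-iw})|^2
  psd <- as.numeric(sigma2 / fs / denom)
  list(freq = freq, psd = psd, degenerate = FALSE)
}

#' Mean spectral density over a frequency band
#' @param spec a list with `freq` and `psd`
#' @param band `c(low, high)` in Hz (inclusive)
#' @return mean of the density values at grid points inside the band
#' @export
band_mean <- function(spec, band) {
  sel <- spec$freq >= band[1] & spec$freq <= band[2]
  if (!any(sel)) return(NA_real_)
  mean(spec$psd[sel])
}

#' Integrated spectral power over a frequency band
#' @inheritParams band_mean
#' @return sum of density values times the grid spacing
#' @export
band_power <- function(spec, band) {
  sel <- spec$freq >= band[1] & spec$freq <= band[2]
  if (!any(sel)) return(NA_real_)
  df <- if (length(spec$freq) > 1) spec$freq[2] - spec$freq[1] else 1
  sum(spec$psd[sel]) * df
}

#' Remap a band that exceeds Nyquist
#'
#' Spectral bands are stated relative to a 200 Hz reference rate; when a
#' band's upper edge exceeds the actual Nyquist frequency, the band is
#' reinterpreted as the same *fraction* of Nyquist (e.g. 80-100 Hz maps to
#' 0.8-1.0 x Nyquist). Bands that already fit are returned unchanged.
#'
#' @param band `c(low, high)` in Hz
#' @param fs actual sampling rate in Hz
#' @param ref_fs reference rate the band was stated for (default 200 Hz)
#' @return the (possibly remapped) band in Hz
#' @export
map_band <- function(band, fs, ref_fs = 200) {
  nyq <- fs / 2
  if (band[2] <= nyq) return(band)
  out <- band / (ref_fs / 2) * nyq
  log_msg("band ", band[1], "-", band[2], " Hz exceeds Nyquist (", nyq,
          " Hz); remapped to ", out[1], "-", out[2], " Hz")
  out
}
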