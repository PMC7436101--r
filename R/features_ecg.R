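#' @name features_ecg
#' @title ECG-derived epoch features (Nos. 1-62)
#' @description
#' Beat detection with a modified Pan-Tompkins detector, physiological RR
#' correction, an R-wave-area ECG-derived respiration (EDR) surrogate, and
#' the 62 per-minute ECG features: HRV time-domain statistics, wavelet
#' sub-band statistics (db4 for EDR, sym3 for the raw ECG), Welch spectra of
#' the evenly resampled RR/EDR series and the raw ECG, spectral-shape
#' descriptors, recurrence quantification of the RR series, serial
#' correlations, and QRS principal-component statistics.
NULL

#' Detect R peaks in a one-minute filtered ECG epoch
#'
#' Pan-Tompkins stages: 5-15 Hz band-pass, five-point derivative, squaring,
#' 150 ms moving-window integration, adaptive dual thresholds with a 200 ms
#' refractory period. Detected peak times are refined to the local maximum
#' of the input (0.05-40 Hz filtered) ECG within +/-50 ms.
#'
#' @param ecg band-pass filtered, baseline-corrected epoch samples
#' @param fs sampling rate in Hz
#' @param config pipeline configuration (uses the `ecg` block)
#' @return a list with `times` (seconds from epoch start, ascending), `amps`
#'   (R amplitudes in signal units) and `usable` (FALSE when fewer than
#'   `min_beats` beats were found)
#' @export
detect_r_peaks <- function(ecg, fs, config = default_config()) {
  cfg <- config$ecg
  n <- length(ecg)
  bp <- butter_filter(ecg, fs, filter_spec("bandpass", cfg$pt_order,
                                           cfg$pt_band))
  # centered five-point derivative, squaring, centered moving-window
  # integration (zero phase, so the energy peak stays aligned with the R
  # wave and no group-delay bookkeeping is needed)
  der <- numeric(n)
  if (n > 4L) {
    der[3:(n - 2)] <- (2 * bp[5:n] + bp[4:(n - 1)] -
                         bp[2:(n - 3)] - 2 * bp[1:(n - 4)]) / 8
  }
  sq <- der^2
  w <- max(1L, as.integer(round(cfg$mwi_s * fs)))
  if (w %% 2L == 0L) w <- w + 1L
  h <- (w - 1L) %/% 2L
  csum <- cumsum(c(0, sq))
  i_all <- seq_len(n)
  mwi <- (csum[pmin(n, i_all + h) + 1L] - csum[pmax(0L, i_all - h - 1L) + 1L]) / w

  # candidate peaks: local maxima of the integrated signal
  dm <- diff(mwi)
  cand <- which(dm[-length(dm)] > 0 & dm[-1] <= 0) + 1L
  refract <- as.integer(round(cfg$refractory_s * fs))
  init <- seq_len(min(n, as.integer(2 * fs)))
  spki <- 0.25 * max(mwi[init])
  npki <- 0.5 * mean(mwi[init])
  peaks <- integer(0)
  last <- -Inf
  for (i in cand) {
    p <- mwi[i]
    thr <- npki + 0.25 * (spki - npki)
    if (p > thr && thr > 0) {
      if (i - last >= refract) {
        peaks <- c(peaks, i)
        last <- i
        spki <- 0.125 * p + 0.875 * spki
      }
    } else {
      npki <- 0.125 * p + 0.875 * npki
    }
  }
  # the integrated energy has a flat top about half the window wide, so
  # first localize the QRS on the 5-15 Hz signal inside the integration
  # window, then refine to the local extremum of the filtered ECG
  hr <- as.integer(round(cfg$refine_s * fs))
  ridx <- vapply(peaks, function(i) {
    lo <- max(1L, i - h)
    hi <- min(n, i + h)
    j <- lo + which.max(abs(bp[lo:hi])) - 1L
    lo2 <- max(1L, j - hr)
    hi2 <- min(n, j + hr)
    lo2 + which.max(ecg[lo2:hi2]) - 1L
  }, integer(1))
  ridx <- sort(unique(ridx))
  if (length(ridx) > 1L) {
    keep <- c(TRUE, diff(ridx) >= refract)
    ridx <- ridx[keep]
  }
  usable <- length(ridx) >= cfg$min_beats
  if (!usable) {
    log_msg("detect_r_peaks: only ", length(ridx),
            " beat(s) found; epoch flagged unusable")
  }
  list(times = (ridx - 1L) / fs, amps = ecg[ridx], usable = usable)
}

#' Correct RR intervals to a physiological series
#'
#' Intervals outside `[rr_min_ms, rr_max_ms]`, or deviating more than
#' `rr_dev` (fraction) from the median of the surrounding `rr_local_k`
#' intervals, are replaced by linear interpolation of the nearest valid
#' neighbours.
#'
#' @param raw_rr successive R-to-R intervals in ms
#' @param config pipeline configuration
#' @return corrected intervals; attributes `n_replaced` and `flagged`
#'   (TRUE when fewer than 3 intervals were supplied and no correction was
#'   attempted)
#' @export
correct_rr <- function(raw_rr, config = default_config()) {
  cfg <- config$ecg
  n <- length(raw_rr)
  if (n < 3L) {
    out <- raw_rr
    attr(out, "n_replaced") <- 0L
    attr(out, "flagged") <- TRUE
    return(out)
  }
  h <- cfg$rr_local_k %/% 2L
  if (n >= cfg$rr_local_k) {
    loc_med <- stats::runmed(raw_rr, cfg$rr_local_k, endrule = "keep")
    edge <- c(seq_len(h), (n - h + 1L):n)
    loc_med[edge] <- vapply(edge, function(i) {
      stats::median(raw_rr[max(1L, i - h):min(n, i + h)])
    }, numeric(1))
  } else {
    loc_med <- vapply(seq_len(n), function(i) {
      stats::median(raw_rr[max(1L, i - h):min(n, i + h)])
    }, numeric(1))
  }
  bad <- raw_rr < cfg$rr_min_ms | raw_rr > cfg$rr_max_ms |
    abs(raw_rr - loc_med) > cfg$rr_dev * loc_med
  out <- raw_rr
  if (any(bad) && !all(bad)) {
    good <- which(!bad)
    out[bad] <- stats::approx(good, raw_rr[good], xout = which(bad),
                              rule = 2)$y
  } else if (all(bad)) {
    out[] <- stats::median(raw_rr)
  }
  if (any(bad)) {
    log_msg("correct_rr: replaced ", sum(bad), " interval(s)")
  }
  attr(out, "n_replaced") <- sum(bad)
  attr(out, "flagged") <- FALSE
  out
}

#' ECG-derived respiration by R-wave area
#'
#' One EDR value per beat: the area (sum x dt) of the baseline-corrected ECG
#' over the symmetric 120 ms QRS window centered on the R peak. Windows
#' truncated by the epoch edge are zero-padded.
#'
#' @param ecg filtered epoch samples
#' @param beats output of [detect_r_peaks()]
#' @param fs sampling rate in Hz
#' @param config pipeline configuration
#' @return numeric vector, one value per beat
#' @export
derive_edr <- function(ecg, beats, fs, config = default_config()) {
  half <- as.integer(round(config$ecg$edr_window_ms / 1000 * fs / 2))
  n <- length(ecg)
  idx <- as.integer(round(beats$times * fs)) + 1L
  cols <- outer(idx, (-half):half, "+")
  v <- matrix(0, nrow(cols), ncol(cols))
  ok <- cols >= 1L & cols <= n
  v[ok] <- ecg[cols[ok]]   # zero-padding at the epoch edges
  rowSums(v) / fs
}

#' Extract the QRS sample matrix
#' @param ecg filtered epoch samples
#' @param beats output of [detect_r_peaks()]
#' @param fs sampling rate
#' @param window_ms symmetric window width (default 120 ms)
#' @return matrix, rows = beats, columns = `round(window_ms/1000*fs)` samples
#'   (zero-padded at epoch edges)
#' @export
qrs_matrix <- function(ecg, beats, fs, window_ms = 120) {
  ncol_q <- as.integer(round(window_ms / 1000 * fs))
  half <- ncol_q %/% 2L
  n <- length(ecg)
  idx <- as.integer(round(beats$times * fs)) + 1L
  cols <- outer(idx, seq_len(ncol_q) - half - 1L, "+")
  v <- matrix(0, nrow(cols), ncol(cols))
  ok <- cols >= 1L & cols <= n
  v[ok] <- ecg[cols[ok]]
  v
}

#' HRV and ECG time-domain features (Nos. 1-11)
#'
#' @param beats output of [detect_r_peaks()]
#' @param rr corrected RR intervals in ms
#' @param ecg filtered epoch samples
#' @param edr EDR series (one value per beat)
#' @param config pipeline configuration
#' @return named numeric vector: `RMSSD_R_amp`, `NN50_RR`, `SDSD_RR`,
#'   `tSD_RR`, `std_RR`, `ecg_mean`, `ecg_var`, `ecg_kurtosis`, `mean_RR`,
#'   `CV_EDR`, `mean_R_amp`
#' @export
ecg_time_features <- function(beats, rr, ecg, edr,
                              config = default_config()) {
  d_amp <- diff(beats$amps)
  d_rr <- diff(rr)
  nn50 <- if (isTRUE(config$ecg$nn50_directional)) {
    sum(d_rr > 50)
  } else {
    sum(abs(d_rr) > 50)
  }
  # interval i spans beats i and i+1; halves split at its midpoint time
  mid_t <- (beats$times[-length(beats$times)] + beats$times[-1]) / 2
  first <- rr[mid_t < 30]
  second <- rr[mid_t >= 30]
  tsd <- if (length(first) >= 2 && length(second) >= 2) {
    stats::sd(c(stats::sd(first), stats::sd(second)))
  } else {
    NA_real_
  }
  m2 <- mean((ecg - mean(ecg))^2)
  kurt <- if (m2 > 0) mean((ecg - mean(ecg))^4) / m2^2 else NA_real_
  cv <- if (mean(edr) != 0) stats::sd(edr) / mean(edr) else NA_real_
  if (is.na(cv) && mean(edr) == 0) log_msg("CV_EDR: zero-mean EDR, missing")
  c(RMSSD_R_amp = sqrt(mean(d_amp^2)),
    NN50_RR = nn50,
    SDSD_RR = stats::sd(d_rr),
    tSD_RR = tsd,
    std_RR = stats::sd(rr),
    ecg_mean = mean(ecg),
    ecg_var = stats::var(ecg),
    ecg_kurtosis = kurt,
    mean_RR = mean(rr),
    CV_EDR = cv,
    mean_R_amp = mean(beats$amps))
}

#' Wavelet features of EDR, raw ECG, RR and R-amplitude series (Nos. 12-39)
#'
#' EDR (resampled to the ECG rate over the epoch so a depth-9 analysis is
#' well defined) is decomposed with db4 to level 9; the raw filtered ECG
#' with sym3 to level 7 (entropy, mean and variance per sub-band); the RR
#' and R-amplitude series contribute their wavelet spectral densities (sym3,
#' maximum feasible depth).
#'
#' @param ecg filtered epoch samples
#' @param edr EDR series (per beat)
#' @param beats output of [detect_r_peaks()]
#' @param rr corrected RR intervals (ms)
#' @param fs sampling rate in Hz
#' @param config pipeline configuration
#' @return named numeric vector of the 28 wavelet features
#' @export
ecg_wavelet_features <- function(ecg, edr, beats, rr, fs,
                                 config = default_config()) {
  # (a) EDR -> db4 level 9 detail variances
  edr_u <- resample_uniform(beats$times, edr, fs)
  we <- wavedec(edr_u, "db4", 9L)
  var_d9 <- if (we$level >= 9L) stats::var(we$d$D9) else NA_real_
  var_d2 <- if (we$level >= 2L) stats::var(we$d$D2) else NA_real_

  # (b) raw ECG -> sym3 level 7 sub-band statistics
  w7 <- wavedec(ecg, "sym3", 7L)
  bands <- c(w7$d, list(A7 = w7$a))
  names(bands) <- c(paste0("D", seq_along(w7$d)), "A7")
  ent <- vapply(bands, band_entropy, numeric(1))
  mn <- vapply(bands, mean, numeric(1))
  vr <- vapply(bands, stats::var, numeric(1))
  out <- c(var_EDR_D9 = var_d9, var_EDR_D2 = var_d2)
  nm <- c(paste0("D", 1:7), "A7")
  for (b in nm) {
    out[paste0("entropy_", b)] <- ent[[b]] %||% NA_real_
  }
  for (b in paste0("D", 1:7)) out[paste0("ecg_mean_", b)] <- mn[[b]]
  out["ecg_mean_A7"] <- mn[["A7"]]
  for (b in paste0("D", 1:7)) out[paste0("ecg_var_", b)] <- vr[[b]]
  out["ecg_var_A7"] <- vr[["A7"]]
  out["WSD_RR"] <- wsd(rr, "sym3")
  out["WSD_R_amp"] <- wsd(beats$amps, "sym3")
  out
}

resample_uniform <- function(times, values, fs) {
  if (length(values) < 4L || length(unique(times)) < 4L) {
    return(rep(mean(values), max(4L, length(values))))
  }
  grid <- seq(min(times), max(times), by = 1 / fs)
  stats::spline(times, values, xout = grid, method = "fmm")$y
}

#' Spectral features of RR, EDR and the raw ECG (Nos. 40-44)
#'
#' The beat-indexed RR and EDR series are resampled to an even 4 Hz grid
#' (cubic interpolation over beat times) before Welch estimation. Bands
#' above Nyquist are remapped per [map_band()].
#'
#' @inheritParams ecg_wavelet_features
#' @param ecg_spec precomputed Welch spectrum of the epoch's ECG (optional)
#' @return named vector: `max_PSD_0.03_0.5` (Hz of the RR spectral maximum),
#'   `ecg_mean_PSD_10_20`, `ecg_mean_PSD_80_100`, `var_EDR_0.03_0.4`,
#'   `var_RR_0.03_0.4`
#' @export
ecg_psd_features <- function(rr, edr, beats, ecg, fs,
                             config = default_config(), ecg_spec = NULL) {
  cfg <- config$ecg
  ref <- config$bands$ref_fs
  out <- c(max_PSD_0.03_0.5 = NA_real_, ecg_mean_PSD_10_20 = NA_real_,
           ecg_mean_PSD_80_100 = NA_real_, var_EDR_0.03_0.4 = NA_real_,
           var_RR_0.03_0.4 = NA_real_)
  if (is.null(ecg_spec)) {
    ecg_spec <- welch_psd(ecg, fs, cfg$welch_nperseg_ecg)
  }
  out["ecg_mean_PSD_10_20"] <- band_mean(ecg_spec,
                                         map_band(cfg$band_mid, fs, ref))
  out["ecg_mean_PSD_80_100"] <- band_mean(ecg_spec,
                                          map_band(cfg$band_high, fs, ref))
  if (length(beats$times) < 4L) {
    log_msg("ecg_psd_features: < 4 beats; RR/EDR spectra missing")
    return(out)
  }
  rs <- cfg$resample_hz
  rr_t <- beats$times[-1]
  rr_grid <- seq(min(rr_t), max(rr_t), by = 1 / rs)
  rr_u <- stats::spline(rr_t, rr, xout = rr_grid, method = "fmm")$y
  edr_grid <- seq(min(beats$times), max(beats$times), by = 1 / rs)
  edr_u <- stats::spline(beats$times, edr, xout = edr_grid,
                         method = "fmm")$y
  rr_spec <- welch_psd(rr_u, rs, min(cfg$welch_nperseg_rr, length(rr_u)))
  edr_spec <- welch_psd(edr_u, rs, min(cfg$welch_nperseg_rr, length(edr_u)))
  sel <- rr_spec$freq >= cfg$band_dominant[1] &
    rr_spec$freq <= cfg$band_dominant[2]
  if (any(sel)) {
    out["max_PSD_0.03_0.5"] <- rr_spec$freq[sel][which.max(rr_spec$psd[sel])]
  }
  out["var_EDR_0.03_0.4"] <- band_power(edr_spec, cfg$band_var)
  out["var_RR_0.03_0.4"] <- band_power(rr_spec, cfg$band_var)
  out
}

#' Spectral-shape descriptors (Nos. 45-49)
#'
#' Standard audio-descriptor definitions applied to a power spectrum:
#' flatness (geometric / arithmetic mean), centroid, spread, decrease and
#' least-squares slope.
#'
#' @param spec a list with `freq` (Hz) and `psd` (non-negative powers, at
#'   least 2 bins)
#' @return named vector `spectral_flatness`, `spectral_centroid`,
#'   `spectral_spread`, `spectral_decrease`, `spectral_slope`; all `NA` for
#'   an all-zero spectrum
#' @export
spectral_shape <- function(spec) {
  p <- spec$psd
  f <- spec$freq
  if (length(p) < 2L) stop("spectral_shape needs at least 2 bins")
  if (all(p == 0)) {
    return(c(spectral_flatness = NA_real_, spectral_centroid = NA_real_,
             spectral_spread = NA_real_, spectral_decrease = NA_real_,
             spectral_slope = NA_real_))
  }
  geo <- if (any(p == 0)) 0 else exp(mean(log(p)))
  flat <- geo / mean(p)
  centroid <- sum(f * p) / sum(p)
  spread <- sqrt(sum((f - centroid)^2 * p) / sum(p))
  k <- seq_along(p)
  decrease <- sum((p[-1] - p[1]) / (k[-1] - 1)) / sum(p[-1])
  slope <- sum((f - mean(f)) * (p - mean(p))) / sum((f - mean(f))^2)
  c(spectral_flatness = flat, spectral_centroid = centroid,
    spectral_spread = spread, spectral_decrease = decrease,
    spectral_slope = slope)
}

#' Recurrence quantification of the RR series (Nos. 50-52)
#'
#' Time-delay embedding with dimension `m` and delay `tau`; two embedded
#' points recur when their Euclidean distance is at most
#' `eps_frac * sd(rr)`. The main diagonal is excluded. `DET` is the fraction
#' of recurrent points on diagonal lines of length >= `lmin`, `LAM` the same
#' for vertical lines, and `V_MAX` the longest diagonal line length (the
#' naming convention of the screening table is kept).
#'
#' @param rr RR series (ms)
#' @param config pipeline configuration
#' @return named vector `V_MAX`, `DET`, `LAM` (all `NA` when too few points)
#' @export
rqa_features <- function(rr, config = default_config()) {
  cfg <- config$ecg
  m <- cfg$rqa_m
  tau <- cfg$rqa_tau
  lmin <- cfg$rqa_lmin
  n <- length(rr) - (m - 1L) * tau
  if (n < 2L) {
    return(c(V_MAX = NA_real_, DET = NA_real_, LAM = NA_real_))
  }
  emb <- vapply(0:(m - 1L), function(j) rr[(1:n) + j * tau], numeric(n))
  eps <- cfg$rqa_eps * stats::sd(rr)
  if (eps == 0) eps <- .Machine$double.xmin
  R <- as.matrix(stats::dist(emb)) <= eps
  diag(R) <- FALSE
  total <- sum(R)
  if (total == 0) {
    return(c(V_MAX = 0, DET = 0, LAM = 0))
  }
  # line counting by shift-and-AND: a point starts a run of length >= l
  # when its l-1 chained neighbours (diagonal or vertical) all recur; the
  # points covered by such runs are the starts smeared back along the line
  shift_diag <- function(M, s) {
    out <- matrix(FALSE, n, n)
    if (s > 0) out[(s + 1):n, (s + 1):n] <- M[1:(n - s), 1:(n - s)]
    else if (s < 0) out[1:(n + s), 1:(n + s)] <- M[(1 - s):n, (1 - s):n]
    else out <- M
    out
  }
  shift_vert <- function(M, s) {
    out <- matrix(FALSE, n, n)
    if (s > 0) out[(s + 1):n, ] <- M[1:(n - s), , drop = FALSE]
    else if (s < 0) out[1:(n + s), ] <- M[(1 - s):n, , drop = FALSE]
    else out <- M
    out
  }
  line_points <- function(shift_fun) {
    starts <- R
    for (t in seq_len(lmin - 1L)) starts <- starts & shift_fun(R, -t)
    covered <- starts
    for (t in seq_len(lmin - 1L)) covered <- covered | shift_fun(starts, t)
    sum(covered & R)
  }
  det_pts <- line_points(shift_diag)
  lam_pts <- line_points(shift_vert)
  # longest diagonal line: after t AND-chained shifts the survivors start
  # runs of length >= t + 1
  vmax <- 0L
  M <- R
  while (any(M)) {
    vmax <- vmax + 1L
    M <- M & shift_diag(M, -1L)
  }
  c(V_MAX = as.numeric(vmax), DET = det_pts / total, LAM = lam_pts / total)
}

#' Serial correlation coefficients of the RR series (Nos. 53-57)
#' @param rr RR series (ms)
#' @param k lag (1..5)
#' @return Pearson correlation of `rr[1:(n-k)]` with `rr[(k+1):n]`, `NA`
#'   when either slice has zero variance or the series is too short
#' @export
serial_correlation <- function(rr, k) {
  n <- length(rr)
  if (n <= k + 2L) return(NA_real_)
  a <- rr[seq_len(n - k)]
  b <- rr[(k + 1L):n]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' QRS principal-component features (Nos. 58-62)
#'
#' Linear PCA of the beat-by-sample QRS matrix (columns centered) plus a
#' kernel PCA with an RBF kernel whose bandwidth defaults to the median
#' pairwise beat distance.
#'
#' @param q QRS matrix from [qrs_matrix()] (>= 3 rows)
#' @param sigma RBF bandwidth; `NULL` = median pairwise distance
#' @return named vector `std_PCA`, `std_kPCA`, `max_dia_PCA`,
#'   `max_dia_kPCA`, `RP_2_PC`
#' @export
qrs_pca_features <- function(q, sigma = NULL) {
  if (nrow(q) < 3L) {
    return(c(std_PCA = NA_real_, std_kPCA = NA_real_, max_dia_PCA = NA_real_,
             max_dia_kPCA = NA_real_, RP_2_PC = NA_real_))
  }
  qc <- sweep(q, 2, colMeans(q))
  cv <- stats::cov(qc)
  eg <- eigen(cv, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  scores1 <- qc %*% eg$vectors[, 1]
  rp2 <- if (sum(lam) > 0) lam[2] / sum(lam) else 0
  # RBF kernel PCA
  d <- as.matrix(stats::dist(q))
  if (is.null(sigma)) {
    sigma <- stats::median(d[upper.tri(d)])
    if (!is.finite(sigma) || sigma == 0) sigma <- 1
  }
  K <- exp(-d^2 / (2 * sigma^2))
  n <- nrow(K)
  H <- diag(n) - matrix(1 / n, n, n)
  Kc <- H %*% K %*% H
  egk <- eigen(Kc, symmetric = TRUE)
  lamk <- pmax(egk$values, 0)
  kscores1 <- sqrt(lamk[1]) * egk$vectors[, 1]
  c(std_PCA = stats::sd(scores1),
    std_kPCA = stats::sd(kscores1),
    max_dia_PCA = lam[1],
    max_dia_kPCA = lamk[1] / n,
    RP_2_PC = rp2)
}

#' All 62 ECG features for one epoch
#'
#' Runs the full ECG chain on a filtered one-minute epoch. Returns `NULL`
#' when the epoch is unusable (fewer than `min_beats` detected beats).
#'
#' @param ecg filtered epoch samples
#' @param fs sampling rate in Hz
#' @param config pipeline configuration
#' @return named numeric vector of 62 features (registry ids), or `NULL`
#' @export
extract_ecg_features <- function(ecg, fs, config = default_config()) {
  beats <- detect_r_peaks(ecg, fs, config)
  if (!beats$usable) return(NULL)
  rr <- correct_rr(diff(beats$times) * 1000, config)
  edr <- derive_edr(ecg, beats, fs, config)
  ecg_spec <- welch_psd(ecg, fs, config$ecg$welch_nperseg_ecg)
  shape_spec <- if (identical(config$ecg$spectral_shape_on, "ecg")) {
    ecg_spec
  } else {
    rs <- config$ecg$resample_hz
    rr_t <- beats$times[-1]
    grid <- seq(min(rr_t), max(rr_t), by = 1 / rs)
    welch_psd(stats::spline(rr_t, rr, xout = grid, method = "fmm")$y, rs,
              min(config$ecg$welch_nperseg_rr, length(grid)))
  }
  q <- qrs_matrix(ecg, beats, fs, config$ecg$edr_window_ms)
  c(
    ecg_time_features(beats, rr, ecg, edr, config),
    ecg_wavelet_features(ecg, edr, beats, rr, fs, config),
    ecg_psd_features(rr, edr, beats, ecg, fs, config, ecg_spec),
    spectral_shape(shape_spec),
    rqa_features(rr, config),
    c(SCrC_1_RR = serial_correlation(rr, 1), SCrC_2_RR = serial_correlation(rr, 2),
      SCrC_3_RR = serial_correlation(rr, 3), SCrC_4_RR = serial_correlation(rr, 4),
      SCrC_5_RR = serial_correlation(rr, 5)),
    qrs_pca_features(q, config$ecg$kpca_sigma)
  )
}
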