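#' @name features_channels
#' @title SaO2, airflow and respiratory-effort epoch features (Nos. 63-87)
#' @description
#' The non-ECG per-minute features: oximetry statistics (median, rapid
#' resaturation count RES4, a Yule-Walker AR band mean in the apnea-cycle
#' frequency range, and the Poincare short-axis SD1), airflow moments with
#' Welch band means and a db3 wavelet decomposition, and abdominal/thoracic
#' effort moments with a Yule-Walker band mean and a db2 decomposition.
NULL

#' SaO2 features for one epoch (Nos. 63-66)
#'
#' `RES4` counts rapid resaturation events: second `t` starts an event when
#' the saturation rises by more than `res4_rise` percentage points within
#' `res4_window_s` seconds; contiguous qualifying start-seconds merge into
#' one event. Up to 10 s of the previous minute are accepted as context so
#' events straddling the minute boundary are not lost; an event seen in the
#' context only counts here when its qualifying rise completes inside this
#' epoch.
#'
#' @param s repaired 1 Hz SaO2 epoch (60 samples, percent saturation)
#' @param context trailing seconds of the previous minute (0-10 samples)
#' @param config pipeline configuration
#' @return named vector `spo2_med`, `RES4`, `spo2_mean_PSD_0.016_0.05`,
#'   `SD_1`
#' @export
spo2_features <- function(s, context = numeric(0),
                          config = default_config()) {
  cfg <- config$spo2
  if (any(s < 0 | s > 100)) stop("SaO2 values must lie in [0, 100]")
  med <- stats::median(s)
  sd1 <- if (length(s) >= 3) sqrt(stats::var(diff(s)) / 2) else NA_real_
  res4 <- res4_count(s, context, cfg$res4_rise, cfg$res4_window_s)
  spec <- ar_yw_psd(s - mean(s), fs = 1, order = cfg$ar_order,
                    nfreq = cfg$ar_nfreq, demean = FALSE)
  psd_mean <- if (spec$degenerate) 0 else band_mean(spec, cfg$band)
  c(spo2_med = med, RES4 = res4,
    spo2_mean_PSD_0.016_0.05 = psd_mean, SD_1 = sd1)
}

res4_count <- function(s, context, rise, window) {
  z <- c(context, s)
  n_ctx <- length(context)
  n <- length(z)
  if (n < 2L) return(0L)
  qualifies <- logical(n)
  for (t in seq_len(n - 1L)) {
    dmax <- min(window, n - t)
    hit <- which(z[t + seq_len(dmax)] - z[t] > rise)
    if (length(hit)) {
      # a context start only counts when its first qualifying rise
      # completes inside the epoch proper
      qualifies[t] <- t > n_ctx || (t + hit[1]) > n_ctx
    }
  }
  r <- rle(qualifies)
  sum(r$values)
}

#' Airflow features for one epoch (Nos. 67-75)
#'
#' Operates on the 1 Hz airflow epoch (3 Hz low-pass, 10-s median baseline
#' correction and block-mean down-sampling applied upstream). The Welch
#' estimate uses 5-sample segments with 2 overlapping samples (the floor of
#' the nominal 2.5) and a Hamming window; the wavelet decomposition is db3
#' at depth 3.
#'
#' @param a 1 Hz airflow epoch (60 samples)
#' @param config pipeline configuration
#' @return named vector `af_mean`, `af_med`, `af_std`, `af_mean_PSD_0_0.1`,
#'   `af_mean_PSD_0.4_0.5`, `af_mean_D1`, `af_mean_D2`, `af_mean_D3`,
#'   `af_mean_A3`
#' @export
airflow_features <- function(a, config = default_config()) {
  cfg <- config$airflow
  spec <- welch_psd(a, fs = 1, nperseg = cfg$welch_nperseg,
                    noverlap = cfg$welch_noverlap)
  w <- wavedec(a, "db3", 3L)
  c(af_mean = mean(a),
    af_med = stats::median(a),
    af_std = stats::sd(a),
    af_mean_PSD_0_0.1 = band_mean(spec, c(0, 0.1)),
    af_mean_PSD_0.4_0.5 = band_mean(spec, c(0.4, 0.5)),
    af_mean_D1 = if (w$level >= 1) mean(w$d$D1) else NA_real_,
    af_mean_D2 = if (w$level >= 2) mean(w$d$D2) else NA_real_,
    af_mean_D3 = if (w$level >= 3) mean(w$d$D3) else NA_real_,
    af_mean_A3 = mean(w$a))
}

effort_band_mean <- function(x, fs, config) {
  cfg <- config$effort
  spec <- ar_yw_psd(x, fs = fs, order = cfg$ar_order, nfreq = cfg$ar_nfreq,
                    seglen = cfg$ar_seglen)
  if (spec$degenerate) return(0)
  band_mean(spec, map_band(cfg$band, fs, config$bands$ref_fs))
}

#' Abdominal effort features for one epoch (Nos. 76-81)
#'
#' @param x filtered abdominal epoch (0.05-40 Hz band-pass + baseline
#'   correction applied upstream)
#' @param fs sampling rate in Hz
#' @param config pipeline configuration
#' @return named vector `sum_abs`, `std_abs`, `ab_mean`,
#'   `ab_mean_PSD_80_100`, `ab_mean_D1`, `ab_mean_D2`
#' @export
abdominal_features <- function(x, fs, config = default_config()) {
  w <- wavedec(x, "db2", 2L)
  c(sum_abs = sum(abs(x)),
    std_abs = stats::sd(abs(x)),
    ab_mean = mean(x),
    ab_mean_PSD_80_100 = effort_band_mean(x, fs, config),
    ab_mean_D1 = if (w$level >= 1) mean(w$d$D1) else NA_real_,
    ab_mean_D2 = if (w$level >= 2) mean(w$d$D2) else NA_real_)
}

#' Thoracic effort features for one epoch (Nos. 82-87)
#'
#' Plain moments and order statistics of the filtered epoch plus the same
#' Yule-Walker band mean as the abdominal channel.
#'
#' @inheritParams abdominal_features
#' @return named vector `th_sum`, `th_std`, `th_med`, `th_mean`, `th_var`,
#'   `th_mean_PSD_80_100`
#' @export
thoracic_features <- function(x, fs, config = default_config()) {
  c(th_sum = sum(x),
    th_std = stats::sd(x),
    th_med = stats::median(x),
    th_mean = mean(x),
    th_var = stats::var(x),
    th_mean_PSD_80_100 = effort_band_mean(x, fs, config))
}
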