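#' @name extract
#' @title Record-level feature extraction
#' @description
#' Applies the channel-specific preprocessing once per record, then walks the
#' one-minute epochs and assembles the 87-column feature table. Epochs whose
#' ECG yields fewer than the configured minimum of detected beats are dropped
#' (HRV features are meaningless there); the count of dropped epochs is
#' attached to the result.
NULL

#' Preprocess all five channels of a record
#'
#' ECG: 0.05-40 Hz zero-phase band-pass (the high-pass edge doubles as
#' baseline correction). SaO2: artifact repair then block-mean down-sampling
#' to 1 Hz. Airflow: 3 Hz low-pass, 10-s running-median baseline correction,
#' down-sampling to 1 Hz. Effort channels: 10-s median baseline correction
#' then the 0.05-40 Hz band-pass.
#'
#' @param record a [signal_record()]
#' @param config pipeline configuration
#' @return list with processed channel vectors and their sampling rates
#' @export
preprocess_record <- function(record, config = default_config()) {
  pp <- config$preprocess
  ch <- record$channels
  ecg <- butter_filter(ch$ECG$x, ch$ECG$fs,
                       filter_spec("bandpass", pp$ecg_order, pp$ecg_band))
  spo2 <- repair_spo2(ch$SaO2$x, ch$SaO2$fs, pp$spo2_jump)
  spo2_1hz <- downsample_1hz(as.numeric(spo2), ch$SaO2$fs)
  spo2_1hz <- pmin(pmax(spo2_1hz, 0), 100)
  af <- butter_filter(ch$AIRFLOW$x, ch$AIRFLOW$fs,
                      filter_spec("lowpass", pp$airflow_order,
                                  pp$airflow_lowpass))
  af <- baseline_correct(af, ch$AIRFLOW$fs, pp$baseline_window_s)
  af_1hz <- downsample_1hz(af, ch$AIRFLOW$fs)
  eff_spec <- filter_spec("bandpass", pp$effort_order, pp$effort_band)
  ab <- baseline_correct(ch$ABDOMINAL$x, ch$ABDOMINAL$fs,
                         pp$baseline_window_s)
  ab <- butter_filter(ab, ch$ABDOMINAL$fs, eff_spec)
  th <- baseline_correct(ch$THORACIC$x, ch$THORACIC$fs, pp$baseline_window_s)
  th <- butter_filter(th, ch$THORACIC$fs, eff_spec)
  list(
    ecg = ecg, ecg_fs = ch$ECG$fs,
    spo2_1hz = spo2_1hz,
    airflow_1hz = af_1hz,
    abdominal = ab, abdominal_fs = ch$ABDOMINAL$fs,
    thoracic = th, thoracic_fs = ch$THORACIC$fs
  )
}

#' Extract the 87-feature table from a record
#'
#' @param record a [signal_record()]
#' @param config pipeline configuration
#' @return a data.frame with columns `record_id`, `minute` (0-based),
#'   `label`, and the 87 registry feature columns; attribute
#'   `dropped_epochs` counts unusable minutes
#' @export
#' @examples
#' rec <- generate_record(synth_params(minutes_per_patient = 3, seed = 7))
#' ft <- extract_features(rec)
#' dim(ft)
extract_features <- function(record, config = default_config()) {
  pre <- preprocess_record(record, config)
  reg <- feature_registry()
  n_min <- record$duration_min
  ctx_s <- config$spo2$context_s
  rows <- vector("list", n_min)
  dropped <- 0L
  for (m in seq_len(n_min) - 1L) {
    efs <- pre$ecg_fs
    ecg_ep <- pre$ecg[(m * 60 * efs + 1L):((m + 1L) * 60 * efs)]
    ecg_feats <- extract_ecg_features(ecg_ep, efs, config)
    if (is.null(ecg_feats)) {
      dropped <- dropped + 1L
      next
    }
    s_ep <- pre$spo2_1hz[(m * 60L + 1L):((m + 1L) * 60L)]
    ctx <- if (m > 0L) {
      pre$spo2_1hz[(m * 60L - ctx_s + 1L):(m * 60L)]
    } else {
      numeric(0)
    }
    a_ep <- pre$airflow_1hz[(m * 60L + 1L):((m + 1L) * 60L)]
    afs <- pre$abdominal_fs
    ab_ep <- pre$abdominal[(m * 60 * afs + 1L):((m + 1L) * 60 * afs)]
    tfs <- pre$thoracic_fs
    th_ep <- pre$thoracic[(m * 60 * tfs + 1L):((m + 1L) * 60 * tfs)]
    feats <- c(
      ecg_feats,
      spo2_features(s_ep, ctx, config),
      airflow_features(a_ep, config),
      abdominal_features(ab_ep, afs, config),
      thoracic_features(th_ep, tfs, config)
    )
    rows[[m + 1L]] <- c(minute = m, feats[reg$id])
  }
  keep <- !vapply(rows, is.null, logical(1))
  if (dropped > 0L) {
    log_msg("extract_features: dropped ", dropped, " unusable epoch(s) of ",
            n_min, " in record ", record$record_id)
  }
  mat <- do.call(rbind, rows[keep])
  out <- data.frame(
    record_id = record$record_id,
    minute = as.integer(mat[, "minute"]),
    label = record$labels[as.integer(mat[, "minute"]) + 1L],
    mat[, reg$id, drop = FALSE],
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "dropped_epochs") <- dropped
  out
}

#' Extract features for a list of records
#' @param records list of [signal_record()]s
#' @param config pipeline configuration
#' @return row-bound feature table over all records
#' @export
extract_features_cohort <- function(records, config = default_config()) {
  out <- do.call(rbind, lapply(records, extract_features, config = config))
  rownames(out) <- NULL
  out
}
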