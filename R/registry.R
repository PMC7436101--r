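#' The canonical registry of the 87 epoch features
#'
#' Returns the ordered table of all features the extractor emits: feature
#' number (1-87), source channel, the canonical printed name, and a unique
#' syntactic column identifier used in feature tables (several printed names,
#' e.g. "mean" or "med", recur across channels and are disambiguated with a
#' channel prefix).
#'
#' Numbers 1-62 come from the ECG, 63-66 from SaO2, 67-75 from airflow,
#' 76-81 from the abdominal and 82-87 from the thoracic effort signal.
#'
#' @return a data.frame with columns `no`, `channel`, `name`, `id`
#' @export
#' @examples
#' nrow(feature_registry())  # 87
feature_registry <- function() {
  ecg_names <- c(
    "RMSSD_R_amp", "NN50_RR", "SDSD_RR", "tSD_RR", "std_RR",
    "mean", "var", "kurtosis", "mean_RR", "CV_EDR", "mean_R_amp",
    "var_EDR_D9", "var_EDR_D2",
    paste0("entropy_D", 1:7), "entropy_A7",
    paste0("mean_D", 1:7), "mean_A7",
    paste0("var_D", 1:7), "var_A7",
    "WSD_RR", "WSD_R_amp",
    "max_PSD_0.03/0.5", "mean_PSD_10/20", "mean_PSD_80/100",
    "var_EDR_0.03/0.4", "var_RR_0.03/0.4",
    "spectral flatness", "spectral centroid", "spectral spread",
    "spectral decrease", "spectral slope",
    "V_MAX", "DET", "LAM",
    paste0("SCrC_", 1:5, "_RR"),
    "std_PCA", "std_kPCA", "max_dia_PCA", "max_dia_kPCA", "RP_2_PC"
  )
  ecg_ids <- c(
    "RMSSD_R_amp", "NN50_RR", "SDSD_RR", "tSD_RR", "std_RR",
    "ecg_mean", "ecg_var", "ecg_kurtosis", "mean_RR", "CV_EDR", "mean_R_amp",
    "var_EDR_D9", "var_EDR_D2",
    paste0("entropy_D", 1:7), "entropy_A7",
    paste0("ecg_mean_D", 1:7), "ecg_mean_A7",
    paste0("ecg_var_D", 1:7), "ecg_var_A7",
    "WSD_RR", "WSD_R_amp",
    "max_PSD_0.03_0.5", "ecg_mean_PSD_10_20", "ecg_mean_PSD_80_100",
    "var_EDR_0.03_0.4", "var_RR_0.03_0.4",
    "spectral_flatness", "spectral_centroid", "spectral_spread",
    "spectral_decrease", "spectral_slope",
    "V_MAX", "DET", "LAM",
    paste0("SCrC_", 1:5, "_RR"),
    "std_PCA", "std_kPCA", "max_dia_PCA", "max_dia_kPCA", "RP_2_PC"
  )
  spo2_names <- c("med", "RES4", "mean_PSD_0.016/0.05", "SD_1")
  spo2_ids <- c("spo2_med", "RES4", "spo2_mean_PSD_0.016_0.05", "SD_1")
  af_names <- c("mean", "med", "std", "mean_PSD_0/0.1", "mean_PSD_0.4/0.5",
                "mean_D1", "mean_D2", "mean_D3", "mean_A3")
  af_ids <- c("af_mean", "af_med", "af_std", "af_mean_PSD_0_0.1",
              "af_mean_PSD_0.4_0.5", "af_mean_D1", "af_mean_D2",
              "af_mean_D3", "af_mean_A3")
  ab_names <- c("sum_abs", "std_abs", "mean", "mean_PSD_80/100",
                "mean_D1", "mean_D2")
  ab_ids <- c("sum_abs", "std_abs", "ab_mean", "ab_mean_PSD_80_100",
              "ab_mean_D1", "ab_mean_D2")
  th_names <- c("sum", "std", "med", "mean", "var", "mean_PSD_80/100")
  th_ids <- c("th_sum", "th_std", "th_med", "th_mean", "th_var",
              "th_mean_PSD_80_100")

  data.frame(
    no = 1:87,
    channel = c(rep("ECG", 62), rep("SaO2", 4), rep("AIRFLOW", 9),
                rep("ABDOMINAL", 6), rep("THORACIC", 6)),
    name = c(ecg_names, spo2_names, af_names, ab_names, th_names),
    id = c(ecg_ids, spo2_ids, af_ids, ab_ids, th_ids),
    stringsAsFactors = FALSE
  )
}

#' Bundled reference lambda table for the 87 features
#'
#' Loads the published per-feature lambda values (the number of patients, out
#' of five, for which the feature separated apnea from normal minutes under
#' the paired ANOVA/rank-sum screen) that ship with the package as a
#' plain-text fixture. Used by [select_from_printed_lambda()] and the
#' `fixture-check` command.
#'
#' @return a data.frame with columns `no`, `channel`, `name`, `id`, `lambda`
#' @export
reference_lambda <- function() {
  path <- system.file("extdata", "reference_lambda.csv",
                      package = "apneascreen", mustWork = TRUE)
  lam <- utils::read.csv(path, stringsAsFactors = FALSE)
  reg <- feature_registry()
  stopifnot(nrow(lam) == 87L, identical(lam$no, reg$no))
  merge_cols <- cbind(reg, lambda = lam$lambda)
  merge_cols
}
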