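#' Default pipeline configuration
#'
#' Every numeric constant of the pipeline lives here so that the extraction,
#' selection and evaluation stages can be re-parameterised without touching
#' code. Values are the pipeline defaults discussed in the methods vignette.
#'
#' @return a nested named list of configuration values
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$selection$alpha
default_config <- function() {
  list(
    preprocess = list(
      ecg_band = c(0.05, 40),       # Hz, 3rd-order Butterworth band-pass
      ecg_order = 3L,
      effort_band = c(0.05, 40),    # Hz, same filter for abdominal/thoracic
      effort_order = 3L,
      airflow_lowpass = 3,          # Hz cut-off, 3rd-order low-pass
      airflow_order = 3L,
      baseline_window_s = 10,       # running-median window, seconds
      spo2_jump = 8                 # % points; larger sample-to-sample steps
    ),                              # are non-physiological artifacts
    ecg = list(
      pt_band = c(5, 15),           # Hz, Pan-Tompkins QRS band
      pt_order = 2L,
      refractory_s = 0.2,
      mwi_s = 0.15,                 # moving-window integration length
      refine_s = 0.05,              # R-peak refinement half-window
      min_beats = 10L,              # fewer detected beats => epoch unusable
      edr_window_ms = 120,          # symmetric QRS window for EDR area
      rr_min_ms = 300, rr_max_ms = 2000,
      rr_dev = 0.2,                 # max deviation from local median
      rr_local_k = 5L,              # local-median window (intervals)
      nn50_directional = TRUE,      # count only +50 ms increments
      resample_hz = 4,              # RR/EDR uniform grid for spectra
      welch_nperseg_ecg = 512L,
      welch_nperseg_rr = 120L,
      band_dominant = c(0.03, 0.5), # Hz, dominant RR frequency search band
      band_mid = c(10, 20),         # Hz, on the raw-ECG spectrum
      band_high = c(80, 100),       # Hz, remapped when above Nyquist
      band_var = c(0.03, 0.4),      # Hz, integrated RR/EDR power
      spectral_shape_on = "ecg",    # "ecg" or "rr" Welch spectrum
      rqa_m = 3L, rqa_tau = 1L, rqa_eps = 0.2, rqa_lmin = 2L,
      kpca_sigma = NULL             # NULL = median pairwise distance
    ),
    spo2 = list(
      res4_rise = 4,                # % points
      res4_window_s = 10L,
      context_s = 10L,              # trailing context from previous minute
      ar_order = 5L, ar_nfreq = 512L,
      band = c(0.016, 0.05)         # Hz
    ),
    airflow = list(
      welch_nperseg = 5L,           # samples at 1 Hz
      welch_noverlap = 2L           # floor of the nominal 2.5
    ),
    effort = list(
      ar_order = 5L, ar_seglen = 40L, ar_nfreq = 512L,
      band = c(80, 100)             # Hz, remapped when above Nyquist
    ),
    bands = list(
      ref_fs = 200                  # Hz; bands above Nyquist are rescaled as
    ),                              # fractions of this rate's Nyquist
    selection = list(
      alpha = 0.05,
      exact_max = 10L,              # exact rank-sum null when min(n) <= this
      positive_rule = "reject"      # rank-sum side of a positive pair
    ),
    svm = list(
      k = 10L,                      # stratified CV folds
      sigma = c(1, 5, 25),          # RBF widths
      degree = c(2L, 3L, 4L),       # polynomial degrees
      R = c(0.2, 1, 10),            # regularization
      poly_coef0 = 1                # (x.y + 1)^d inhomogeneous form
    )
  )
}

#' Load a configuration file on top of the defaults
#'
#' Reads a YAML file and merges it recursively onto [default_config()], so a
#' file only needs to state the values it overrides.
#'
#' @param path YAML file, or `NULL` for pure defaults
#' @return the merged configuration list
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) {
    return(cfg)
  }
  if (!file.exists(path)) {
    stop("config file not found: ", path)
  }
  user <- yaml::read_yaml(path)
  merge_lists(cfg, user)
}

merge_lists <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_lists(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}
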