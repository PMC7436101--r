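#' @name synth
#' @title Synthetic PSG cohorts with apnea physiology
#' @description
#' Generates labeled five-channel records that exhibit the apnea signatures
#' the 87 features target: cyclic RR-interval modulation at the apnea cycle
#' period, oxygen desaturations with rapid (> 4 percentage points within
#' 10 s) resaturation, an airflow amplitude collapse lasting 10-30 s, and
#' elevated abdominal excursion. Apnea events are minute-aligned (one event
#' per apnea minute) so the per-minute labels are unambiguous; real PSG has
#' events straddling minute boundaries — a documented limitation.
NULL

#' Parameters of the synthetic cohort
#'
#' Defaults are the nominal study conditions: five patients, 200 minutes
#' each, 35% apnea minutes, 100 ms cyclic RR modulation, 6-point
#' desaturations recovering within 8 s, a 90% airflow amplitude collapse,
#' and doubled abdominal excursion during apnea.
#'
#' @param n_patients number of records in the cohort
#' @param minutes_per_patient annotated minutes per record
#' @param apnea_fraction probability a minute is an apnea minute, in `[0,1]`
#' @param rr_effect amplitude (ms) of the sinusoidal RR modulation (30 s
#'   period) in apnea minutes
#' @param desat_depth SaO2 desaturation depth in percentage points
#' @param desat_recovery_s resaturation time in seconds (<= 10 so the RES4
#'   rule fires)
#' @param airflow_drop fractional airflow amplitude reduction in `[0,1]`
#' @param abdo_gain abdominal amplitude multiplier during apnea (>= 1)
#' @param noise_sd per-channel Gaussian noise SDs (list: ecg, spo2, airflow,
#'   effort)
#' @param rr_noise_ms beat-to-beat RR jitter (ms)
#' @param fs sampling rate of all channels (Hz)
#' @param seed master RNG seed
#' @return a `synth_params` list
#' @export
synth_params <- function(n_patients = 5L, minutes_per_patient = 200L,
                         apnea_fraction = 0.35, rr_effect = 100,
                         desat_depth = 6, desat_recovery_s = 8,
                         airflow_drop = 0.9, abdo_gain = 2,
                         noise_sd = list(ecg = 0.05, spo2 = 0.3,
                                         airflow = 0.1, effort = 0.1),
                         rr_noise_ms = 25, fs = 100, seed = 1L) {
  stopifnot(apnea_fraction >= 0, apnea_fraction <= 1,
            airflow_drop >= 0, airflow_drop <= 1,
            abdo_gain >= 1, desat_recovery_s > 0, desat_recovery_s <= 10,
            n_patients >= 1, minutes_per_patient >= 1, fs > 0)
  structure(
    list(n_patients = as.integer(n_patients),
         minutes_per_patient = as.integer(minutes_per_patient),
         apnea_fraction = apnea_fraction, rr_effect = rr_effect,
         desat_depth = desat_depth, desat_recovery_s = desat_recovery_s,
         airflow_drop = airflow_drop, abdo_gain = abdo_gain,
         noise_sd = noise_sd, rr_noise_ms = rr_noise_ms,
         fs = fs, seed = as.integer(seed)),
    class = "synth_params"
  )
}

patient_seed <- function(seed, patient_index) {
  as.integer((as.numeric(seed) * 48271 + patient_index * 16807) %%
               2147483629)
}

#' Generate one synthetic PSG record
#'
#' Normal minutes: RR ~ N(1000, rr_noise^2) ms with Gaussian-bump QRS
#' templates at the beat times, airflow and effort sinusoids at 0.25 Hz,
#' SaO2 around 97%. Apnea minutes additionally impose the cyclic RR
#' modulation, a desaturation ramp with fast recovery, the airflow
#' amplitude collapse over a random 10-30 s span, and the abdominal gain.
#' All randomness derives from the per-patient seed, so records are
#' reproducible and mutually independent.
#'
#' @param p a [synth_params()]
#' @param patient_index 1-based patient number (selects the RNG substream)
#' @param record_id record identifier (default `sprintf("s%02d", index)`)
#' @param all_normal force every minute to "N" (exercises records without
#'   apnea events)
#' @return a [signal_record()]
#' @export
generate_record <- function(p, patient_index = 1L,
                            record_id = sprintf("s%02d", patient_index),
                            all_normal = FALSE) {
  stopifnot(inherits(p, "synth_params"))
  set.seed(patient_seed(p$seed, patient_index))
  fs <- p$fs
  n_min <- p$minutes_per_patient
  total_s <- n_min * 60
  n <- total_s * fs
  labels <- if (all_normal) {
    rep("N", n_min)
  } else {
    ifelse(stats::runif(n_min) < p$apnea_fraction, "A", "N")
  }
  is_a <- labels == "A"

  # --- beat times: RR walk with apnea-minute cyclic modulation ----------
  t_beats <- numeric(ceiling(total_s / 0.3))
  nb <- 0L
  t <- stats::runif(1, 0, 0.5)
  while (t < total_s) {
    nb <- nb + 1L
    t_beats[nb] <- t
    minute <- min(n_min, floor(t / 60) + 1L)
    rr <- 1000 + stats::rnorm(1, 0, p$rr_noise_ms)
    if (is_a[minute]) rr <- rr + p$rr_effect * sin(2 * pi * t / 30)
    rr <- max(rr, 400)
    t <- t + rr / 1000
  }
  t_beats <- t_beats[seq_len(nb)]

  # --- ECG: Gaussian-bump QRS templates at the beat times ---------------
  ecg <- stats::rnorm(n, 0, p$noise_sd$ecg)
  bump_halfwidth <- round(0.04 * fs)
  tmpl_t <- (-bump_halfwidth:bump_halfwidth) / fs
  tmpl <- exp(-tmpl_t^2 / (2 * 0.01^2))
  amps <- 1 + stats::rnorm(nb, 0, 0.05)
  centers <- round(t_beats * fs) + 1L
  for (b in seq_len(nb)) {
    idx <- centers[b] + (-bump_halfwidth:bump_halfwidth)
    ok <- idx >= 1L & idx <= n
    ecg[idx[ok]] <- ecg[idx[ok]] + amps[b] * tmpl[ok]
  }

  # --- SaO2 at 1 Hz, upsampled ------------------------------------------
  spo2_1 <- 97 + stats::rnorm(total_s, 0, p$noise_sd$spo2)
  desat <- desat_profile(p$desat_depth, p$desat_recovery_s)
  for (m in which(is_a)) {
    sec0 <- (m - 1L) * 60L
    spo2_1[sec0 + seq_along(desat)] <- spo2_1[sec0 + seq_along(desat)] + desat
  }
  spo2 <- pmin(pmax(rep(spo2_1, each = fs), 0), 100)

  # --- airflow: 0.25 Hz breathing with apnea amplitude collapse ---------
  tt <- (seq_len(n) - 1) / fs
  amp_af <- rep(1, n)
  for (m in which(is_a)) {
    span <- stats::runif(1, 10, 30)
    start <- stats::runif(1, 0, 60 - span)
    i0 <- (m - 1L) * 60L * fs + round(start * fs) + 1L
    i1 <- min(n, i0 + round(span * fs))
    amp_af[i0:i1] <- 1 - p$airflow_drop
  }
  airflow <- amp_af * sin(2 * pi * 0.25 * tt) +
    stats::rnorm(n, 0, p$noise_sd$airflow)

  # --- effort: 0.25 Hz sinusoids; abdominal gain during apnea -----------
  amp_ab <- rep(1, n)
  for (m in which(is_a)) {
    i0 <- (m - 1L) * 60L * fs + 1L
    amp_ab[i0:(i0 + 60L * fs - 1L)] <- p$abdo_gain
  }
  abdo <- amp_ab * sin(2 * pi * 0.25 * tt + 0.3) +
    stats::rnorm(n, 0, p$noise_sd$effort)
  thor <- sin(2 * pi * 0.25 * tt + 0.8) +
    stats::rnorm(n, 0, p$noise_sd$effort)

  signal_record(
    record_id,
    list(ECG = list(fs = fs, x = ecg),
         SaO2 = list(fs = fs, x = spo2),
         AIRFLOW = list(fs = fs, x = airflow),
         ABDOMINAL = list(fs = fs, x = abdo),
         THORACIC = list(fs = fs, x = thor)),
    labels
  )
}

# additive SaO2 event profile (seconds): ~20 s linear desaturation, a short
# nadir, then recovery of the full depth within desat_recovery_s (<= 10 s,
# so the rise exceeds 4 points inside a 10-s window)
desat_profile <- function(depth, recovery_s) {
  down <- seq(0, -depth, length.out = 21)[-1]   # seconds 9..28
  hold <- rep(-depth, 2)
  up <- seq(-depth, 0, length.out = round(recovery_s) + 1)[-1]
  c(rep(0, 8), down, hold, up)
}

#' Generate a synthetic cohort
#'
#' Records are generated from independent per-patient RNG substreams of the
#' master seed, so any record's content is independent of cohort order or
#' size.
#'
#' @param p a [synth_params()]
#' @param all_normal integer vector of patient indices forced to all-"N"
#'   (emulates records without any apnea event, which the selection stage
#'   must skip)
#' @return list of [signal_record()]s
#' @export
generate_cohort <- function(p, all_normal = integer(0)) {
  lapply(seq_len(p$n_patients), function(i) {
    generate_record(p, i, all_normal = i %in% all_normal)
  })
}
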