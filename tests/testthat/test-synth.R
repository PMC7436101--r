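test_that("generation is seeded and patient-wise independent", {
  p <- synth_params(minutes_per_patient = 2, seed = 61)
  r1 <- generate_record(p, 1)
  r2 <- generate_record(p, 1)
  expect_identical(r1, r2)
  # a different seed changes the record
  r3 <- generate_record(synth_params(minutes_per_patient = 2, seed = 62), 1)
  expect_false(identical(r1$channels$ECG$x, r3$channels$ECG$x))
  # patient content does not depend on cohort order or size
  p5 <- synth_params(n_patients = 5, minutes_per_patient = 2, seed = 61)
  coh <- generate_cohort(p5)
  expect_identical(coh[[1]], r1)
  expect_identical(coh[[3]], generate_record(p5, 3))
})

test_that("apnea_fraction 0 and all_normal produce pure-normal records", {
  p <- synth_params(minutes_per_patient = 5, apnea_fraction = 0, seed = 63)
  expect_true(all(generate_record(p, 1)$labels == "N"))
  p2 <- synth_params(minutes_per_patient = 5, seed = 63)
  rec <- generate_record(p2, 2, all_normal = TRUE)
  expect_true(all(rec$labels == "N"))
})

test_that("apnea minutes carry the planted physiology", {
  p <- synth_params(minutes_per_patient = 30, seed = 64)
  rec <- generate_record(p, 1)
  pre <- preprocess_record(rec)
  a_min <- which(rec$labels == "A")
  expect_gt(length(a_min), 2)
  for (m in utils::head(a_min, 3)) {
    s <- pre$spo2_1hz[((m - 1) * 60 + 1):(m * 60)]
    expect_gte(unname(spo2_features(s)["RES4"]), 1)
  }
  n_min <- utils::head(which(rec$labels == "N"), 3)
  for (m in n_min) {
    s <- pre$spo2_1hz[((m - 1) * 60 + 1):(m * 60)]
    expect_equal(unname(spo2_features(s)["RES4"]), 0)
  }
})

test_that("an all-normal record is skipped by the selection stage", {
  p <- synth_params(n_patients = 5, minutes_per_patient = 12, seed = 65)
  coh <- generate_cohort(p, all_normal = 5L)
  ft <- extract_features_cohort(coh)
  sr <- lambda_counts(ft)
  expect_equal(sr$nu, 4L)
  expect_true(all(sr$lambda <= 4L))
})

test_that("with all effects zeroed, apnea and normal minutes are exchangeable", {
  # null cohort: no planted physiology; lambda should almost never exceed 1.
  # The alpha = 0.05 joint-test analysis bounds the expected fraction of
  # (feature, seed) pairs with lambda >= 2 near 2-3%; require >= 90% at
  # lambda <= 1 in aggregate.
  lams <- list()
  for (s in 1:4) {
    p <- synth_params(minutes_per_patient = 60, rr_effect = 0,
                      desat_depth = 0, airflow_drop = 0, abdo_gain = 1,
                      seed = 700 + s)
    ft <- extract_features_cohort(generate_cohort(p))
    sr <- lambda_counts(ft)
    lams[[s]] <- sr$lambda
  }
  all_lam <- unlist(lams)
  expect_gte(mean(all_lam <= 1), 0.9)
})
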