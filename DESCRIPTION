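Package: apneascreen
Title: Feature Screening and SVM Evaluation for Sleep Apnea Detection from Polysomnography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage pipeline for per-minute sleep apnea detection from
    five polysomnography channels (ECG, SaO2, airflow, abdominal and thoracic
    effort). Stage one extracts 87 time-domain, frequency-domain and
    non-linear features per one-minute epoch (heart-rate variability, ECG
    derived respiration, wavelet sub-band statistics, Welch and Yule-Walker
    spectra, recurrence quantification, QRS principal components, oximetry
    desaturation/resaturation statistics, respiratory effort moments) and
    screens them by a per-patient ANOVA plus Wilcoxon rank-sum count
    statistic (lambda), stratifying features into classes A-E. Stage two
    evaluates cumulative class subsets with under-sampled, stratified k-fold
    cross-validated support vector machines over a linear/polynomial/RBF
    kernel grid, choosing the subset by hill-climbing on mean accuracy.
    Readers for WFDB and CSV record formats and a physiology-aware synthetic
    cohort generator make every stage testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
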