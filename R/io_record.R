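#' @name io_record
#' @title Multi-channel PSG records and one-minute epochs
#' @description
#' A `signal_record` holds one subject's five PSG channels (ECG, SaO2,
#' airflow, abdominal and thoracic effort), each with its own sampling rate,
#' plus one apnea/normal label per minute. [epochs()] slices a record into
#' aligned one-minute views: epoch `m` (0-based) covers samples
#' `[m*60*fs, (m+1)*60*fs)` of every channel, a half-open partition of the
#' annotated part of the record.
NULL

#' Canonical channel names
#' @return character vector of the five channel names
#' @export
channel_names <- function() c("ECG", "SaO2", "AIRFLOW", "ABDOMINAL", "THORACIC")

#' Construct a PSG signal record
#'
#' @param record_id record identifier
#' @param channels named list over [channel_names()]; each element a list
#'   with `fs` (sampling rate, Hz, > 0) and `x` (numeric samples)
#' @param labels character vector of per-minute labels, each "A" or "N"
#' @param duration_min annotated minutes; defaults to `length(labels)`
#'
#' @details Channels longer than `duration_min * 60 * fs` samples are
#'   truncated (with a log message); shorter channels are an error. Trailing
#'   un-annotated samples therefore never reach the feature extractor.
#'
#' @return an object of class `signal_record`
#' @export
signal_record <- function(record_id, channels, labels,
                          duration_min = length(labels)) {
  if (!all(names(channels) %in% channel_names())) {
    stop("unknown channel name(s): ",
         paste(setdiff(names(channels), channel_names()), collapse = ", "))
  }
  if (anyDuplicated(names(channels))) {
    stop("duplicated channel names in record ", record_id)
  }
  if (!all(labels %in% c("A", "N"))) {
    stop("labels must be 'A' or 'N'; found: ",
         paste(unique(setdiff(labels, c("A", "N"))), collapse = ", "))
  }
  duration_min <- as.integer(duration_min)
  if (length(labels) != duration_min) {
    stop("labels length (", length(labels), ") != duration_min (",
         duration_min, ")")
  }
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (is.null(ch$fs) || ch$fs <= 0) {
      stop("channel ", nm, ": sampling rate must be > 0")
    }
    need <- duration_min * 60 * ch$fs
    if (abs(need - round(need)) > 1e-9) {
      stop("channel ", nm, ": fs * 60 s is not an integer sample count")
    }
    need <- as.integer(round(need))
    if (length(ch$x) < need) {
      stop("channel ", nm, ": ", length(ch$x), " samples < ", need,
           " required for ", duration_min, " annotated minutes")
    }
    if (length(ch$x) > need) {
      log_msg("record ", record_id, ", channel ", nm, ": discarding ",
              length(ch$x) - need, " trailing samples beyond minute ",
              duration_min)
      channels[[nm]]$x <- ch$x[seq_len(need)]
    }
  }
  structure(
    list(record_id = record_id, channels = channels,
         labels = labels, duration_min = duration_min),
    class = "signal_record"
  )
}

#' @export
print.signal_record <- function(x, ...) {
  cat("<signal_record>", x$record_id, "-", x$duration_min, "min,",
      sum(x$labels == "A"), "apnea /", sum(x$labels == "N"), "normal\n")
  for (nm in names(x$channels)) {
    ch <- x$channels[[nm]]
    cat(sprintf("  %-10s fs=%g Hz, n=%d\n", nm, ch$fs, length(ch$x)))
  }
  invisible(x)
}

#' Slice a record into one-minute epoch views
#'
#' @param record a [signal_record()]
#' @return a list of `duration_min` epoch views; each is a list with
#'   `record_id`, `minute_index` (0-based), `label`, `windows` (named list of
#'   per-channel sample vectors, exactly 60 s each) and `fs` (named vector)
#' @export
#' @examples
#' rec <- generate_record(synth_params(minutes_per_patient = 2, seed = 1))
#' length(epochs(rec))  # 2
epochs <- function(record) {
  stopifnot(inherits(record, "signal_record"))
  lapply(seq_len(record$duration_min) - 1L, function(m) {
    epoch_view(record, m)
  })
}

#' Extract a single epoch view (0-based minute index)
#' @param record a [signal_record()]
#' @param minute_index 0-based minute
#' @return one epoch view (see [epochs()])
#' @export
epoch_view <- function(record, minute_index) {
  if (minute_index < 0 || minute_index >= record$duration_min) {
    stop("minute_index ", minute_index, " outside [0, ",
         record$duration_min - 1L, "]")
  }
  windows <- lapply(record$channels, function(ch) {
    n_min <- as.integer(round(60 * ch$fs))
    ch$x[(minute_index * n_min + 1L):((minute_index + 1L) * n_min)]
  })
  list(
    record_id = record$record_id,
    minute_index = as.integer(minute_index),
    label = record$labels[minute_index + 1L],
    windows = windows,
    fs = vapply(record$channels, function(ch) ch$fs, numeric(1))
  )
}

#' Read a record from the package CSV dialect
#'
#' The CSV dialect stores all five channels at a common sampling rate in
#' columns `time_s, ecg, spo2, airflow, abdo, thor`, with a sidecar label
#' file (`<stem>_labels.txt`, one "A"/"N" per line, one line per minute).
#'
#' @param path CSV file path
#' @param record_id identifier for the returned record; defaults to the file
#'   stem
#' @param labels_path sidecar label file; defaults to `<stem>_labels.txt`
#' @return a [signal_record()]
#' @export
read_csv_record <- function(path, record_id = NULL, labels_path = NULL) {
  if (!file.exists(path)) stop("CSV record file not found: ", path)
  stem <- sub("\\.csv$", "", path)
  record_id <- record_id %||% basename(stem)
  labels_path <- labels_path %||% paste0(stem, "_labels.txt")
  if (!file.exists(labels_path)) {
    stop("label sidecar file not found: ", labels_path)
  }
  nf <- utils::count.fields(path, sep = ",")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1])[1]
    stop("ragged CSV: row ", bad, " has ", nf[bad], " fields, expected ",
         nf[1], " (", path, ")")
  }
  df <- utils::read.csv(path)
  need <- c("time_s", "ecg", "spo2", "airflow", "abdo", "thor")
  if (!all(need %in% names(df))) {
    stop("CSV record must have columns ", paste(need, collapse = ", "),
         "; found ", paste(names(df), collapse = ", "))
  }
  dt <- stats::median(diff(df$time_s))
  fs <- round(1 / dt)
  if (!isTRUE(all.equal(fs * dt, 1, tolerance = 1e-6))) {
    stop("non-uniform or non-integer sampling in time_s (dt = ", dt, ")")
  }
  labels <- readLines(labels_path)
  labels <- labels[nzchar(labels)]
  have_min <- floor(nrow(df) / (60 * fs))
  if (length(labels) > have_min) {
    stop("label file has ", length(labels), " minutes but the CSV holds only ",
         have_min, " full minutes of samples")
  }
  chans <- list(
    ECG = list(fs = fs, x = df$ecg),
    SaO2 = list(fs = fs, x = df$spo2),
    AIRFLOW = list(fs = fs, x = df$airflow),
    ABDOMINAL = list(fs = fs, x = df$abdo),
    THORACIC = list(fs = fs, x = df$thor)
  )
  signal_record(record_id, chans, labels)
}

#' Write a record in the package CSV dialect
#'
#' All channels must share one sampling rate (the dialect has a single time
#' axis). Writes `<path>` and the `<stem>_labels.txt` sidecar.
#'
#' @param record a [signal_record()]
#' @param path output CSV path
#' @return invisibly, the CSV path
#' @export
write_csv_record <- function(record, path) {
  fs <- vapply(record$channels, function(ch) ch$fs, numeric(1))
  if (length(unique(fs)) != 1L) {
    stop("CSV dialect requires a single sampling rate; found ",
         paste(unique(fs), collapse = ", "))
  }
  fs <- fs[[1]]
  n <- length(record$channels$ECG$x)
  df <- data.frame(
    time_s = (seq_len(n) - 1) / fs,
    ecg = record$channels$ECG$x,
    spo2 = record$channels$SaO2$x,
    airflow = record$channels$AIRFLOW$x,
    abdo = record$channels$ABDOMINAL$x,
    thor = record$channels$THORACIC$x
  )
  utils::write.csv(df, path, row.names = FALSE)
  writeLines(record$labels, paste0(sub("\\.csv$", "", path), "_labels.txt"))
  invisible(path)
}
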