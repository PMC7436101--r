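#' @name io_wfdb
#' @title WFDB record and apnea-annotation I/O
#' @description
#' Minimal reader/writer for the WFDB format family used by overnight PSG
#' archives: `.hea` text headers, `.dat` signal files in formats 16 (16-bit
#' little-endian) and 212 (packed 12-bit pairs), and the binary MIT
#' annotation format carrying one "A"/"N" label per minute. Channel
#' descriptions are matched case-insensitively against a configurable alias
#' table, since archived records name the respiratory channels in several
#' ways ("Resp A", "Resp C", "Resp N", ...).
NULL

#' Default channel alias table
#'
#' Maps each canonical channel to the lowercase description strings accepted
#' for it. Matching is case-insensitive on the full description first, then
#' on a leading substring.
#'
#' @return named list of character vectors
#' @export
default_channel_aliases <- function() {
  list(
    ECG = c("ecg", "ekg"),
    SaO2 = c("spo2", "sao2", "oxygen saturation"),
    AIRFLOW = c("resp n", "airflow", "flow", "resp nasal", "nasal"),
    ABDOMINAL = c("resp a", "abdo", "abdomen", "abdominal"),
    THORACIC = c("resp c", "chest", "thor", "thoracic")
  )
}

match_channel <- function(desc, aliases) {
  d <- tolower(trimws(desc))
  for (nm in names(aliases)) {
    if (d %in% aliases[[nm]]) return(nm)
  }
  for (nm in names(aliases)) {
    if (any(startsWith(d, aliases[[nm]]))) return(nm)
  }
  NA_character_
}

parse_hea <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(rec[2])
  fs <- if (length(rec) >= 3) as.numeric(strsplit(rec[3], "/")[[1]][1]) else 250
  sig <- lapply(lines[1 + seq_len(nsig)], function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    gain_field <- f[3]
    gain_main <- sub("\\(.*", "", sub("/.*", "", gain_field))
    baseline <- if (grepl("\\(", gain_field)) {
      as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_field))
    } else NA_real_
    adczero <- if (length(f) >= 5) as.numeric(f[5]) else 0
    gain <- as.numeric(gain_main)
    if (is.na(gain) || gain == 0) gain <- 200
    list(
      file = f[1],
      fmt = as.integer(sub("[^0-9].*", "", f[2])),
      gain = gain,
      baseline = if (is.na(baseline)) adczero else baseline,
      desc = if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else ""
    )
  })
  list(record = rec[1], nsig = nsig, fs = fs,
       nsamp = if (length(rec) >= 4) as.numeric(rec[4]) else NA, signals = sig)
}

read_dat <- function(path, fmt, nsig, nsamp = NA) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (fmt == 16L) {
    v <- readBin(raw, "integer", n = length(raw) %/% 2L, size = 2L,
                 signed = TRUE, endian = "little")
  } else if (fmt == 212L) {
    n3 <- (length(raw) %/% 3L) * 3L
    b <- as.integer(raw[seq_len(n3)])
    b0 <- b[seq(1L, n3, by = 3L)]
    b1 <- b[seq(2L, n3, by = 3L)]
    b2 <- b[seq(3L, n3, by = 3L)]
    s1 <- b0 + bitwShiftL(bitwAnd(b1, 0x0FL), 8L)
    s2 <- b2 + bitwShiftL(bitwShiftR(b1, 4L), 8L)
    s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
    s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
    v <- as.vector(rbind(s1, s2))
  } else {
    stop("unsupported WFDB signal format: ", fmt)
  }
  per_sig <- length(v) %/% nsig
  if (!is.na(nsamp) && nsamp > 0) per_sig <- min(per_sig, nsamp)
  m <- matrix(v[seq_len(per_sig * nsig)], nrow = nsig)
  m  # rows = signals (frame-interleaved), columns = frames
}

#' Read minute labels from an MIT-format annotation file
#'
#' Decodes the standard 16-bit annotation words (type in the high 6 bits,
#' sample-interval in the low 10), honouring SKIP (long intervals), NUM, SUB,
#' CHN and AUX pseudo-annotations. Type 1 maps to "N", type 8 to "A"; any
#' other visible annotation type is a format error for an apnea stream.
#'
#' @param path annotation file
#' @return data.frame with columns `sample` (0-based) and `label`
#' @export
read_wfdb_annotations <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  words <- readBin(raw, "integer", n = length(raw) %/% 2L, size = 2L,
                   signed = FALSE, endian = "little")
  i <- 1L
  t <- 0
  skip <- 0
  out_t <- numeric(0)
  out_c <- integer(0)
  while (i <= length(words)) {
    w <- words[i]
    code <- bitwShiftR(w, 10L)
    delta <- bitwAnd(w, 0x3FFL)
    if (code == 0L && delta == 0L) break
    if (code == 59L) {           # SKIP: 32-bit interval in the next 2 words
      hi <- words[i + 1L]
      lo <- words[i + 2L]
      skip <- skip + hi * 65536 + lo
      i <- i + 3L
      next
    }
    if (code == 63L) {           # AUX: delta = byte count, padded to even
      i <- i + 1L + (delta + delta %% 2L) %/% 2L
      next
    }
    if (code %in% c(60L, 61L, 62L)) {  # NUM / SUB / CHN modifiers
      i <- i + 1L
      next
    }
    t <- t + skip + delta
    skip <- 0
    out_t <- c(out_t, t)
    out_c <- c(out_c, code)
    i <- i + 1L
  }
  lab <- ifelse(out_c == 1L, "N", ifelse(out_c == 8L, "A", NA))
  if (anyNA(lab)) {
    stop("annotation stream contains non-apnea annotation type(s): ",
         paste(unique(out_c[is.na(lab)]), collapse = ", "))
  }
  data.frame(sample = out_t, label = lab, stringsAsFactors = FALSE)
}

#' Write minute labels as an MIT-format annotation file
#' @param labels character vector of "A"/"N", one per minute
#' @param fs sampling frequency the annotation times refer to
#' @param path output file
#' @return invisibly, `path`
#' @export
write_wfdb_annotations <- function(labels, fs, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  step <- round(60 * fs)
  prev <- 0
  for (m in seq_along(labels)) {
    t <- (m - 1) * step
    delta <- t - prev
    prev <- t
    if (delta > 1023) {
      writeBin(as.integer(59L * 1024L), con, size = 2, endian = "little")
      writeBin(as.integer(delta %/% 65536), con, size = 2, endian = "little")
      writeBin(as.integer(delta %% 65536), con, size = 2, endian = "little")
      delta <- 0
    }
    code <- if (labels[m] == "A") 8L else 1L
    writeBin(as.integer(code * 1024L + delta), con, size = 2,
             endian = "little")
  }
  writeBin(as.integer(0L), con, size = 2, endian = "little")
  invisible(path)
}

#' Read a WFDB PSG record with per-minute apnea annotations
#'
#' @param dir directory holding `<record_id>.hea`, the `.dat` file(s) and the
#'   annotation file
#' @param record_id record name
#' @param annotator annotation file extension (default `"apn"`)
#' @param aliases channel alias table, see [default_channel_aliases()]
#' @return a [signal_record()]
#' @export
read_wfdb_record <- function(dir, record_id, annotator = "apn",
                             aliases = default_channel_aliases()) {
  hea <- file.path(dir, paste0(record_id, ".hea"))
  if (!file.exists(hea)) stop("WFDB header not found: ", hea)
  h <- parse_hea(hea)
  mapped <- vapply(h$signals, function(s) match_channel(s$desc, aliases),
                   character(1))
  if (anyNA(mapped) || anyDuplicated(mapped) ||
      length(mapped) != length(channel_names())) {
    stop("expected exactly the 5 PSG channels; header describes: ",
         paste(vapply(h$signals, `[[`, character(1), "desc"),
               collapse = ", "))
  }
  dat_files <- unique(vapply(h$signals, `[[`, character(1), "file"))
  sig_list <- vector("list", h$nsig)
  for (df in dat_files) {
    idx <- which(vapply(h$signals, `[[`, character(1), "file") == df)
    fmt <- h$signals[[idx[1]]]$fmt
    fp <- file.path(dir, df)
    if (!file.exists(fp)) stop("WFDB signal file not found: ", fp)
    m <- read_dat(fp, fmt, length(idx), h$nsamp)
    for (j in seq_along(idx)) sig_list[[idx[j]]] <- m[j, ]
  }
  ann_path <- file.path(dir, paste0(record_id, ".", annotator))
  if (!file.exists(ann_path)) {
    stop("annotation file not found: ", ann_path)
  }
  ann <- read_wfdb_annotations(ann_path)
  labels <- ann$label[order(ann$sample)]
  chans <- list()
  for (j in seq_len(h$nsig)) {
    s <- h$signals[[j]]
    chans[[mapped[j]]] <- list(fs = h$fs,
                               x = (sig_list[[j]] - s$baseline) / s$gain)
  }
  chans <- chans[channel_names()]
  signal_record(record_id, chans, labels)
}

#' Write a signal record as a WFDB record (format 16) plus annotations
#'
#' Intended for tests and data exchange: samples are quantized with a
#' per-channel gain of 1000 ADC units per physical unit.
#'
#' @param record a [signal_record()]
#' @param dir output directory
#' @param annotator annotation extension (default `"apn"`)
#' @param gain ADC units per physical unit
#' @return invisibly, the header path
#' @export
write_wfdb_record <- function(record, dir, annotator = "apn", gain = 1000) {
  fs <- vapply(record$channels, function(ch) ch$fs, numeric(1))
  if (length(unique(fs)) != 1L) {
    stop("WFDB writer requires a single sampling rate")
  }
  fs <- fs[[1]]
  id <- record$record_id
  desc <- c(ECG = "ECG", SaO2 = "SpO2", AIRFLOW = "Resp N",
            ABDOMINAL = "Resp A", THORACIC = "Resp C")
  nms <- channel_names()
  n <- length(record$channels[[1]]$x)
  adc <- vapply(nms, function(nm) {
    v <- round(record$channels[[nm]]$x * gain)
    as.integer(pmax(pmin(v, 32767), -32768))
  }, integer(n))
  dat <- as.vector(t(adc))
  dat_file <- paste0(id, ".dat")
  writeBin(dat, file.path(dir, dat_file), size = 2, endian = "little")
  hea <- c(
    paste(id, length(nms), fs, n),
    vapply(nms, function(nm) {
      paste(dat_file, "16", paste0(gain, "(0)/adu"), "16", "0", "0", "0",
            "0", desc[[nm]])
    }, character(1))
  )
  writeLines(hea, file.path(dir, paste0(id, ".hea")))
  write_wfdb_annotations(record$labels, fs,
                         file.path(dir, paste0(id, ".", annotator)))
  invisible(file.path(dir, paste0(id, ".hea")))
}
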