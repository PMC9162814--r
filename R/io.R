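# Minimal WFDB dialect reader/writer: .hea headers, format-212 .dat signal
# files, and MIT .atr annotation files — the subset the MIT-BIH arrhythmia
# records use. 12-bit two's-complement samples, two samples packed per 3
# bytes, annotations as 6-bit code + 10-bit time-increment words.

# WFDB annotation codes that mark QRS complexes (beats): NORMAL..UNKNOWN,
# BBB, AESC, SVESC, PFUS, RONT. Rhythm/quality/non-beat codes are dropped.
.WFDB_BEAT_CODES <- c(1:13, 25L, 34L, 35L, 38L, 41L)

#' Read a WFDB record header
#'
#' Parses the `.hea` file of a WFDB record: record name, number of signals,
#' sampling rate, record length, and the per-signal gain/baseline/description
#' fields needed to convert raw ADC units to millivolts.
#'
#' @param path Path to the record, with or without the `.hea` extension.
#' @return A list of class `record_meta`: `record_id`, `channels` (character
#'   vector of signal descriptions), `fs`, `n_samples`, plus per-signal
#'   `gain`, `baseline`, `file_name`, `format`.
#' @export
read_wfdb_header <- function(path) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) {
    stop("header file not found: ", hea, call. = FALSE)
  }
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 1) stop("corrupt header: empty file", call. = FALSE)
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 4) {
    stop("corrupt header: record line needs name, nsig, fs, nsamp",
         call. = FALSE)
  }
  record_id <- sub("/.*$", "", top[1])
  nsig <- suppressWarnings(as.integer(top[2]))
  fs <- suppressWarnings(as.numeric(sub("/.*$", "", top[3])))
  n_samples <- suppressWarnings(as.integer(top[4]))
  if (is.na(nsig) || is.na(fs) || is.na(n_samples) || nsig < 1 || fs <= 0) {
    stop("corrupt header: unparseable record line", call. = FALSE)
  }
  if (length(lines) < 1 + nsig) {
    stop("corrupt header: fewer signal lines than declared signals",
         call. = FALSE)
  }
  sig <- lapply(lines[2:(1 + nsig)], function(ln) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) < 2) stop("corrupt header: bad signal line",
                              call. = FALSE)
    gain_spec <- if (length(tok) >= 3) tok[3] else "200"
    gain_num <- sub("\\(.*", "", sub("/.*$", "", gain_spec))
    gain <- suppressWarnings(as.numeric(gain_num))
    if (is.na(gain) || gain == 0) gain <- 200
    baseline <- if (grepl("\\(", gain_spec)) {
      suppressWarnings(as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1",
                                      gain_spec)))
    } else if (length(tok) >= 5) {
      # default baseline is the ADC zero
      suppressWarnings(as.numeric(tok[5]))
    } else {
      0
    }
    if (is.na(baseline)) baseline <- 0
    desc <- if (length(tok) >= 9) paste(tok[9:length(tok)], collapse = " ")
            else tok[1]
    list(file_name = tok[1], format = sub("x.*$", "", tok[2]),
         gain = gain, baseline = baseline, description = desc)
  })
  structure(
    list(record_id = record_id,
         channels = vapply(sig, `[[`, character(1), "description"),
         fs = fs, n_samples = n_samples, signals = sig),
    class = "record_meta"
  )
}

# unpack a format-212 byte stream into 12-bit two's-complement integers
.unpack_212 <- function(bytes, n_values) {
  nb <- length(bytes)
  n_pairs <- nb %/% 3L
  b <- as.integer(bytes[seq_len(n_pairs * 3L)])
  b1 <- b[seq(1, by = 3, length.out = n_pairs)]
  b2 <- b[seq(2, by = 3, length.out = n_pairs)]
  b3 <- b[seq(3, by = 3, length.out = n_pairs)]
  s1 <- b1 + 256L * (b2 %% 16L)
  s2 <- b3 + 256L * (b2 %/% 16L)
  v <- numeric(2L * n_pairs)
  v[c(TRUE, FALSE)] <- s1
  v[c(FALSE, TRUE)] <- s2
  v <- ifelse(v > 2047, v - 4096, v)
  v[seq_len(n_values)]
}

.pack_212 <- function(values) {
  if (length(values) %% 2L == 1L) values <- c(values, 0L)
  v <- as.integer(values)
  if (any(v < -2048L | v > 2047L)) {
    stop("sample out of 12-bit range for format 212", call. = FALSE)
  }
  v <- ifelse(v < 0L, v + 4096L, v)
  s1 <- v[c(TRUE, FALSE)]
  s2 <- v[c(FALSE, TRUE)]
  out <- integer(3L * length(s1))
  out[seq(1, by = 3, length.out = length(s1))] <- s1 %% 256L
  out[seq(2, by = 3, length.out = length(s1))] <-
    (s1 %/% 256L) + 16L * (s2 %/% 256L)
  out[seq(3, by = 3, length.out = length(s1))] <- s2 %% 256L
  as.raw(out)
}

#' Read one channel of a WFDB record
#'
#' Reads the header and the format-212 signal file, checks the signal file is
#' not truncated relative to the declared length, and returns the selected
#' channel converted to millivolts via the header's gain and baseline.
#'
#' @param path Record path with or without the `.hea` extension.
#' @param channel_index 0-based channel index (0 = first channel, the MLII
#'   lead on most MIT-BIH records).
#' @return An [ecg_signal] with `record_id` and `channel` from the header.
#' @export
read_wfdb_record <- function(path, channel_index = 0L) {
  meta <- read_wfdb_header(path)
  nsig <- length(meta$channels)
  if (channel_index < 0 || channel_index >= nsig) {
    stop(sprintf("channel_index %d out of range for %d-channel record",
                 channel_index, nsig), call. = FALSE)
  }
  fmt <- meta$signals[[1]]$format
  if (fmt != "212") {
    stop("only format 212 signal files are supported, got ", fmt,
         call. = FALSE)
  }
  dat <- file.path(dirname(if (grepl("\\.hea$", path)) path
                           else paste0(path, ".hea")),
                   meta$signals[[channel_index + 1L]]$file_name)
  if (!file.exists(dat)) stop("signal file not found: ", dat, call. = FALSE)
  n_values <- meta$n_samples * nsig
  need_bytes <- ceiling(n_values / 2) * 3
  got <- file.size(dat)
  if (got < need_bytes) {
    stop(sprintf("signal file truncated: %d bytes, need %d", got,
                 need_bytes), call. = FALSE)
  }
  bytes <- readBin(dat, "raw", n = need_bytes)
  v <- .unpack_212(bytes, n_values)
  ch <- v[seq(channel_index + 1L, by = nsig, length.out = meta$n_samples)]
  s <- meta$signals[[channel_index + 1L]]
  mv <- (ch - s$baseline) / s$gain
  ecg_signal(mv, meta$fs, record_id = meta$record_id,
             channel = meta$channels[channel_index + 1L])
}

#' Write a WFDB record (format 212)
#'
#' Writes `.hea` and `.dat` files for one or two channels at gain 200
#' ADC units per mV, for round-tripping synthetic records through the WFDB
#' path. Voltages are quantised to the 12-bit ADC grid.
#'
#' @param signals An [ecg_signal] or list of them (equal lengths and rates).
#' @param dir Output directory.
#' @param record_id Record name; defaults to the first signal's.
#' @return The record path (without extension), invisibly.
#' @export
write_wfdb_record <- function(signals, dir, record_id = NULL) {
  if (inherits(signals, "ecg_signal")) signals <- list(signals)
  stopifnot(length(signals) >= 1,
            all(vapply(signals, inherits, logical(1), "ecg_signal")))
  fs <- signals[[1]]$fs
  n <- length(signals[[1]]$samples)
  if (!all(vapply(signals, function(s) s$fs == fs &&
                  length(s$samples) == n, logical(1)))) {
    stop("all signals must share length and sampling rate", call. = FALSE)
  }
  if (is.null(record_id)) record_id <- signals[[1]]$record_id
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gain <- 200
  adc <- lapply(signals, function(s) {
    v <- round(s$samples * gain)
    pmin(pmax(v, -2048), 2047)
  })
  nsig <- length(signals)
  inter <- integer(n * nsig)
  for (k in seq_len(nsig)) inter[seq(k, by = nsig, length.out = n)] <- adc[[k]]
  dat_name <- paste0(record_id, ".dat")
  writeBin(.pack_212(inter), file.path(dir, dat_name))
  hea <- c(sprintf("%s %d %g %d", record_id, nsig, fs, n),
           vapply(seq_len(nsig), function(k) {
             sprintf("%s 212 %d(0)/mV 12 0 %d 0 0 %s", dat_name, gain,
                     as.integer(adc[[k]][1]), signals[[k]]$channel)
           }, character(1)))
  writeLines(hea, file.path(dir, paste0(record_id, ".hea")))
  invisible(file.path(dir, record_id))
}

#' Read R-peak (beat) annotations from a MIT-format annotation file
#'
#' Decodes the MIT annotation byte stream (6-bit type code, 10-bit time
#' increment, with SKIP/NUM/SUB/CHN/AUX pseudo-codes handled) and keeps only
#' beat-type annotations; rhythm and signal-quality annotations are dropped.
#'
#' @param path Path to the annotation file (e.g. `record.atr`).
#' @param fs Sampling rate of the annotated signal, in Hz.
#' @return An [rpeak_annotation] of strictly increasing beat sample indices.
#' @export
read_rpeak_annotations <- function(path, fs) {
  if (!file.exists(path)) {
    stop("annotation file not found: ", path, call. = FALSE)
  }
  bytes <- as.integer(readBin(path, "raw", n = file.size(path)))
  i <- 1L
  t_now <- 0
  idx <- integer(0)
  codes <- integer(0)
  nb <- length(bytes)
  word_at <- function(j) bytes[j] + 256L * bytes[j + 1L]
  while (i + 1L <= nb) {
    w <- word_at(i)
    i <- i + 2L
    code <- w %/% 1024L
    tfield <- w %% 1024L
    if (code == 0L && tfield == 0L) break  # end of annotations
    if (code == 59L) {            # SKIP: 4-byte interval follows
      if (tfield == 0L) {
        if (i + 3L > nb) stop("truncated annotation file", call. = FALSE)
        hi <- word_at(i); lo <- word_at(i + 2L)
        i <- i + 4L
        delta <- hi * 65536 + lo
        if (delta >= 2^31) delta <- delta - 2^32
        t_now <- t_now + delta
      }
    } else if (code == 63L) {     # AUX: tfield bytes of payload, even-padded
      skip <- tfield + (tfield %% 2L)
      i <- i + skip
    } else if (code %in% c(60L, 61L, 62L)) {
      # NUM / SUB / CHN modifiers: no time advance, fields ignored
    } else {
      t_now <- t_now + tfield
      idx <- c(idx, t_now)
      codes <- c(codes, code)
    }
  }
  keep <- codes %in% .WFDB_BEAT_CODES
  rpeak_annotation(unique(sort(idx[keep])), fs)
}

#' Write R-peak annotations as a MIT-format annotation file
#'
#' Inverse of [read_rpeak_annotations()]: writes each peak as a NORMAL beat
#' annotation, emitting SKIP words for inter-annotation gaps beyond the
#' 10-bit time field.
#'
#' @param peaks An [rpeak_annotation].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rpeak_annotations <- function(peaks, path) {
  stopifnot(inherits(peaks, "rpeak_annotation"))
  deltas <- diff(c(0L, peaks$indices))
  words <- integer(0)
  for (d in deltas) {
    if (d > 1023L) {
      words <- c(words, 59L * 1024L, d %/% 65536, d %% 65536,
                 1L * 1024L + 0L)
    } else {
      words <- c(words, 1L * 1024L + d)
    }
  }
  words <- c(words, 0L)  # EOF word
  bytes <- as.raw(as.vector(rbind(words %% 256L, words %/% 256L)))
  writeBin(bytes, path)
  invisible(path)
}

#' Write detected peaks as CSV
#'
#' Two columns: `sample_index` (0-based) and `time_s = sample_index / fs`.
#'
#' @param peaks An [rpeak_annotation].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(peaks, path) {
  stopifnot(inherits(peaks, "rpeak_annotation"))
  df <- data.frame(sample_index = peaks$indices,
                   time_s = peaks$indices / peaks$fs)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a detections CSV written by [write_detections()]
#'
#' @param path CSV path with a `sample_index` column.
#' @param fs Sampling rate in Hz.
#' @return An [rpeak_annotation].
#' @export
read_detections <- function(path, fs) {
  df <- utils::read.csv(path)
  if (!"sample_index" %in% names(df)) {
    stop("detections file lacks a sample_index column", call. = FALSE)
  }
  rpeak_annotation(df$sample_index, fs)
}

#' Write an ECG signal as a flat CSV
#'
#' Two columns: `sample_index` (0-based) and `mV`.
#'
#' @param signal An [ecg_signal].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(signal, path) {
  stopifnot(inherits(signal, "ecg_signal"))
  df <- data.frame(sample_index = seq_along(signal$samples) - 1L,
                   mV = signal$samples)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ECG signal from a flat CSV
#'
#' @param path CSV with columns `sample_index` and `mV`.
#' @param fs Sampling rate in Hz.
#' @param record_id,channel Provenance strings for the result.
#' @return An [ecg_signal].
#' @export
read_signal_csv <- function(path, fs, record_id = "csv", channel = "I") {
  df <- utils::read.csv(path)
  if (!all(c("sample_index", "mV") %in% names(df))) {
    stop("signal CSV needs sample_index and mV columns", call. = FALSE)
  }
  if (nrow(df) > 1 && any(diff(df$sample_index) != 1)) {
    stop("signal CSV has gaps: refusing partial data", call. = FALSE)
  }
  ecg_signal(df$mV, fs, record_id = record_id, channel = channel)
}
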