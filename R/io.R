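# Interchange formats: CSV (one line per sample) and 16-bit EDF, plus the
# JSON ground-truth sidecar written next to generated recordings.

#' Write a signal record as CSV
#'
#' Columns `sample_index` (0-based), `eeg_left_uV`, `eeg_right_uV`,
#' `ecg_uV`, with a header row and one line per sample. The sampling rate
#' is not stored in the file; supply it again when reading.
#'
#' @param record A [signal_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(record, path) {
  stopifnot(inherits(record, "signal_record"))
  # %.17g keeps the full double precision so a write/read cycle is lossless
  df <- data.frame(
    sample_index = seq_len(n_samples(record)) - 1L,
    eeg_left_uV = sprintf("%.17g", record$eeg_left),
    eeg_right_uV = sprintf("%.17g", record$eeg_right),
    ecg_uV = sprintf("%.17g", record$ecg)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

pad_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)
}

#' Write a signal record as EDF
#'
#' Minimal single-patient European Data Format writer: 16-bit samples,
#' physical dimension uV, 1 s data records (the sampling rate must be a
#' whole number). A trailing partial second is dropped with a warning.
#' Channel labels are `EEG Left`, `EEG Right`, `ECG`.
#'
#' @param record A [signal_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_signal_edf <- function(record, path) {
  stopifnot(inherits(record, "signal_record"))
  fs <- record$fs
  if (fs != round(fs)) stop("EDF writer needs an integer sampling rate",
                            call. = FALSE)
  chans <- list(`EEG Left` = record$eeg_left,
                `EEG Right` = record$eeg_right,
                ECG = record$ecg)
  n_rec <- floor(n_samples(record) / fs)
  if (n_rec < 1) stop("recording shorter than one data record", call. = FALSE)
  if (n_rec * fs < n_samples(record)) {
    warning("dropping trailing partial second", call. = FALSE)
  }
  ns <- length(chans)
  pmax_ <- vapply(chans, function(x) max(abs(x), 1e-6) * 1.0001, numeric(1))
  con <- file(path, "wb")
  on.exit(close(con))
  wf <- function(x, w) writeChar(pad_field(x, w), con, eos = NULL)
  wf("0", 8)
  wf("X X X X", 80)                     # patient id
  wf("Startdate X X X X", 80)           # recording id
  wf("01.01.00", 8); wf("00.00.00", 8)  # date, time
  wf(256 * (ns + 1), 8)
  wf("", 44)
  wf(n_rec, 8)
  wf(1, 8)                              # record duration, s
  wf(ns, 4)
  for (nm in names(chans)) wf(nm, 16)
  for (i in seq_len(ns)) wf("", 80)     # transducer
  for (i in seq_len(ns)) wf("uV", 8)
  for (p in pmax_) wf(formatC(-p, format = "g", digits = 6), 8)
  for (p in pmax_) wf(formatC(p, format = "g", digits = 6), 8)
  for (i in seq_len(ns)) wf(-32768, 8)
  for (i in seq_len(ns)) wf(32767, 8)
  for (i in seq_len(ns)) wf("", 80)     # prefilter
  for (i in seq_len(ns)) wf(fs, 8)
  for (i in seq_len(ns)) wf("", 32)
  # re-read the physical bounds exactly as a reader will parse them, so the
  # digital<->physical mapping round-trips without printing error
  pmin_r <- as.numeric(formatC(-pmax_, format = "g", digits = 6))
  pmax_r <- as.numeric(formatC(pmax_, format = "g", digits = 6))
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(ns)) {
      scale <- (pmax_r[i] - pmin_r[i]) / 65535
      dig <- round((chans[[i]][idx] - pmin_r[i]) / scale) - 32768
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_edf_record <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rf <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rf(8); rf(80); rf(80); rf(8); rf(8)
  rf(8)                                  # header bytes
  rf(44)
  n_rec <- as.integer(rf(8))
  rec_dur <- as.numeric(rf(8))
  ns <- as.integer(rf(4))
  labels <- vapply(seq_len(ns), function(i) rf(16), character(1))
  for (i in seq_len(ns)) rf(80)
  dims <- vapply(seq_len(ns), function(i) rf(8), character(1))
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rf(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rf(8), character(1)))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rf(8), character(1)))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rf(8), character(1)))
  for (i in seq_len(ns)) rf(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rf(8), character(1)))
  for (i in seq_len(ns)) rf(32)
  out <- lapply(seq_len(ns), function(i) numeric(n_rec * spr[i]))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[i], size = 2, signed = TRUE,
                     endian = "little")
      scale <- (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i])
      out[[i]][((r - 1L) * spr[i] + 1L):(r * spr[i])] <-
        pmin_[i] + (dig - dmin_[i]) * scale
    }
  }
  names(out) <- labels
  list(channels = out, fs = spr / rec_dur, dims = dims)
}

#' Read a signal record from CSV or EDF
#'
#' CSV files must carry the columns written by [write_signal_csv()]; the
#' sampling rate is taken from `fs`. EDF files carry their own rate and
#' physical (uV) scaling; channels are resolved by label (`EEG Left`,
#' `EEG Right`, `ECG`, case-insensitive).
#'
#' @param path Input file.
#' @param format `"csv"`, `"edf"`, or `"auto"` (by file extension).
#' @param fs Sampling rate in Hz for CSV input (default 250).
#' @return A [signal_record()].
#' @export
read_signals <- function(path, format = c("auto", "csv", "edf"), fs = 250) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", edf = "edf",
                     stop("unsupported format: .", ext, call. = FALSE))
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv") {
    df <- utils::read.csv(path)
    need <- c("eeg_left_uV", "eeg_right_uV", "ecg_uV")
    missing_cols <- setdiff(need, names(df))
    if (length(missing_cols)) {
      stop("missing channel column(s): ", paste(missing_cols, collapse = ", "),
           call. = FALSE)
    }
    signal_record(df$eeg_left_uV, df$eeg_right_uV, df$ecg_uV, fs = fs)
  } else {
    edf <- read_edf_record(path)
    find_chan <- function(role) {
      hit <- which(tolower(names(edf$channels)) == tolower(role))
      if (!length(hit)) stop("channel role not found in EDF: ", role,
                             call. = FALSE)
      hit[1]
    }
    il <- find_chan("EEG Left"); ir <- find_chan("EEG Right")
    ie <- find_chan("ECG")
    if (length(unique(edf$fs[c(il, ir, ie)])) != 1) {
      stop("channels have inconsistent sampling rates", call. = FALSE)
    }
    signal_record(edf$channels[[il]], edf$channels[[ir]],
                  edf$channels[[ie]], fs = edf$fs[il])
  }
}

#' Write generator ground truth as a JSON sidecar
#'
#' @param truth A ground-truth list (from [generate_ecg()],
#'   [generate_eeg()], ...).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a ground-truth JSON sidecar
#' @param path JSON path written by [write_ground_truth()].
#' @return The ground-truth list.
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
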