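# Multichannel raw-signal container used throughout the pipeline.

#' Fixed-rate multichannel physiological recording
#'
#' Bundles the three channels produced by the wearable recorder (left EEG,
#' right EEG, head ECG), all in microvolts at a common sampling rate.
#'
#' @param eeg_left,eeg_right,ecg Numeric vectors of equal length, in uV.
#' @param fs Sampling rate in Hz.
#' @return An object of class `signal_record`: a list with elements
#'   `eeg_left`, `eeg_right`, `ecg` (numeric, uV) and `fs` (Hz).
#' @examples
#' rec <- signal_record(rnorm(500), rnorm(500), rnorm(500), fs = 250)
#' n_samples(rec)
#' @export
signal_record <- function(eeg_left, eeg_right, ecg, fs) {
  stopifnot(is.numeric(fs), length(fs) == 1L, fs > 0)
  n <- length(ecg)
  if (length(eeg_left) != n || length(eeg_right) != n) {
    stop("all channels must have the same length", call. = FALSE)
  }
  structure(
    list(
      eeg_left = as.numeric(eeg_left),
      eeg_right = as.numeric(eeg_right),
      ecg = as.numeric(ecg),
      fs = as.numeric(fs)
    ),
    class = "signal_record"
  )
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf(
    "<signal_record> %d samples (%.1f s) at %g Hz, channels: eeg_left, eeg_right, ecg\n",
    n_samples(x), n_samples(x) / x$fs, x$fs
  ))
  invisible(x)
}

#' Number of samples in a signal record
#' @param record A [signal_record()].
#' @return Integer sample count.
#' @export
n_samples <- function(record) {
  stopifnot(inherits(record, "signal_record"))
  length(record$ecg)
}

#' Extract a time slice of a recording
#'
#' Half-open interval `[start, start + duration)` in seconds, at sample
#' resolution: sample `i` (0-based) belongs to the slice when
#' `start <= i / fs < start + duration`.
#'
#' @param record A [signal_record()].
#' @param start Slice start in seconds (>= 0).
#' @param duration Slice length in seconds (> 0).
#' @return A [signal_record()] covering the requested window.
#' @export
slice_record <- function(record, start, duration) {
  stopifnot(inherits(record, "signal_record"), start >= 0, duration > 0)
  fs <- record$fs
  i0 <- ceiling(start * fs - 1e-9) + 1L        # first sample with t >= start
  i1 <- ceiling((start + duration) * fs - 1e-9) # last sample with t < start+duration
  if (i1 > n_samples(record)) {
    stop(sprintf(
      "slice [%g, %g) extends past the recording end (%.2f s)",
      start, start + duration, n_samples(record) / fs
    ), call. = FALSE)
  }
  signal_record(
    record$eeg_left[i0:i1], record$eeg_right[i0:i1], record$ecg[i0:i1],
    fs = fs
  )
}

# Run expr under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
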