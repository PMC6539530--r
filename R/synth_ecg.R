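# Template-based synthetic head ECG with exact R-peak ground truth.

# Biphasic "Mexican hat" QRS template evaluated at lag tau (s): a sharp
# positive R deflection flanked by negative lobes (Q/S-like), unit peak.
qrs_template <- function(tau, sigma) {
  (1 - (tau / sigma)^2) * exp(-tau^2 / (2 * sigma^2))
}

#' Generate a synthetic head-scale ECG from beat times
#'
#' Renders a biphasic QRS waveform (Mexican-hat pulse with a single sharp R
#' maximum) at each beat time, plus white Gaussian noise. Template centers
#' are snapped to the sample grid, so each ground-truth R-peak sample
#' coincides with the requested beat time to within half a sample and, in
#' the noiseless case, is an exact local maximum of value `qrs_amp`.
#'
#' @param beat_times Beat times in seconds (non-negative, strictly
#'   increasing); may be empty, giving a noise-only record.
#' @param qrs_amp R-peak amplitude in uV (> 0). Head ECG is ~25 uV.
#' @param noise_sd White noise standard deviation in uV (>= 0).
#' @param fs Sampling rate in Hz (>= 100).
#' @param duration Record length in seconds; defaults to the last beat time
#'   plus 0.5 s.
#' @param qrs_width Full width of the QRS wavelet support in seconds
#'   (default 0.1); the positive R lobe is about one fifth of this.
#' @param t_amp Optional T-wave amplitude in uV (half-sine bump, 160 ms wide,
#'   centered 300 ms after each R-peak). Default 0.
#' @param seed Integer RNG seed for the noise.
#' @return A list with elements:
#'   * `record` - a [signal_record()] whose `ecg` channel holds the signal
#'     (EEG channels are zero),
#'   * `truth` - list with `r_peak_indices` (1-based sample indices),
#'     `r_peak_times` (s) and the generation parameters.
#' @examples
#' rr <- generate_rr_series(rr_spec(mean_rr = 800, duration = 24))
#' ecg <- generate_ecg(rr$beat_times, qrs_amp = 25, noise_sd = 0)
#' length(ecg$truth$r_peak_indices)
#' @export
generate_ecg <- function(beat_times, qrs_amp = 25, noise_sd = 0, fs = 250,
                         duration = NULL, qrs_width = 0.1, t_amp = 0,
                         seed = 1L) {
  stopifnot(fs >= 100, qrs_amp > 0, noise_sd >= 0, qrs_width > 0)
  if (length(beat_times) > 0) {
    stopifnot(all(beat_times >= 0), !is.unsorted(beat_times, strictly = TRUE))
  }
  if (is.null(duration)) {
    duration <- if (length(beat_times)) max(beat_times) + 0.5 else 1
  }
  n <- ceiling(duration * fs)
  x <- numeric(n)
  sigma <- qrs_width / 10
  half <- ceiling(5 * sigma * fs)
  tmpl <- qrs_template((-half:half) / fs, sigma)
  peak_idx <- integer(0)
  if (length(beat_times)) {
    peak_idx <- pmin(pmax(round(beat_times * fs) + 1L, 1L), n)
    for (c0 in peak_idx) {
      lo <- max(1L, c0 - half)
      hi <- min(n, c0 + half)
      x[lo:hi] <- x[lo:hi] + qrs_amp * tmpl[(lo - c0 + half + 1L):(hi - c0 + half + 1L)]
    }
    if (t_amp > 0) {
      t_half <- round(0.08 * fs)
      t_wave <- t_amp * sin(pi * seq(0, 1, length.out = 2L * t_half + 1L))
      for (c0 in peak_idx) {
        ct <- c0 + round(0.3 * fs)
        lo <- max(1L, ct - t_half)
        hi <- min(n, ct + t_half)
        if (lo <= hi) {
          x[lo:hi] <- x[lo:hi] + t_wave[(lo - ct + t_half + 1L):(hi - ct + t_half + 1L)]
        }
      }
    }
  }
  if (noise_sd > 0) {
    x <- x + with_seed(seed, stats::rnorm(n, 0, noise_sd))
  }
  list(
    record = signal_record(numeric(n), numeric(n), x, fs = fs),
    truth = list(
      r_peak_indices = peak_idx,
      r_peak_times = (peak_idx - 1L) / fs,
      qrs_amp = qrs_amp, noise_sd = noise_sd, fs = fs,
      qrs_width = qrs_width, seed = as.integer(seed)
    )
  )
}
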