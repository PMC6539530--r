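# Time- and frequency-domain heart rate variability features.

intervals_of <- function(rr) {
  if (inherits(rr, "rr_series")) rr$intervals else as.numeric(rr)
}

#' Time-domain HRV features
#'
#' For intervals `RR_1..RR_N`:
#' `mRR = sum(RR_i)/N`, `SDRR = sqrt(sum((RR_i - mRR)^2)/(N-1))`,
#' `RMSSD = sqrt(sum((RR_{i+1} - RR_i)^2)/(N-1))`.
#'
#' @param rr An [rr_series()] or a numeric vector of R-R intervals in ms.
#' @return Named numeric vector `c(mRR, SDRR, RMSSD)` in ms.
#' @examples
#' time_domain_features(c(800, 810, 790))
#' @export
time_domain_features <- function(rr) {
  iv <- intervals_of(rr)
  n <- length(iv)
  if (n < 2) stop("need at least 2 R-R intervals", call. = FALSE)
  m <- sum(iv) / n
  c(
    mRR = m,
    SDRR = sqrt(sum((iv - m)^2) / (n - 1)),
    RMSSD = sqrt(sum(diff(iv)^2) / (n - 1))
  )
}

#' Resample an R-R series to a uniform tachogram
#'
#' Linearly interpolates the (beat time, interval) pairs — each interval
#' anchored at the time of the beat that closes it — onto a uniform grid
#' from the first to the last peak time. Values before the second beat are
#' held constant (no interval is defined there yet). The mean is *not*
#' removed here; [hrv_spectrum()] removes it before the FFT.
#'
#' @param rr An [rr_series()].
#' @param rate Resampling rate in Hz (default 2).
#' @return A list with `time` (s), `rr` (ms) and `rate` (Hz).
#' @export
resample_rr <- function(rr, rate = 2) {
  stopifnot(inherits(rr, "rr_series"), rate > 0)
  if (length(rr$intervals) < 2) {
    stop("need at least 2 R-R intervals", call. = FALSE)
  }
  grid <- seq(rr$peak_times[1], rr$peak_times[length(rr$peak_times)],
              by = 1 / rate)
  vals <- stats::approx(rr$peak_times[-1], rr$intervals, xout = grid,
                        method = "linear", rule = 2)$y
  list(time = grid, rr = vals, rate = rate)
}

#' HRV power spectrum of a uniformly resampled tachogram
#'
#' Single periodogram (squared FFT magnitude, one-sided density in ms^2/Hz)
#' of the mean-removed tachogram. LF power integrates the density over
#' `[0.04, 0.15)` Hz, HF over `[0.15, 0.4]` Hz, and total power over
#' `(0, 1]` Hz with DC excluded (so the very-low-frequency region below
#' 0.04 Hz counts toward the total).
#'
#' @param tachogram Output of [resample_rr()].
#' @param lf_band,hf_band LF and HF band edges in Hz.
#' @param total_band Upper edge of the total-power integration range in Hz.
#' @return An object of class `hrv_spectrum`: list with `frequencies` (Hz),
#'   `density` (ms^2/Hz), `rate`, `total_power`, `lf_power`, `hf_power`
#'   (all ms^2).
#' @export
hrv_spectrum <- function(tachogram, lf_band = c(0.04, 0.15),
                         hf_band = c(0.15, 0.4), total_band = 1.0) {
  x <- tachogram$rr
  fs <- tachogram$rate
  n <- length(x)
  if (n < 64) stop("tachogram too short: need >= 64 samples", call. = FALSE)
  x <- x - mean(x)
  xf <- stats::fft(x)
  k <- seq_len(floor(n / 2))          # DC excluded
  freqs <- k * fs / n
  dens <- 2 * Mod(xf[k + 1L])^2 / (n * fs)
  if (n %% 2 == 0) dens[length(dens)] <- dens[length(dens)] / 2  # Nyquist
  df <- fs / n
  band_sum <- function(lo, hi, closed_hi = TRUE) {
    sel <- freqs >= lo & (if (closed_hi) freqs <= hi else freqs < hi)
    sum(dens[sel]) * df
  }
  structure(
    list(
      frequencies = freqs, density = dens, rate = fs,
      total_power = band_sum(df / 2, total_band),
      lf_power = band_sum(lf_band[1], lf_band[2], closed_hi = FALSE),
      hf_power = band_sum(hf_band[1], hf_band[2])
    ),
    class = "hrv_spectrum"
  )
}

#' Normalized frequency-domain HRV features
#'
#' `nLF_HRV = 100 * lf / total`, `nHF_HRV = 100 * hf / total` (percent of
#' total power), and `LF_HF = 100 * nLF_HRV / nHF_HRV`. The ratio is
#' reported on a x100 scale so its magnitude matches the reference cohort's
#' published values; when HF power is zero the ratio is undefined and is
#' returned as `NA` with a warning.
#'
#' @param spectrum An [hrv_spectrum()].
#' @return Named numeric vector `c(nLF_HRV, nHF_HRV, LF_HF)`.
#' @export
frequency_features <- function(spectrum) {
  stopifnot(inherits(spectrum, "hrv_spectrum"))
  if (spectrum$total_power <= 0) {
    stop("total power must be positive", call. = FALSE)
  }
  nlf <- 100 * spectrum$lf_power / spectrum$total_power
  nhf <- 100 * spectrum$hf_power / spectrum$total_power
  lfhf <- if (nhf > 0) 100 * nlf / nhf else {
    warning("HF power is zero; LF/HF undefined", call. = FALSE)
    NA_real_
  }
  c(nLF_HRV = nlf, nHF_HRV = nhf, LF_HF = lfhf)
}

#' All six HRV features of one segment
#'
#' Convenience wrapper: time-domain features from the raw intervals plus
#' frequency-domain features from the 2 Hz resampled tachogram.
#'
#' @param rr An [rr_series()].
#' @param rate Tachogram resampling rate in Hz (default 2).
#' @return Named numeric vector of the six HRV features.
#' @export
hrv_features <- function(rr, rate = 2) {
  td <- time_domain_features(rr)
  fd <- frequency_features(hrv_spectrum(resample_rr(rr, rate = rate)))
  c(td, fd)
}
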