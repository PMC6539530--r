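# EEG cleaning (band-pass + amplitude-threshold EOG rejection) and the
# eight band-power / hemispheric-asymmetry features.

#' Band-pass filter the EEG channels
#'
#' Zero-phase Butterworth band-pass (default 1-35 Hz, order 4 applied
#' forward and backward) on both EEG channels; the ECG channel is left
#' untouched.
#'
#' @param record A [signal_record()].
#' @param band Pass-band edges in Hz.
#' @param order Butterworth order (per direction).
#' @return A filtered [signal_record()].
#' @export
bandpass_eeg <- function(record, band = c(1, 35), order = 4) {
  stopifnot(inherits(record, "signal_record"))
  fs <- record$fs
  if (fs <= 2 * band[2]) stop("sampling rate too low for the pass band",
                              call. = FALSE)
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  signal_record(
    as.numeric(signal::filtfilt(bf, record$eeg_left)),
    as.numeric(signal::filtfilt(bf, record$eeg_right)),
    record$ecg,
    fs = fs
  )
}

#' Reject EOG-contaminated epochs by amplitude threshold
#'
#' Splits the recording into non-overlapping epochs and rejects every epoch
#' in which either EEG channel exceeds the threshold in absolute value —
#' large deflections are assumed to be eye-movement (EOG) artifacts. Both
#' channels share one mask, since the asymmetry features need paired data.
#'
#' @param record A (filtered) [signal_record()].
#' @param threshold Rejection threshold in uV (default 100).
#' @param epoch_len Epoch length in seconds (default 1).
#' @return An object of class `epoch_mask`: list with `epoch_len`, `keep`
#'   (logical per epoch; the last, possibly partial, epoch included) and
#'   `cause` (character, `""` or `"amplitude"`).
#' @export
reject_eog <- function(record, threshold = 100, epoch_len = 1) {
  stopifnot(inherits(record, "signal_record"), threshold > 0, epoch_len > 0)
  fs <- record$fs
  n <- n_samples(record)
  m <- round(epoch_len * fs)
  n_ep <- ceiling(n / m)
  keep <- logical(n_ep)
  cause <- character(n_ep)
  for (e in seq_len(n_ep)) {
    idx <- ((e - 1L) * m + 1L):min(e * m, n)
    bad <- max(abs(record$eeg_left[idx]), abs(record$eeg_right[idx])) > threshold
    keep[e] <- !bad
    cause[e] <- if (bad) "amplitude" else ""
  }
  if (!any(keep)) stop("no clean data: every epoch exceeds the threshold",
                       call. = FALSE)
  structure(list(epoch_len = epoch_len, keep = keep, cause = cause),
            class = "epoch_mask")
}

hann_window <- function(m) 0.5 - 0.5 * cos(2 * pi * (0:(m - 1)) / (m - 1))

# One-sided Hann-tapered periodogram density (uV^2/Hz), DC excluded.
epoch_periodogram <- function(x, fs, w, u) {
  x <- (x - mean(x)) * w
  xf <- stats::fft(x)
  n <- length(x)
  k <- seq_len(floor(n / 2))
  dens <- 2 * Mod(xf[k + 1L])^2 / (fs * u)
  if (n %% 2 == 0) dens[length(dens)] <- dens[length(dens)] / 2
  dens
}

#' Absolute EEG band powers from clean epochs
#'
#' Welch-style spectral estimate restricted to artifact-free data: Hann
#' windows spanning `window_epochs` consecutive *clean* rejection epochs
#' (stepped one epoch at a time, so neighboring windows overlap) are
#' mean-removed, tapered, and their periodograms averaged. Windows never
#' bridge a rejected epoch — splicing across gaps would smear the
#' discontinuities into broadband leakage — and multi-epoch windows keep
#' the frequency resolution fine enough that adjacent bands do not bleed
#' into each other. Band power integrates the averaged density over
#' `[lo, hi)`; total power over the analysis band `[1, 35)` Hz.
#'
#' @param record A (filtered) [signal_record()].
#' @param mask An [reject_eog()] mask; `NULL` keeps all epochs.
#' @param bands Band definition data.frame (default [eeg_bands()]).
#' @param total_band Total-power integration range in Hz.
#' @param window_epochs Clean epochs per Welch window (default 8, i.e. 8 s
#'   windows and 0.125 Hz resolution with 1 s epochs; fewer are used when
#'   fewer clean epochs exist).
#' @return A list of class `eeg_band_powers`: `left` and `right` named
#'   vectors of band powers (uV^2), `total_left`, `total_right`,
#'   `n_epochs_used`, `n_windows`, `frequencies`, `density_left`,
#'   `density_right`.
#' @export
band_powers <- function(record, mask = NULL, bands = eeg_bands(),
                        total_band = c(1, 35), window_epochs = 8) {
  stopifnot(inherits(record, "signal_record"))
  fs <- record$fs
  n <- n_samples(record)
  if (is.null(mask)) {
    m <- round(1 * fs)
    keep <- rep(TRUE, ceiling(n / m))
  } else {
    stopifnot(inherits(mask, "epoch_mask"))
    keep <- mask$keep
    m <- round(mask$epoch_len * fs)
  }
  full <- keep & (seq_along(keep) * m <= n)  # drop partial tail epoch
  if (sum(full) < 8) {
    stop("insufficient clean epochs: need >= 8", call. = FALSE)
  }
  # window start epochs: runs of `window_epochs` consecutive clean epochs
  we <- min(window_epochs, sum(full))
  starts <- which(vapply(seq_len(length(full) - we + 1L),
                         function(s) all(full[s:(s + we - 1L)]), logical(1)))
  if (!length(starts)) {
    stop("no run of ", we, " consecutive clean epochs", call. = FALSE)
  }
  mw <- m * we
  w <- hann_window(mw)
  u <- sum(w^2)
  k <- seq_len(floor(mw / 2))
  freqs <- k * fs / mw
  dl <- numeric(length(k))
  dr <- numeric(length(k))
  for (s in starts) {
    idx <- ((s - 1L) * m + 1L):((s - 1L + we) * m)
    dl <- dl + epoch_periodogram(record$eeg_left[idx], fs, w, u)
    dr <- dr + epoch_periodogram(record$eeg_right[idx], fs, w, u)
  }
  dl <- dl / length(starts)
  dr <- dr / length(starts)
  df <- fs / mw
  integrate_band <- function(dens, lo, hi) sum(dens[freqs >= lo & freqs < hi]) * df
  pl <- vapply(seq_len(nrow(bands)),
               function(i) integrate_band(dl, bands$lo[i], bands$hi[i]),
               numeric(1))
  pr <- vapply(seq_len(nrow(bands)),
               function(i) integrate_band(dr, bands$lo[i], bands$hi[i]),
               numeric(1))
  names(pl) <- names(pr) <- bands$name
  structure(
    list(
      left = pl, right = pr,
      total_left = integrate_band(dl, total_band[1], total_band[2]),
      total_right = integrate_band(dr, total_band[1], total_band[2]),
      n_epochs_used = sum(full),
      n_windows = length(starts),
      frequencies = freqs, density_left = dl, density_right = dr
    ),
    class = "eeg_band_powers"
  )
}

#' The eight EEG features from band powers
#'
#' Normalized band powers `nLAP = 100 * alpha_L / total_L` (likewise nRAP,
#' nLBP, nRBP), and per-band asymmetries
#' `100 * (P_R - P_L) / (P_R + P_L)` computed on *normalized* band powers
#' (percent of each channel's total), so inter-channel gain differences
#' cancel. Asymmetries are reported on a -100..100 scale.
#'
#' @param bp An [band_powers()] result.
#' @return Named numeric vector
#'   `c(nLAP, nRAP, nLBP, nRBP, DPA, TPA, APA, BPA)`.
#' @export
eeg_feature_vector <- function(bp) {
  stopifnot(inherits(bp, "eeg_band_powers"))
  if (bp$total_left <= 0 || bp$total_right <= 0) {
    stop("total power must be positive in both channels", call. = FALSE)
  }
  nl <- 100 * bp$left / bp$total_left    # normalized band powers, left
  nr <- 100 * bp$right / bp$total_right  # and right
  asym <- vapply(c("delta", "theta", "alpha", "beta"), function(b) {
    s <- nr[[b]] + nl[[b]]
    if (s <= 0) {
      warning("zero band power in both channels; ", b,
              " asymmetry undefined", call. = FALSE)
      return(NA_real_)
    }
    100 * (nr[[b]] - nl[[b]]) / s
  }, numeric(1))
  c(
    nLAP = nl[["alpha"]], nRAP = nr[["alpha"]],
    nLBP = nl[["beta"]], nRBP = nr[["beta"]],
    DPA = asym[["delta"]], TPA = asym[["theta"]],
    APA = asym[["alpha"]], BPA = asym[["beta"]]
  )
}

#' All eight EEG features of one segment
#'
#' Convenience wrapper: band-pass filter, EOG rejection, Welch band powers,
#' feature vector.
#'
#' @param record A raw [signal_record()].
#' @param band Analysis band in Hz (default `c(1, 35)`).
#' @param threshold EOG rejection threshold in uV (default 100).
#' @param epoch_len Epoch length in seconds (default 1).
#' @param window_epochs Clean epochs per Welch window (see [band_powers()]).
#' @return Named numeric vector of the eight EEG features, with the epoch
#'   counts attached as attributes `n_epochs_used` and `n_epochs_total`.
#' @export
eeg_features <- function(record, band = c(1, 35), threshold = 100,
                         epoch_len = 1, window_epochs = 8) {
  filt <- bandpass_eeg(record, band = band)
  mask <- reject_eog(filt, threshold = threshold, epoch_len = epoch_len)
  bp <- band_powers(filt, mask, total_band = band, window_epochs = window_epochs)
  out <- eeg_feature_vector(bp)
  attr(out, "n_epochs_used") <- bp$n_epochs_used
  attr(out, "n_epochs_total") <- length(mask$keep)
  out
}
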