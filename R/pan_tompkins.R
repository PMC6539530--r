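# Pan-Tompkins QRS detection for low-amplitude head ECG.
#
# Classic stage chain: band-pass (5-15 Hz) -> five-point derivative ->
# squaring -> 150 ms moving-window integration -> dual adaptive thresholds
# on the integrated and filtered signals with running signal/noise peak
# estimates, a 200 ms refractory period, T-wave rejection inside 360 ms,
# and search-back at 166% of the running RR average. Offline use permits
# zero-phase filtering, so no group-delay bookkeeping is needed and peak
# times are finalized on the raw signal.

#' Ordered R-peak series
#'
#' @param peak_indices Strictly increasing 1-based sample indices.
#' @param fs Sampling rate in Hz.
#' @return An object of class `rr_series`: list with `peak_indices`,
#'   `peak_times` (s), `intervals` (ms, one fewer than the peaks) and `fs`.
#' @export
rr_series <- function(peak_indices, fs) {
  stopifnot(fs > 0)
  peak_indices <- as.integer(peak_indices)
  if (length(peak_indices) >= 2 &&
      is.unsorted(peak_indices, strictly = TRUE)) {
    stop("peak indices must be strictly increasing", call. = FALSE)
  }
  times <- (peak_indices - 1L) / fs
  structure(
    list(peak_indices = peak_indices, peak_times = times,
         intervals = diff(times) * 1000, fs = fs),
    class = "rr_series"
  )
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d peaks, %d intervals, mean RR %.1f ms\n",
              length(x$peak_indices), length(x$intervals),
              mean(x$intervals)))
  invisible(x)
}

# Local maxima (strict left, non-strict right so plateaus yield one peak).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Detect R-peaks with the Pan-Tompkins algorithm
#'
#' @param record A [signal_record()]; detection runs on the `ecg` channel
#'   unless `channel` says otherwise.
#' @param channel Channel name to analyze (default `"ecg"`).
#' @param band Detection band-pass edges in Hz (default `c(5, 15)`).
#' @param integration_window Moving-window integration length in seconds
#'   (default 0.15).
#' @param refractory Minimum distance between QRS detections in seconds
#'   (default 0.2).
#' @param t_wave_window Candidates closer than this to the previous QRS are
#'   checked for T-wave morphology via the slope rule (default 0.36 s).
#' @param update_accept,update_searchback Exponential-update coefficients
#'   for accepted peaks in the running signal estimate (defaults 0.125 and
#'   0.25 as in the original description; noise peaks use `update_accept`).
#' @param threshold_frac Position of the detection threshold between the
#'   running noise and signal peak levels (default 0.25).
#' @param searchback_factor Search-back triggers when the current RR exceeds
#'   this multiple of the running 8-beat RR average (default 1.66).
#' @param refine_window Half-width, in seconds, of the raw-signal window in
#'   which each detection is refined to the local absolute maximum
#'   (default 0.04).
#' @return An [rr_series()].
#' @examples
#' rr <- generate_rr_series(rr_spec(mean_rr = 800, duration = 30))
#' ecg <- generate_ecg(rr$beat_times, qrs_amp = 25, noise_sd = 2, seed = 2)
#' detect_r_peaks(ecg$record)
#' @export
detect_r_peaks <- function(record, channel = "ecg",
                           band = c(5, 15),
                           integration_window = 0.15,
                           refractory = 0.2,
                           t_wave_window = 0.36,
                           update_accept = 0.125,
                           update_searchback = 0.25,
                           threshold_frac = 0.25,
                           searchback_factor = 1.66,
                           refine_window = 0.04) {
  stopifnot(inherits(record, "signal_record"))
  fs <- record$fs
  if (fs < 100) stop("sampling rate must be >= 100 Hz", call. = FALSE)
  x <- record[[channel]]
  if (is.null(x)) stop("unknown channel: ", channel, call. = FALSE)
  n <- length(x)
  if (n < 10 * fs) {
    stop("segment too short: need >= 10 s for threshold adaptation",
         call. = FALSE)
  }

  # --- stage chain -----------------------------------------------------
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  filt <- as.numeric(signal::filtfilt(bf, x))
  # centered five-point derivative, zero delay
  d <- stats::filter(filt, c(1, 2, 0, -2, -1) / 8, sides = 2)
  d[is.na(d)] <- 0
  sq <- as.numeric(d)^2
  nw <- max(3L, round(integration_window * fs))
  mwi <- stats::filter(sq, rep(1 / nw, nw), sides = 2)
  mwi[is.na(mwi)] <- 0
  mwi <- as.numeric(mwi)
  afilt <- abs(filt)

  cand <- local_maxima(mwi)
  cand <- cand[mwi[cand] > 0]
  if (length(cand) < 2) stop("insufficient beats", call. = FALSE)

  half_w <- round(integration_window * fs)
  peakf_at <- function(i) {
    max(afilt[max(1L, i - half_w):min(n, i + half_w)])
  }
  # fiducial mark: the filtered-signal peak near an integrated-signal
  # candidate (the MWI maximum is a plateau, so it localizes poorly)
  fiducial_at <- function(i) {
    lo <- max(1L, i - half_w)
    as.integer(lo + which.max(afilt[lo:min(n, i + half_w)]) - 1L)
  }
  slope_at <- function(i) {
    max(abs(as.numeric(d)[max(1L, i - half_w):min(n, i + half_w)]))
  }

  # --- initialization from the first 2 s -------------------------------
  init <- seq_len(min(n, 2L * round(fs)))
  spki <- max(mwi[init]); npki <- mean(mwi[init]) / 2
  spkf <- max(afilt[init]); npkf <- mean(afilt[init]) / 2

  thr_i <- function() npki + threshold_frac * (spki - npki)
  thr_f <- function() npkf + threshold_frac * (spkf - npkf)

  qrs <- integer(0)
  qrs_slope <- numeric(0)
  rr_hist <- numeric(0)
  pending <- integer(0)   # candidates since the last accepted QRS

  accept <- function(i, searchback = FALSE) {
    a <- if (searchback) update_searchback else update_accept
    spki <<- a * mwi[i] + (1 - a) * spki
    spkf <<- a * peakf_at(i) + (1 - a) * spkf
  }

  for (i in cand) {
    if (length(qrs)) {
      dt <- (fiducial_at(i) - qrs[length(qrs)]) / fs
      if (dt < refractory) next
      if (dt < t_wave_window &&
          slope_at(i) < 0.5 * qrs_slope[length(qrs_slope)]) {
        # T-wave: treat as noise
        npki <- update_accept * mwi[i] + (1 - update_accept) * npki
        npkf <- update_accept * peakf_at(i) + (1 - update_accept) * npkf
        pending <- c(pending, i)
        next
      }
    }
    if (mwi[i] > thr_i() && peakf_at(i) > thr_f()) {
      fi <- fiducial_at(i)
      if (length(qrs)) {
        rr <- (fi - qrs[length(qrs)]) / fs
        rr_avg <- mean(utils::tail(rr_hist, 8))
        if (length(rr_hist) >= 2 && rr > searchback_factor * rr_avg &&
            length(pending)) {
          # search-back: rescan skipped candidates at half threshold
          ok <- pending[mwi[pending] > thr_i() / 2]
          sbf <- vapply(ok, fiducial_at, integer(1))
          keep_sb <- (sbf - qrs[length(qrs)]) / fs >= refractory &
            (fi - sbf) / fs >= refractory
          ok <- ok[keep_sb]; sbf <- sbf[keep_sb]
          if (length(ok)) {
            j <- which.max(mwi[ok])
            accept(ok[j], searchback = TRUE)
            rr_hist <- c(rr_hist, (sbf[j] - qrs[length(qrs)]) / fs)
            qrs <- c(qrs, sbf[j])
            qrs_slope <- c(qrs_slope, slope_at(sbf[j]))
            rr <- (fi - sbf[j]) / fs
          }
        }
        rr_hist <- c(rr_hist, rr)
      }
      accept(i)
      qrs <- c(qrs, fi)
      qrs_slope <- c(qrs_slope, slope_at(i))
      pending <- integer(0)
    } else {
      npki <- update_accept * mwi[i] + (1 - update_accept) * npki
      npkf <- update_accept * peakf_at(i) + (1 - update_accept) * npkf
      pending <- c(pending, i)
    }
  }

  if (length(qrs) < 2) stop("insufficient beats", call. = FALSE)

  # --- refinement: local raw-signal maximum magnitude ------------------
  rw <- round(refine_window * fs)
  refined <- vapply(qrs, function(i) {
    lo <- max(1L, i - rw); hi <- min(n, i + rw)
    seg <- x[lo:hi]
    as.integer(lo + which.max(abs(seg - stats::median(seg))) - 1L)
  }, integer(1))
  refined <- sort(unique(refined))
  rr_series(refined, fs)
}
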