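# Synthetic two-channel EEG as a sum of band-limited noise processes,
# with optional EOG-like artifacts and exact band-power ground truth.

#' Standard EEG band definitions
#'
#' Half-open frequency bands `[lo, hi)`: delta `[1, 4)`, theta `[4, 8)`,
#' alpha `[8, 13)`, beta `[13, 30)` Hz. Delta and theta edges are the
#' conventional clinical choices; alpha and beta match the feature
#' definitions used throughout the package.
#'
#' @return A data.frame with columns `name`, `lo`, `hi` (Hz).
#' @export
eeg_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta"),
    lo = c(1, 4, 8, 13),
    hi = c(4, 8, 13, 30),
    stringsAsFactors = FALSE
  )
}

#' Specification of a synthetic two-channel EEG
#'
#' Each channel is a sum over bands of band-limited Gaussian noise scaled to
#' a prescribed variance, optionally contaminated by EOG-like half-sine
#' deflections shared by both channels.
#'
#' @param band_power Named list mapping band name (see [eeg_bands()]) to a
#'   length-2 numeric `c(left, right)` of variances in uV^2 (>= 0). Bands
#'   omitted from the list contribute nothing.
#' @param eog_rate EOG event rate in events per minute (>= 0).
#' @param eog_amp EOG deflection amplitude in uV; must exceed 100 uV when
#'   `eog_rate > 0` so the artifacts are detectable by the amplitude rule.
#' @param duration Record length in seconds.
#' @param seed Integer RNG seed.
#' @return A list of class `eeg_spec`.
#' @export
eeg_spec <- function(band_power, eog_rate = 0, eog_amp = 300,
                     duration = 360, seed = 1L) {
  known <- eeg_bands()$name
  stopifnot(is.list(band_power), length(band_power) > 0, duration > 0,
            eog_rate >= 0)
  if (!all(names(band_power) %in% known)) {
    stop("unknown band name(s): ",
         paste(setdiff(names(band_power), known), collapse = ", "),
         call. = FALSE)
  }
  for (bp in band_power) {
    stopifnot(length(bp) == 2L, all(bp >= 0))
  }
  if (eog_rate > 0 && eog_amp <= 100) {
    stop("eog_amp must exceed 100 uV when eog_rate > 0", call. = FALSE)
  }
  structure(
    list(band_power = band_power, eog_rate = eog_rate, eog_amp = eog_amp,
         duration = duration, seed = as.integer(seed)),
    class = "eeg_spec"
  )
}

# Band-limited Gaussian noise, rescaled exactly to `target` variance.
# Synthesized in the frequency domain (white noise passed through an ideal
# brick-wall band-pass), so all power lies strictly inside [lo, hi).
band_noise <- function(n, lo, hi, fs, target) {
  if (target <= 0) return(numeric(n))
  xf <- stats::fft(stats::rnorm(n))
  freqs <- (seq_len(n) - 1L) * fs / n
  fold <- pmin(freqs, fs - freqs)  # two-sided frequency magnitude
  xf[fold < lo | fold >= hi] <- 0i
  x <- Re(stats::fft(xf, inverse = TRUE)) / n
  x * sqrt(target / stats::var(x))
}

#' Generate a synthetic two-channel EEG record
#'
#' Each channel is built as a sum over bands of white Gaussian noise
#' band-pass filtered to the band and rescaled so its sample variance equals
#' the requested variance exactly (the realized variances recorded as ground
#' truth therefore equal the spec). EOG events are half-sine deflections of
#' 0.5 s duration and amplitude `eog_amp`, Poisson-placed at `eog_rate` and
#' added to both channels (eye movements project to both electrodes).
#'
#' @param spec An [eeg_spec()].
#' @param fs Sampling rate in Hz; must be at least twice the highest band
#'   edge used.
#' @return A list with elements:
#'   * `record` - a [signal_record()] (ECG channel zero),
#'   * `truth` - list with `band_power` (realized per-band variances,
#'     left/right), `asymmetry` (per band, `(R - L)/(R + L)` on absolute
#'     powers), `eog_times` (event centers, s), spec echo.
#' @export
generate_eeg <- function(spec, fs = 250) {
  stopifnot(inherits(spec, "eeg_spec"))
  bands <- eeg_bands()
  used <- bands[bands$name %in% names(spec$band_power), , drop = FALSE]
  if (fs < 2 * max(used$hi)) {
    stop("fs must be at least twice the highest band edge", call. = FALSE)
  }
  n <- ceiling(spec$duration * fs)
  out <- with_seed(spec$seed, {
    left <- numeric(n)
    right <- numeric(n)
    realized <- list()
    for (b in used$name) {
      lo <- bands$lo[bands$name == b]
      hi <- bands$hi[bands$name == b]
      tgt <- spec$band_power[[b]]
      l <- band_noise(n, lo, hi, fs, tgt[1])
      r <- band_noise(n, lo, hi, fs, tgt[2])
      left <- left + l
      right <- right + r
      realized[[b]] <- c(
        left = if (tgt[1] > 0) stats::var(l) else 0,
        right = if (tgt[2] > 0) stats::var(r) else 0
      )
    }
    eog_times <- numeric(0)
    if (spec$eog_rate > 0) {
      n_ev <- stats::rpois(1, spec$eog_rate * spec$duration / 60)
      if (n_ev > 0) {
        eog_times <- sort(stats::runif(n_ev, 0.5, spec$duration - 0.5))
        half <- round(0.25 * fs)
        pulse <- spec$eog_amp * sin(pi * seq(0, 1, length.out = 2L * half + 1L))
        for (tc in eog_times) {
          c0 <- round(tc * fs) + 1L
          lo_i <- max(1L, c0 - half)
          hi_i <- min(n, c0 + half)
          seg <- (lo_i - c0 + half + 1L):(hi_i - c0 + half + 1L)
          left[lo_i:hi_i] <- left[lo_i:hi_i] + pulse[seg]
          right[lo_i:hi_i] <- right[lo_i:hi_i] + pulse[seg]
        }
      }
    }
    list(left = left, right = right, realized = realized, eog_times = eog_times)
  })
  asym <- lapply(out$realized, function(p) {
    if (p[["left"]] + p[["right"]] > 0) {
      unname((p[["right"]] - p[["left"]]) / (p[["right"]] + p[["left"]]))
    } else NA_real_
  })
  list(
    record = signal_record(out$left, out$right, numeric(n), fs = fs),
    truth = list(
      band_power = out$realized,
      asymmetry = asym,
      eog_times = out$eog_times,
      spec = unclass(spec), fs = fs
    )
  )
}
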