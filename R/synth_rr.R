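# Synthetic R-R interval series with controllable LF/HF modulation.

#' Specification of a synthetic R-R interval series
#'
#' Describes a beat-to-beat interval series as a constant mean plus
#' sinusoidal low-frequency (LF, 0.04-0.15 Hz) and high-frequency
#' (HF, 0.15-0.4 Hz) modulation and Gaussian beat-to-beat jitter. The
#' modulation is applied directly to the intervals, so the spectral location
#' of the LF and HF components of the resulting tachogram is known exactly.
#'
#' @param mean_rr Mean R-R interval in ms (> 0).
#' @param lf_amp,lf_freq LF modulation amplitude (ms) and frequency (Hz);
#'   the frequency must lie in `[0.04, 0.15)` whenever `lf_amp > 0`.
#' @param hf_amp,hf_freq HF modulation amplitude (ms) and frequency (Hz);
#'   the frequency must lie in `[0.15, 0.4]` whenever `hf_amp > 0`.
#' @param jitter_sd Standard deviation of white Gaussian interval jitter (ms).
#' @param duration Target series duration in seconds.
#' @param seed Integer RNG seed.
#' @return A list of class `rr_spec`.
#' @seealso [generate_rr_series()]
#' @export
rr_spec <- function(mean_rr = 800, lf_amp = 0, lf_freq = 0.1,
                    hf_amp = 0, hf_freq = 0.25, jitter_sd = 0,
                    duration = 360, seed = 1L) {
  stopifnot(mean_rr > 0, lf_amp >= 0, hf_amp >= 0, jitter_sd >= 0, duration > 0)
  if (lf_amp > 0 && (lf_freq < 0.04 || lf_freq >= 0.15)) {
    stop("lf_freq must lie in [0.04, 0.15) when lf_amp > 0", call. = FALSE)
  }
  if (hf_amp > 0 && (hf_freq < 0.15 || hf_freq > 0.4)) {
    stop("hf_freq must lie in [0.15, 0.4] when hf_amp > 0", call. = FALSE)
  }
  if (lf_amp + hf_amp + 4 * jitter_sd >= mean_rr) {
    stop("lf_amp + hf_amp + 4*jitter_sd must be < mean_rr (intervals must stay positive)",
         call. = FALSE)
  }
  structure(
    list(mean_rr = mean_rr, lf_amp = lf_amp, lf_freq = lf_freq,
         hf_amp = hf_amp, hf_freq = hf_freq, jitter_sd = jitter_sd,
         duration = duration, seed = as.integer(seed)),
    class = "rr_spec"
  )
}

#' Generate a synthetic R-R interval series
#'
#' Interval i is
#' `mean_rr + lf_amp*sin(2*pi*lf_freq*t_i) + hf_amp*sin(2*pi*hf_freq*t_i) + e_i`
#' with `e_i ~ N(0, jitter_sd^2)` and `t_i` the (cumulative) time of the
#' beat opening interval i. Beat times are the cumulative sum of intervals,
#' starting at 0.
#'
#' @param spec An [rr_spec()].
#' @return A list with elements:
#'   * `beat_times` - beat times in seconds (first beat at 0),
#'   * `intervals` - R-R intervals in ms (`length(beat_times) - 1`),
#'   * `truth` - ground truth list (`r_peak_times`, spec echo).
#' @examples
#' rr <- generate_rr_series(rr_spec(mean_rr = 800, duration = 24))
#' length(rr$beat_times)  # 31 beats span 24 s
#' @export
generate_rr_series <- function(spec) {
  stopifnot(inherits(spec, "rr_spec"))
  n_max <- ceiling(spec$duration * 1000 / spec$mean_rr * 2) + 8L
  intervals <- with_seed(spec$seed, {
    t_cur <- 0
    out <- numeric(n_max)
    n <- 0L
    eps <- stats::rnorm(n_max, 0, spec$jitter_sd)
    while (t_cur < spec$duration && n < n_max) {
      n <- n + 1L
      iv <- spec$mean_rr +
        spec$lf_amp * sin(2 * pi * spec$lf_freq * t_cur) +
        spec$hf_amp * sin(2 * pi * spec$hf_freq * t_cur) +
        eps[n]
      out[n] <- iv
      t_cur <- t_cur + iv / 1000
    }
    out[seq_len(n)]
  })
  if (any(intervals <= 0)) {
    stop("spec produced a non-positive R-R interval", call. = FALSE)
  }
  beat_times <- c(0, cumsum(intervals) / 1000)
  list(
    beat_times = beat_times,
    intervals = intervals,
    truth = list(r_peak_times = beat_times, spec = unclass(spec))
  )
}
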