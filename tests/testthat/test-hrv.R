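test_that("time-domain features match hand-computed values", {
  expect_equal(time_domain_features(c(800, 800, 800)),
               c(mRR = 800, SDRR = 0, RMSSD = 0))
  got <- time_domain_features(c(800, 810, 790))
  expect_equal(got[["mRR"]], 800)
  expect_equal(got[["SDRR"]], 10)
  expect_equal(got[["RMSSD"]], sqrt((10^2 + 20^2) / 2))
  expect_error(time_domain_features(800), "at least 2")
})

test_that("time-domain features match the brute-force oracle to 1e-9", {
  set.seed(1)
  for (i in 1:100) {
    iv <- runif(sample(3:50, 1), 400, 1200)
    expect_equal(time_domain_features(iv), oracle_time_domain(iv),
                 tolerance = 1e-9)
  }
})

test_that("translation and scaling act as expected on time-domain features", {
  set.seed(2)
  iv <- runif(30, 600, 1000)
  base <- time_domain_features(iv)
  shifted <- time_domain_features(iv + 100)
  expect_equal(shifted[["mRR"]], base[["mRR"]] + 100)
  expect_equal(shifted[c("SDRR", "RMSSD")], base[c("SDRR", "RMSSD")])
  scaled <- time_domain_features(iv * 3)
  expect_equal(scaled, base * 3)
})

test_that("tachogram resampling is linear with a 1/rate grid", {
  rr <- rr_series(seq(1, by = 200, length.out = 10), fs = 250)  # constant 800 ms
  tach <- resample_rr(rr, rate = 2)
  expect_equal(unique(diff(tach$time)), 0.5)
  expect_equal(tach$rr, rep(800, length(tach$rr)))
  # midway between two interval anchors the value is their arithmetic mean
  rr2 <- rr_series(c(1, 751, 2001), fs = 1000)  # intervals 750, 1250 ms
  tach2 <- resample_rr(rr2, rate = 8)
  mid <- which(abs(tach2$time - 1.375) < 1e-9)
  expect_equal(tach2$rr[mid], 1000)
})

test_that("spectral power localizes in the band of the modulation", {
  t <- seq(0, 359.5, by = 0.5)
  for (f0 in c(0.1, 0.25)) {
    tach <- list(time = t, rr = 800 + 50 * sin(2 * pi * f0 * t), rate = 2)
    sp <- hrv_spectrum(tach)
    band <- if (f0 < 0.15) sp$lf_power else sp$hf_power
    expect_gt(band / sp$total_power, 0.95)
  }
})

test_that("the periodogram conserves tachogram variance (Parseval)", {
  set.seed(4)
  x <- stats::rnorm(720, 800, 30)
  sp <- hrv_spectrum(list(time = seq_along(x) / 2, rr = x, rate = 2))
  all_power <- sum(sp$density) * (2 / length(x))
  expect_equal(all_power, mean((x - mean(x))^2), tolerance = 0.01)
})

test_that("normalized frequency features follow their definitions", {
  mk <- function(lf, hf, tot) structure(
    list(frequencies = NULL, density = NULL, rate = 2,
         total_power = tot, lf_power = lf, hf_power = hf),
    class = "hrv_spectrum"
  )
  expect_equal(frequency_features(mk(50, 50, 100)),
               c(nLF_HRV = 50, nHF_HRV = 50, LF_HF = 100))
  # published S1 group means for the normalized powers imply this ratio
  got <- frequency_features(mk(10.89, 11.63, 100))
  expect_equal(got[["LF_HF"]], 100 * 10.89 / 11.63, tolerance = 1e-9)
  expect_equal(got[["LF_HF"]], 93.64, tolerance = 0.01)
  expect_warning(out <- frequency_features(mk(10, 0, 100)), "undefined")
  expect_true(is.na(out[["LF_HF"]]))
})

test_that("adding HF modulation to an LF-only series lowers nLF and LF/HF", {
  base <- rr_spec(mean_rr = 800, lf_amp = 40, lf_freq = 0.1, jitter_sd = 2,
                  duration = 240, seed = 5)
  both <- rr_spec(mean_rr = 800, lf_amp = 40, lf_freq = 0.1, hf_amp = 40,
                  hf_freq = 0.25, jitter_sd = 2, duration = 240, seed = 5)
  f_of <- function(sp) {
    rr <- generate_rr_series(sp)
    idx <- round(rr$beat_times * 250) + 1
    frequency_features(hrv_spectrum(resample_rr(rr_series(idx, 250))))
  }
  a <- f_of(base)
  b <- f_of(both)
  expect_lt(b[["nLF_HRV"]], a[["nLF_HRV"]])
  expect_lt(b[["LF_HF"]], a[["LF_HF"]])
})
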