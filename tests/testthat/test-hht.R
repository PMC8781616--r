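# Analytic two-pass Butterworth magnitude: |H(f)|^2 for zero-phase
# forward-backward filtering.
butter2_gain <- function(f, fc = 16, order = 5) 1 / (1 + (f / fc)^(2 * order))

# Amplitude of a tone in a series, by projection on the complex
# exponential over the central 60% of the frame (skips filter edges).
tone_amplitude <- function(x, f0, fs = FS) {
  n <- length(x)
  keep <- floor(0.2 * n):ceiling(0.8 * n)
  t <- (keep - 1) / fs
  2 * Mod(mean(x[keep] * exp(-2i * pi * f0 * t)))
}

test_that("low-pass filter has unit DC gain and the analytic Butterworth response", {
  const <- ecg_frame(rep(1, 1080), FS)
  expect_equal(lowpass_filter(const)$samples, rep(1, 1080), tolerance = 1e-9)

  for (f0 in c(5, 16, 60)) {
    fr <- tone_frame(f0, duration_s = 6)        # longer frame, cleaner edges
    y <- lowpass_filter(fr)$samples
    measured <- tone_amplitude(y, f0)
    expect_lt(abs(measured - butter2_gain(f0)),
              0.01 * max(butter2_gain(f0), 0.01))
  }
  # passband essentially transparent, stopband essentially opaque
  expect_gt(tone_amplitude(lowpass_filter(tone_frame(5))$samples, 5), 0.99)
  expect_lt(tone_amplitude(lowpass_filter(tone_frame(60))$samples, 60), 0.001)

  expect_error(lowpass_filter(tone_frame(5), cutoff_hz = 200), "Nyquist")
})

test_that("filtering is idempotent on band-limited signals", {
  fr <- tone_frame(5)
  once <- lowpass_filter(fr)
  twice <- lowpass_filter(once)
  a1 <- tone_amplitude(once$samples, 5)
  a2 <- tone_amplitude(twice$samples, 5)
  expect_lt(abs(a2 - a1) / a1, 0.001)
})

test_that("one sifting step subtracts the envelope mean", {
  t <- frame_time(3)
  s <- sift_once(sin(2 * pi * 8 * t))
  expect_lt(max(abs(s$mean_envelope[100:980])), 0.01)
  expect_equal(s$candidate[100:980], sin(2 * pi * 8 * t)[100:980],
               tolerance = 0.02)

  s5 <- sift_once(sin(2 * pi * 8 * t) + 5)
  expect_equal(mean(s5$mean_envelope[100:980]), 5, tolerance = 0.01)

  expect_error(sift_once(c(1, 2, 1)), "fewer than 2")
})

test_that("EMD recovers known components and is complete", {
  # monotonic input: nothing to decompose
  ramp <- emd(ecg_frame(seq(0, 1, length.out = 1080), FS))
  expect_length(ramp$imfs, 0)
  expect_equal(ramp$residue, seq(0, 1, length.out = 1080))

  # oscillation + trend separate cleanly
  t <- frame_time(3)
  x <- sin(2 * pi * 8 * t) + 0.3 * t
  d <- emd(ecg_frame(x, FS))
  expect_gte(length(d$imfs), 1)
  expect_gt(cor(d$imfs[[1]], sin(2 * pi * 8 * t)), 0.95)
  trend <- x - d$imfs[[1]]
  expect_gt(cor(trend, 0.3 * t), 0.95)

  # two tones an order of magnitude apart land in successive IMFs
  x2 <- sin(2 * pi * 10 * t) + sin(2 * pi * 1 * t)
  d2 <- emd(ecg_frame(x2, FS))
  expect_gte(length(d2$imfs), 2)
  expect_equal(dominant_freq(d2$imfs[[1]]), 10, tolerance = 0.15)
  expect_equal(dominant_freq(d2$imfs[[2]]), 1, tolerance = 0.35)

  expect_error(emd(c(1, NA, 3, 4)), "non-finite")
})

test_that("EMD completeness, IMF conditions and residue hold on random frames", {
  set.seed(2024)
  for (rep in 1:20) {
    x <- as.numeric(stats::filter(rnorm(1080), rep(1 / 4, 4), sides = 1))
    x[is.na(x)] <- 0
    d <- emd(ecg_frame(x, FS))
    recon <- Reduce(`+`, d$imfs, accumulate = FALSE) + d$residue
    expect_lt(max(abs(x - recon)), 1e-8 * max(abs(x)))
    for (imf in d$imfs) {
      ex <- ecghht:::find_extrema(imf)
      n_ext <- length(ex$maxima) + length(ex$minima)
      expect_lte(abs(n_ext - ecghht:::count_zero_crossings(imf)), 1)
    }
    ex <- ecghht:::find_extrema(d$residue)
    expect_true(length(ex$maxima) < 2 || length(ex$minima) < 2)
  }
})

test_that("Hilbert analysis recovers tone frequency, amplitude and chirp law", {
  d <- emd(tone_frame(5))
  hs <- hilbert_analysis(d)
  e <- hs$per_imf[[1]]
  expect_equal(median(e$freq_hz), 5, tolerance = 0.1 / 5)
  expect_equal(median(e$amp), 1, tolerance = 0.02)

  hs2 <- hilbert_analysis(list(2 * sin(2 * pi * 5 * frame_time(3))), fs = FS)
  expect_equal(median(hs2$per_imf[[1]]$amp), 2, tolerance = 0.04)

  # linear chirp 2 -> 8 Hz: instantaneous frequency rises with time
  t <- frame_time(3)
  chirp <- sin(2 * pi * (2 * t + (8 - 2) / (2 * 3) * t^2))
  hc <- hilbert_analysis(list(chirp), fs = FS)
  ec <- hc$per_imf[[1]]
  expect_gt(cor(ec$time_s, ec$freq_hz, method = "spearman"), 0.9)
  expect_error(hilbert_analysis(list(), fs = FS), "empty")
})

test_that("marginal spectrum concentrates tones and conserves energy", {
  d <- emd(tone_frame(5))
  hs <- hilbert_analysis(d)
  mhs <- marginal_spectrum(hs, 1)
  in_band <- mhs$freq_hz >= 4.8 & mhs$freq_hz <= 5.2
  expect_gt(sum(mhs$energy[in_band]) / sum(mhs$energy), 0.95)

  # conservation: bin sum equals the time integral of the amplitude
  e <- hs$per_imf[[1]]
  expect_equal(sum(mhs$energy), sum(e$amp) / FS, tolerance = 1e-12)

  # zero IMF -> all-zero spectrum and (0, 0) centroid
  hz <- hilbert_analysis(list(rep(0, 1080)), fs = FS)
  mz <- marginal_spectrum(hz, 1)
  expect_true(all(mz$energy == 0))
  cz <- mhs_centroid(mz)
  expect_equal(c(cz$freq_hz, cz$power), c(0, 0))

  expect_error(marginal_spectrum(hs, 5), "out of range")
  expect_error(marginal_spectrum(hs, 1, bin_hz = 0), "bin_hz")
})

test_that("centroids are weighted means with scale equivariance", {
  d <- emd(tone_frame(5))
  hs <- hilbert_analysis(d)
  mhs <- marginal_spectrum(hs, 1)
  ct <- mhs_centroid(mhs)
  # oracle: direct weighted mean over the binned spectrum
  expect_equal(ct$freq_hz, sum(mhs$freq_hz * mhs$energy) / sum(mhs$energy))
  expect_equal(ct$freq_hz, 5, tolerance = 0.2 / 5)
  expect_equal(ct$power, sum(mhs$energy) / 3)

  # doubling amplitude doubles power, leaves the frequency centroid alone
  d2 <- emd(tone_frame(5, amp = 2))
  ct2 <- mhs_centroid(marginal_spectrum(hilbert_analysis(d2), 1))
  expect_equal(ct2$power / ct$power, 2, tolerance = 0.01)
  expect_equal(ct2$freq_hz, ct$freq_hz, tolerance = 0.02)
})

test_that("single tones anywhere in band recover their centroid frequency", {
  for (f0 in c(1, 2, 5, 8, 12, 14)) {
    d <- emd(tone_frame(f0))
    ct <- mhs_centroid(marginal_spectrum(hilbert_analysis(d), 1))
    expect_equal(ct$freq_hz, f0, tolerance = 0.05,
                 label = sprintf("centroid at f0=%g", f0))
  }
})
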