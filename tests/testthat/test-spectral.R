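test_that("segmentation drops the remainder and rejects short recordings", {
  ts <- gen_pink_noise(250 * 30, 250, noise_spec(seed = 1))
  expect_equal(nrow(segment(ts, 3)$segments), 10)
  expect_equal(ncol(segment(ts, 3)$segments), 750)

  ts7 <- gen_pink_noise(250 * 7, 250, noise_spec(seed = 1))
  expect_equal(nrow(segment(ts7, 3)$segments), 2)

  ts2 <- gen_pink_noise(250 * 2, 250, noise_spec(seed = 1))
  expect_error(segment(ts2, 3), "shorter than one segment")
})

test_that("segments tile the recording contiguously in source order", {
  ts <- gen_pink_noise(250 * 9, 250, noise_spec(seed = 5))
  segs <- segment(ts, 3)
  expect_equal(as.vector(t(segs$segments)), ts$samples[1, ])
})

test_that("segment spectrum localizes a sinusoid and zeroes a constant", {
  x <- sin(2 * pi * 10 * (0:749) / 250)
  sp <- segment_spectrum(x, 250)
  expect_equal(sp$resolution, 1 / 3)
  expect_equal(sp$freqs[which.max(sp$power)], 10)
  spc <- segment_spectrum(rep(3.7, 750), 250)
  expect_lt(max(spc$power), 1e-20)
})

test_that("segment spectrum agrees with a naive direct DFT to 1e-10", {
  withr::with_seed(11, x <- stats::rnorm(64))
  got <- segment_spectrum(x, 250)
  ref <- naive_dft_spectrum(x, 250)
  expect_equal(got$freqs, ref$freqs)
  expect_lt(max(abs(got$power - ref$power) / pmax(ref$power, 1e-30)), 1e-10)
})

test_that("spectrum integral approximates signal variance (Parseval)", {
  # the Hann density normalization is unbiased for broadband signals:
  # averaged over many segments, integral(power df) matches variance (a
  # single windowed segment deviates by a few percent by design; signals
  # with strong below-resolution power are biased by demeaning + windowing)
  check_parseval <- function(ts) {
    segs <- segment(ts, 3)
    totals <- vapply(segment_spectra(segs), function(sp) {
      sum(sp$power) * sp$resolution
    }, numeric(1))
    vars <- apply(segs$segments, 1, function(x) mean((x - mean(x))^2))
    expect_lt(abs(mean(totals) - mean(vars)) / mean(vars), 0.01)
  }
  check_parseval(gen_pink_noise(250 * 3 * 200, 250,
                                noise_spec(exponent = 0, seed = 42)))
  check_parseval(gen_pink_noise(250 * 3 * 200, 250,
                                noise_spec(exponent = 0, seed = 7)))
})

test_that("band power averages the closed-interval band bins", {
  sp <- structure(list(freqs = seq(0, 50, by = 1 / 3),
                       power = rep(1, length(seq(0, 50, by = 1 / 3))),
                       resolution = 1 / 3),
                  class = "spectrum_est")
  expect_equal(band_power(sp, beta_band()), 1)
  # closed interval [16, 30] on a 1/3 Hz grid holds 43 bins
  expect_equal(length(betaharmonics:::band_bins(sp, beta_band())), 43)
  expect_error(band_power(sp, band_definition("x", 60, 70)), "beyond")
})

test_that("aperiodic fit is exact on noiseless power laws", {
  sp <- powerlaw_spectrum(2, 1.5)
  fit <- fit_aperiodic(sp)
  expect_equal(fit$offset, 2, tolerance = 1e-9)
  expect_equal(fit$exponent, 1.5, tolerance = 1e-9)

  # a Gaussian alpha peak does not bias the fit when its band is excluded
  spk <- sp
  spk$power <- spk$power + 5 * exp(-(spk$freqs - 10)^2 / (2 * 0.5^2))
  fit2 <- fit_aperiodic(spk, excluded = list(band_definition("alpha", 7, 14)))
  expect_equal(fit2$exponent, 1.5, tolerance = 1e-6)

  expect_error(fit_aperiodic(sp, fit_range = c(1, 2)), "fewer than 5 bins")
})

test_that("aperiodic exponent is recovered from noisy pink noise", {
  ts <- gen_pink_noise(250 * 180, 250, noise_spec(exponent = 1.5, seed = 21))
  sp <- mean_spectrum(segment_spectra(segment(ts, 3)))  # 60 segments
  fit <- fit_aperiodic(sp)
  expect_lt(abs(fit$exponent - 1.5), 0.1)
})

test_that("corrected power is the mean dB deviation from the fit", {
  sp <- powerlaw_spectrum(2, 1.5)
  fit <- fit_aperiodic(sp)
  expect_equal(corrected_power(sp, fit, beta_band()), 0, tolerance = 1e-9)

  sp10 <- sp
  sp10$power <- sp$power * 10
  fit_of_orig <- fit
  expect_equal(corrected_power(sp10, fit_of_orig, beta_band()), 10,
               tolerance = 1e-9)

  # one of the 43 beta bins raised tenfold contributes 10/43 dB to the mean
  sp1 <- sp
  bins <- betaharmonics:::band_bins(sp, beta_band())
  expect_length(bins, 43)
  sp1$power[bins[5]] <- sp1$power[bins[5]] * 10
  expect_equal(corrected_power(sp1, fit, beta_band()), 10 / 43,
               tolerance = 1e-9)
})

test_that("band SNR is the peak dB deviation from the fit", {
  sp <- powerlaw_spectrum(2, 1.5)
  fit <- fit_aperiodic(sp)
  expect_equal(snr_db(sp, fit, alpha_band()), 0, tolerance = 1e-9)
  sp2 <- sp
  bins <- betaharmonics:::band_bins(sp, alpha_band())
  sp2$power[bins[3]] <- sp2$power[bins[3]] * 100
  expect_equal(snr_db(sp2, fit, alpha_band()), 20, tolerance = 1e-9)
  expect_error(snr_db(sp, fit, band_definition("x", 10.01, 10.02)), "no frequency bins")
})
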