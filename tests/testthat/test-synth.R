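test_that("pink noise generator matches its target spectral slope", {
  # white noise: flat spectrum
  avg <- NULL
  for (s in 1:10) {
    ts <- gen_pink_noise(250 * 30, 250, noise_spec(exponent = 0, scale = 1,
                                                   seed = s))
    sp <- mean_spectrum(segment_spectra(segment(ts, 2)))
    avg <- if (is.null(avg)) sp$power / 10 else avg + sp$power / 10
  }
  expect_lt(abs(loglog_slope(sp$freqs, avg, 1, 45)), 0.1)

  # 1/f^1.5 noise: slope -1.5 on the seed-averaged periodogram
  avg <- NULL
  for (s in 1:50) {
    ts <- gen_pink_noise(250 * 60, 250, noise_spec(exponent = 1.5, scale = 0.5,
                                                   seed = s))
    sp <- mean_spectrum(segment_spectra(segment(ts, 2)))
    avg <- if (is.null(avg)) sp$power / 50 else avg + sp$power / 50
  }
  expect_lt(abs(loglog_slope(sp$freqs, avg, 1, 45) - (-1.5)), 0.1)
})

test_that("pink noise generator rejects degenerate arguments and is seeded", {
  expect_error(gen_pink_noise(0, 250), "n_samples")
  expect_error(gen_pink_noise(1000, -1), "rate")
  a <- gen_pink_noise(1000, 250, noise_spec(seed = 7))
  b <- gen_pink_noise(1000, 250, noise_spec(seed = 7))
  expect_identical(a$samples, b$samples)
})

test_that("rhythm generator places power at the base frequency and harmonics", {
  # pure 10 Hz sinusoid: no energy at 20 Hz
  ts <- gen_rhythm(rhythm_spec(10), 3, 250, seed = 1)
  sp <- segment_spectrum(ts$samples[1, ], 250)
  i10 <- which.min(abs(sp$freqs - 10))
  i20 <- which.min(abs(sp$freqs - 20))
  expect_equal(which.max(sp$power), i10)
  expect_lt(sp$power[i20], 0.01 * sp$power[i10])

  # harmonic at relative amplitude 0.5: bin power ratio (0.5)^2 = 0.25
  ts <- gen_rhythm(rhythm_spec(10, list(harmonic(2, 0.5, pi / 2))), 3, 250,
                   seed = 1)
  sp <- segment_spectrum(ts$samples[1, ], 250)
  expect_equal(sp$power[i20] / sp$power[i10], 0.25, tolerance = 1e-9)

  expect_error(gen_rhythm(rhythm_spec(10), duration = 0.05, rate = 250),
               "base period")
})

test_that("harmonic band power tracks base band power under a common envelope", {
  spec <- rhythm_spec(10, list(harmonic(2, 0.5)), envelope_random(seed = 3))
  ts <- gen_rhythm(spec, 120, 250, seed = 3)
  spectra <- segment_spectra(segment(ts, 3))
  p10 <- vapply(spectra, band_power, numeric(1), band = alpha_band())
  p20 <- vapply(spectra, band_power, numeric(1), band = beta_band())
  expect_gt(spearman_rho(p10, p20), 0.9)
})

test_that("harmonic phase locking is exact by construction", {
  # noise off, constant envelope; isolate the 10 and 20 Hz components and
  # compare instantaneous phases phi(2 f0) - 2 phi(f0) against the lag
  lag <- pi / 3
  rate <- 250
  ts <- gen_rhythm(rhythm_spec(10, list(harmonic(2, 0.5, lag))), 4, rate,
                   seed = 2)
  x <- ts$samples[1, ]
  n <- length(x)
  f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * rate / n
  analytic <- function(f_lo, f_hi) {
    X <- stats::fft(x)
    X[!(f >= f_lo & f <= f_hi)] <- 0  # positive-frequency band only
    stats::fft(X, inverse = TRUE) / n
  }
  ph1 <- Arg(analytic(8, 12))
  ph2 <- Arg(analytic(18, 22))
  dphi <- (ph2 - 2 * ph1 + pi) %% (2 * pi) - pi
  expect_lt(max(abs(dphi - stats::median(dphi))), 1e-6)  # constant over time
  # with the sine convention the constant is the lag plus pi/2
  expect_equal(stats::median(dphi), lag + pi / 2, tolerance = 1e-9)
})

test_that("with noise off, spectral power sits in the specified bins only", {
  rate <- 250
  dur <- 2
  ts <- gen_rhythm(rhythm_spec(10, list(harmonic(2, 0.5))), dur, rate,
                   seed = 1)
  x <- ts$samples[1, ]
  # rectangular periodogram: exact-bin sinusoids leak nowhere
  p <- Mod(stats::fft(x))^2
  n <- length(x)
  k10 <- 10 * dur + 1
  k20 <- 20 * dur + 1
  sig <- p[c(k10, k20, n + 2 - k10, n + 2 - k20)]
  expect_gt(sum(sig) / sum(p), 0.99)
})

test_that("scenario generation is deterministic and validates its regime", {
  a <- gen_scenario(scenario_spec("harmonic", seed = 9, duration = 30))
  b <- gen_scenario(scenario_spec("harmonic", seed = 9, duration = 30))
  expect_identical(a$ts$samples, b$ts$samples)
  c <- gen_scenario(scenario_spec("harmonic", seed = 10, duration = 30))
  expect_false(identical(a$ts$samples, c$ts$samples))

  # regime/rhythm consistency rules
  expect_error(
    scenario_spec("harmonic", alpha_rhythm = rhythm_spec(10)),
    "requires alpha harmonics")
  expect_error(
    scenario_spec("independent",
                  alpha_rhythm = rhythm_spec(10, list(harmonic(2, 0.5)))),
    "sinusoidal alpha")
  expect_error(
    scenario_spec("independent",
                  alpha_rhythm = rhythm_spec(10, amplitude = 0),
                  beta_rhythm = list(amplitude = 0)),
    "degenerate")
})

test_that("anticorrelated scenario envelopes have rank correlation -1", {
  out <- gen_scenario(scenario_spec("anticorrelated", seed = 4,
                                    duration = 60))
  gt <- out$ground_truth
  expect_equal(spearman_rho(gt$alpha_envelope, gt$beta_envelope), -1,
               tolerance = 1e-12)
})

test_that("forward mixing reproduces sources under identity mixing", {
  src <- gen_pink_noise(1000, 250, noise_spec(seed = 2))
  out <- mix_forward(src, diag(1))
  expect_equal(out$samples, src$samples)
  expect_error(mix_forward(src, matrix(1, 2, 3)), "column count")
})
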