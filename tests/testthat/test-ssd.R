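# Known-ground-truth mixtures for SSD tests.
make_mixture <- function(n_noise = 7, dur = 120, rate = 250, seed = 5,
                         sensor_noise = 0.1) {
  alpha <- gen_rhythm(
    rhythm_spec(10, list(harmonic(2, 0.5)), envelope_random(0.2, 1),
                freq_jitter = 0.25, jitter_cutoff = 1),
    dur, rate, seed = seed)
  noise <- do.call(rbind, lapply(seq_len(n_noise), function(i) {
    gen_pink_noise(dur * rate, rate, noise_spec(1.5, 0.5, seed = 100 + i))$samples
  }))
  sources <- time_series(rbind(alpha$samples, noise), rate)
  withr::with_seed(9, A <- qr.Q(qr(matrix(stats::rnorm((n_noise + 1)^2),
                                          n_noise + 1, n_noise + 1))))
  list(mixed = mix_forward(sources, A, sensor_noise = sensor_noise, seed = 10),
       alpha_source = alpha$samples[1, ])
}

test_that("zero-phase band-pass preserves the passband and rejects outside it", {
  t <- (0:(250 * 8 - 1)) / 250
  in_band <- time_series(sin(2 * pi * 10 * t), 250)
  out <- bandpass(in_band, alpha_band())
  core <- 500:1500
  expect_lt(abs(max(abs(out$samples[1, core])) - 1), 0.01)

  out_band <- time_series(sin(2 * pi * 25 * t), 250)
  att <- bandpass(out_band, alpha_band())
  ratio <- max(abs(att$samples[1, core])) / 1
  expect_lt(20 * log10(ratio), -20)

  expect_error(bandpass(in_band, band_definition("x", 100, 130)), "Nyquist")
})

test_that("SSD recovers a mixed alpha source and orders by eigenvalue", {
  mx <- make_mixture()
  res <- ssd_decompose(mx$mixed)
  expect_true(all(diff(res$eigenvalues) <= 1e-12))
  best <- best_alpha_component(res, mx$mixed)
  expect_gt(abs(stats::cor(best$samples[1, ], mx$alpha_source)), 0.95)

  expect_error(ssd_decompose(time_series(sin(1:1000), 250)), "2 channels")
  expect_error(
    ssd_decompose(mx$mixed, flank_lo = band_definition("f", 7, 9)),
    "overlap")
})

test_that("generalized eigenvalue residuals vanish for every component", {
  mx <- make_mixture(dur = 60)
  res <- ssd_decompose(mx$mixed)
  for (j in seq_len(ncol(res$filters))) {
    w <- res$filters[, j]
    r <- res$signal_cov %*% w - res$eigenvalues[j] * (res$flank_cov %*% w)
    expect_lt(sqrt(sum(r^2)), 1e-8 * sqrt(sum(w^2)))
  }
  # patterns are the signal covariance applied to the filters (scaled columns)
  raw <- res$signal_cov %*% res$filters
  for (j in seq_len(ncol(raw))) {
    expect_equal(res$patterns[, j], raw[, j] / max(abs(raw[, j])),
                 tolerance = 1e-12)
  }
})

test_that("channel permutation permutes filters but not components", {
  mx <- make_mixture(n_noise = 3, dur = 60)
  res1 <- ssd_decompose(mx$mixed)
  perm <- c(3, 1, 4, 2)
  ts2 <- time_series(mx$mixed$samples[perm, ],
                     mx$mixed$rate, mx$mixed$channel_labels[perm])
  res2 <- ssd_decompose(ts2)
  c1 <- drop(crossprod(res1$filters[, 1, drop = FALSE], mx$mixed$samples))
  c2 <- drop(crossprod(res2$filters[, 1, drop = FALSE], ts2$samples))
  expect_gt(abs(stats::cor(c1, c2)), 1 - 1e-6)  # same component up to sign
})

test_that("SSD prefers the alpha source over a genuine beta source", {
  rate <- 250
  dur <- 60
  alpha <- gen_rhythm(rhythm_spec(10, list(), envelope_random(0.2, 1)),
                      dur, rate, seed = 1)
  beta <- gen_broadband_rhythm(22, 3, 1, envelope_random(0.2, 1, seed = 2),
                               dur, rate, seed = 2)
  sources <- time_series(rbind(alpha$samples, beta$samples), rate)
  withr::with_seed(3, A <- matrix(stats::rnorm(8 * 2), 8, 2))
  mixed <- mix_forward(sources, A, sensor_noise = 0.2, seed = 4)
  best <- best_alpha_component(ssd_decompose(mixed), mixed)
  expect_gt(abs(stats::cor(best$samples[1, ], alpha$samples[1, ])),
            abs(stats::cor(best$samples[1, ], beta$samples[1, ])))
})

test_that("best_alpha_component selects by component SNR", {
  res <- structure(list(filters = diag(2), patterns = diag(2),
                        eigenvalues = c(2, 1), component_snr = c(3, 12)),
                   class = "ssd_result")
  ts <- time_series(rbind(sin(2 * pi * 5 * (0:999) / 250),
                          sin(2 * pi * 10 * (0:999) / 250)), 250)
  best <- best_alpha_component(res, ts)
  expect_equal(best$meta$component, 2L)
  expect_equal(best$samples[1, ], ts$samples[2, ])

  empty <- res
  empty$filters <- matrix(numeric(0), nrow = 2, ncol = 0)
  expect_error(best_alpha_component(empty, ts), "empty")
})
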