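# Independent reference implementations used as oracles. These deliberately
# avoid the package's code paths (stats::fft, stats::cor) so that agreement
# is informative.

# Naive O(n^2) direct DFT periodogram with the same Hann / one-sided density
# convention as segment_spectrum().
naive_dft_spectrum <- function(x, rate) {
  n <- length(x)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))
  xw <- (x - mean(x)) * w
  n_keep <- floor(n / 2) + 1L
  p <- numeric(n_keep)
  for (k in seq_len(n_keep)) {
    ang <- -2 * pi * (k - 1) * (seq_len(n) - 1) / n
    re <- sum(xw * cos(ang))
    im <- sum(xw * sin(ang))
    p[k] <- (re^2 + im^2) / (rate * sum(w^2))
  }
  dbl <- rep(2, n_keep)
  dbl[1] <- 1
  if (n %% 2 == 0) dbl[n_keep] <- 1
  list(freqs = (seq_len(n_keep) - 1) * rate / n, power = p * dbl)
}

# Brute-force average ranks by counting, then the Pearson product-moment
# formula written out.
ranks_by_counting <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    below <- sum(x < x[i])
    ties <- sum(x == x[i])
    r[i] <- below + (ties + 1) / 2
  }
  r
}

spearman_bruteforce <- function(x, y) {
  rx <- ranks_by_counting(x)
  ry <- ranks_by_counting(y)
  mx <- sum(rx) / length(rx)
  my <- sum(ry) / length(ry)
  num <- sum((rx - mx) * (ry - my))
  den <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  num / den
}

# Log-log least squares on an averaged periodogram, written out (normal
# equations), as an independent slope estimate for noise spectra.
loglog_slope <- function(freqs, power, f_lo = 1, f_hi = 45) {
  keep <- freqs >= f_lo & freqs <= f_hi
  lx <- log10(freqs[keep])
  ly <- log10(power[keep])
  sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
}

# A power-law spectrum on a uniform grid, as a spectrum_est object.
powerlaw_spectrum <- function(offset_log10, exponent, resolution = 1 / 3,
                              f_max = 50) {
  freqs <- seq(resolution, f_max, by = resolution)
  structure(list(freqs = freqs,
                 power = 10^(offset_log10 - exponent * log10(freqs)),
                 resolution = resolution),
            class = "spectrum_est")
}
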