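#' Zero-phase band-pass filter
#'
#' Butterworth band-pass applied forward and backward (`signal::filtfilt`),
#' giving zero phase distortion and squared magnitude response; output length
#' equals input length.
#'
#' @param ts An [time_series()] (any number of channels).
#' @param band A [band_definition()]; `f_hi` must be below Nyquist.
#' @param order Butterworth order per pass (default 4).
#' @return A filtered `eeg_ts`.
#' @export
bandpass <- function(ts, band, order = 4) {
  stopifnot(inherits(ts, "eeg_ts"), inherits(band, "band"))
  nyq <- ts$rate / 2
  if (band$f_hi >= nyq) {
    stop(sprintf("bandpass: band edge %g Hz is not below Nyquist (%g Hz)",
                 band$f_hi, nyq))
  }
  bf <- signal::butter(order, c(band$f_lo, band$f_hi) / nyq, type = "pass")
  y <- t(apply(ts$samples, 1, function(row) signal::filtfilt(bf, row)))
  if (n_channels(ts) == 1L) y <- matrix(y, nrow = 1L)
  time_series(y, ts$rate, ts$channel_labels, ts$meta)
}

# Channel covariance of a (channels x time) matrix, rows demeaned.
channel_cov <- function(x) {
  xc <- x - rowMeans(x)
  tcrossprod(xc) / (ncol(x) - 1)
}

#' Spatio-spectral decomposition (SSD)
#'
#' Finds spatial filters `w` maximizing band power in `signal_band` relative
#' to power in two flanking bands, via the generalized eigenvalue problem
#' `S w = lambda N w` with `S` the covariance of the signal-band-filtered
#' data and `N` the summed covariance of the two flank-band-filtered data.
#' Solved by whitening `N` (symmetric eigendecomposition) and an ordinary
#' symmetric eigendecomposition in the whitened space; components are ordered
#' by decreasing eigenvalue. A rank-deficient `N` is handled by projecting
#' onto its principal subspace, with a warning.
#'
#' @param ts A multichannel [time_series()] (>= 2 channels).
#' @param signal_band Signal [band_definition()] (default alpha, 8-13 Hz).
#' @param flank_lo,flank_hi Flanking noise bands (defaults 6-7 and
#'   14-15 Hz); must not overlap the signal band.
#' @param shrinkage Shrinkage coefficient toward the trace-scaled identity
#'   for the flank covariance (default 1e-6), for numerical stability.
#' @param snr_seg_len Segment length (s) used when computing each
#'   component's alpha-band SNR (default 3).
#' @param filter_order Butterworth order for the band-pass filters.
#' @return An object of class `"ssd_result"`: list with `filters`
#'   (channels x components), `patterns` (channels x components, columns of
#'   `S %*% filters` scaled to unit maximum magnitude), `eigenvalues`
#'   (decreasing), `component_snr` (dB, alpha SNR of each component's time
#'   series), plus the `signal_cov` and `flank_cov` used.
#' @export
ssd_decompose <- function(ts, signal_band = alpha_band(),
                          flank_lo = band_definition("flank_lo", 6, 7),
                          flank_hi = band_definition("flank_hi", 14, 15),
                          shrinkage = 1e-6, snr_seg_len = 3,
                          filter_order = 4) {
  stopifnot(inherits(ts, "eeg_ts"))
  if (n_channels(ts) < 2) stop("ssd_decompose: need at least 2 channels")
  overlaps <- function(a, b) a$f_lo <= b$f_hi && b$f_lo <= a$f_hi
  if (overlaps(flank_lo, signal_band) || overlaps(flank_hi, signal_band)) {
    stop("ssd_decompose: flank bands must not overlap the signal band")
  }
  S <- channel_cov(bandpass(ts, signal_band, filter_order)$samples)
  N <- channel_cov(bandpass(ts, flank_lo, filter_order)$samples) +
       channel_cov(bandpass(ts, flank_hi, filter_order)$samples)
  p <- nrow(N)
  N <- (1 - shrinkage) * N + shrinkage * (sum(diag(N)) / p) * diag(p)

  en <- eigen(N, symmetric = TRUE)
  tol <- max(en$values) * 1e-10
  keep <- en$values > tol
  if (!all(keep)) {
    warning(sprintf(
      "ssd_decompose: flank covariance is rank deficient; reduced to %d dimensions",
      sum(keep)))
  }
  # whitening transform restricted to the principal subspace of N
  Wh <- en$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(en$values[keep]), sum(keep))
  K <- crossprod(Wh, S %*% Wh)
  K <- (K + t(K)) / 2
  ek <- eigen(K, symmetric = TRUE)
  filters <- Wh %*% ek$vectors
  eigenvalues <- ek$values

  patterns <- S %*% filters
  scl <- apply(abs(patterns), 2, max)
  scl[scl == 0] <- 1
  patterns <- sweep(patterns, 2, scl, "/")

  comps <- t(filters) %*% ts$samples
  comp_snr <- vapply(seq_len(nrow(comps)), function(i) {
    component_alpha_snr(comps[i, ], ts$rate, signal_band, snr_seg_len)
  }, numeric(1))

  structure(list(filters = filters, patterns = patterns,
                 eigenvalues = eigenvalues, component_snr = comp_snr,
                 signal_cov = S, flank_cov = N,
                 signal_band = signal_band),
            class = "ssd_result")
}

# Alpha SNR of one component: mean spectrum over segments, aperiodic fit,
# peak dB above the fit within the band.
component_alpha_snr <- function(x, rate, band, seg_len) {
  ts <- time_series(x, rate)
  if (duration(ts) < seg_len) seg_len <- duration(ts)
  sp <- mean_spectrum(segment_spectra(segment(ts, seg_len)))
  margin <- 2 * sp$resolution
  excl <- list(band_definition("signal", max(band$f_lo - margin, sp$resolution),
                               band$f_hi + margin),
               band_definition("harmonic2",
                               max(2 * band$f_lo - margin, sp$resolution),
                               2 * band$f_hi + margin))
  fit <- fit_aperiodic(sp, fit_range = c(1, min(45, rate / 2 - 1)),
                       excluded = excl)
  snr_db(sp, fit, band)
}

#' @export
print.ssd_result <- function(x, ...) {
  cat(sprintf("<ssd_result> %d components from %d channels; top eigenvalue %.3g, top alpha SNR %.1f dB\n",
              ncol(x$filters), nrow(x$filters), x$eigenvalues[1],
              max(x$component_snr)))
  invisible(x)
}

#' Extract the component with the highest alpha-band SNR
#'
#' Applies every SSD spatial filter to the broadband recording and returns
#' the component time series whose spectrum shows the highest alpha-band SNR
#' (peak dB above its own aperiodic fit) — selection is by SNR, not by SSD
#' eigenvalue.
#'
#' @param res An [ssd_decompose()] result.
#' @param ts The multichannel [time_series()] the decomposition came from.
#' @return A one-channel `eeg_ts` labelled `"ssd_alpha"`, with the filter
#'   index and SNR in `meta`.
#' @export
best_alpha_component <- function(res, ts) {
  stopifnot(inherits(res, "ssd_result"), inherits(ts, "eeg_ts"))
  if (ncol(res$filters) == 0) stop("best_alpha_component: empty SSD result")
  if (nrow(res$filters) != n_channels(ts)) {
    stop("best_alpha_component: filter/channel count mismatch")
  }
  best <- which.max(res$component_snr)
  comp <- drop(crossprod(res$filters[, best, drop = FALSE], ts$samples))
  time_series(comp, ts$rate, "ssd_alpha",
              meta = list(component = best, alpha_snr = res$component_snr[best]))
}
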