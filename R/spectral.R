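#' Cut a single-channel recording into fixed-length segments
#'
#' Contiguous, non-overlapping segments in source order; any trailing
#' remainder shorter than one segment is discarded.
#'
#' @param ts A one-channel [time_series()].
#' @param seg_len Segment length in seconds.
#' @return An object of class `"segment_set"`: list with `segments`
#'   (n_segments x n_samples matrix), `rate`, `seg_len`, `source_label`.
#' @export
#'
#' @examples
#' ts <- gen_pink_noise(250 * 30, 250, noise_spec(seed = 1))
#' segs <- segment(ts, 3)
#' nrow(segs$segments)  # 10
segment <- function(ts, seg_len) {
  stopifnot(inherits(ts, "eeg_ts"))
  if (n_channels(ts) != 1L) stop("segment: expected a single-channel time series")
  if (seg_len <= 0) stop("segment: seg_len must be positive")
  n_per <- round(seg_len * ts$rate)
  n_total <- ncol(ts$samples)
  if (n_total < n_per) {
    stop("segment: recording shorter than one segment")
  }
  n_seg <- floor(n_total / n_per)
  x <- ts$samples[1, seq_len(n_seg * n_per)]
  structure(
    list(segments = matrix(x, nrow = n_seg, ncol = n_per, byrow = TRUE),
         rate = ts$rate, seg_len = seg_len,
         source_label = ts$channel_labels[1]),
    class = "segment_set"
  )
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d segments of %g s (%d samples) @ %g Hz from '%s'\n",
              nrow(x$segments), x$seg_len, ncol(x$segments), x$rate,
              x$source_label))
  invisible(x)
}

# Periodic Hann window.
hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))

#' Power spectrum of one segment
#'
#' Mean-removed, Hann-windowed one-sided periodogram with density
#' normalization: the integral of power over frequency approximates the
#' segment variance (Parseval). Frequency resolution is `1 / seg_len`.
#'
#' @param x Numeric vector, one segment of samples.
#' @param rate Sampling rate in Hz.
#' @return An object of class `"spectrum_est"`: list with `freqs` (Hz,
#'   ascending from 0 to Nyquist), `power` (microvolts^2/Hz), `resolution`
#'   (Hz).
#' @export
segment_spectrum <- function(x, rate) {
  stopifnot(is.numeric(x), length(x) >= 2, rate > 0)
  n <- length(x)
  w <- hann_window(n)
  xw <- (x - mean(x)) * w
  X <- stats::fft(xw)
  n_keep <- floor(n / 2) + 1L
  p <- Mod(X[seq_len(n_keep)])^2 / (rate * sum(w^2))
  # one-sided: double everything except DC and (for even n) Nyquist
  dbl <- rep(2, n_keep)
  dbl[1] <- 1
  if (n %% 2 == 0) dbl[n_keep] <- 1
  p <- p * dbl
  structure(list(freqs = (seq_len(n_keep) - 1) * rate / n,
                 power = p, resolution = rate / n),
            class = "spectrum_est")
}

#' @export
print.spectrum_est <- function(x, ...) {
  cat(sprintf("<spectrum_est> %d bins, 0-%g Hz, resolution %g Hz\n",
              length(x$freqs), max(x$freqs), x$resolution))
  invisible(x)
}

#' Power spectra for every segment of a segment set
#'
#' @param segset A [segment()] result.
#' @return List of `"spectrum_est"` objects, one per segment.
#' @export
segment_spectra <- function(segset) {
  stopifnot(inherits(segset, "segment_set"))
  apply(segset$segments, 1, segment_spectrum, rate = segset$rate,
        simplify = FALSE)
}

#' Average several spectra bin by bin
#'
#' @param spectra List of `"spectrum_est"` objects on identical grids.
#' @return A `"spectrum_est"` holding the arithmetic mean power per bin.
#' @export
mean_spectrum <- function(spectra) {
  stopifnot(length(spectra) >= 1)
  p <- Reduce(`+`, lapply(spectra, `[[`, "power")) / length(spectra)
  out <- spectra[[1]]
  out$power <- p
  out
}

# Indices of spectrum bins inside a band, closed on both ends.
# A tolerance of 1e-6 bins absorbs floating-point error on the grid.
band_bins <- function(spec, band) {
  eps <- spec$resolution * 1e-6
  which(spec$freqs >= band$f_lo - eps & spec$freqs <= band$f_hi + eps)
}

#' Mean power of a spectrum within a band
#'
#' The mean of `power` over bins with `f_lo <= f <= f_hi` (closed interval).
#'
#' @param spec A `"spectrum_est"`.
#' @param band A [band_definition()].
#' @return Scalar mean band power (microvolts^2/Hz).
#' @export
band_power <- function(spec, band) {
  stopifnot(inherits(spec, "spectrum_est"), inherits(band, "band"))
  if (band$f_lo >= max(spec$freqs)) {
    stop(sprintf("band_power: band '%s' lies beyond the spectrum (max %g Hz)",
                 band$name, max(spec$freqs)))
  }
  idx <- band_bins(spec, band)
  if (length(idx) == 0) stop("band_power: band contains no frequency bins")
  mean(spec$power[idx])
}

#' Fit the aperiodic (1/f) component of a spectrum
#'
#' Ordinary least squares of `log10(power)` on `log10(frequency)` over the
#' bins of `fit_range`, excluding bins inside any band of `excluded`
#' (typically the alpha and beta bands, so oscillatory peaks do not bias the
#' fit). The exponent is the negative slope; the offset is the intercept at
#' 1 Hz. Zero or negative power bins are floored at `epsilon` before taking
#' the log.
#'
#' @param spec A `"spectrum_est"`.
#' @param fit_range Numeric length-2, fit range in Hz (default `c(1, 45)`).
#' @param excluded List of [band_definition()]s to exclude from the fit.
#' @param epsilon Power floor before the log (default 1e-15).
#' @return An object of class `"aperiodic_fit"`: list with `offset`
#'   (log10 power at 1 Hz), `exponent`, `fit_range`, `excluded_bands`.
#' @export
#'
#' @examples
#' sp <- structure(list(freqs = 1:45, power = 100 * (1:45)^-1.5,
#'                      resolution = 1), class = "spectrum_est")
#' fit_aperiodic(sp)  # offset 2, exponent 1.5
fit_aperiodic <- function(spec, fit_range = c(1, 45), excluded = list(),
                          epsilon = 1e-15) {
  stopifnot(inherits(spec, "spectrum_est"), length(fit_range) == 2,
            fit_range[1] > 0, fit_range[2] > fit_range[1])
  eps_f <- spec$resolution * 1e-6
  keep <- spec$freqs >= fit_range[1] - eps_f & spec$freqs <= fit_range[2] + eps_f
  for (b in excluded) {
    keep <- keep & !(spec$freqs >= b$f_lo - eps_f & spec$freqs <= b$f_hi + eps_f)
  }
  idx <- which(keep & spec$freqs > 0)
  if (length(idx) < 5) {
    stop("fit_aperiodic: fewer than 5 bins remain after exclusion")
  }
  lf <- log10(spec$freqs[idx])
  lp <- log10(pmax(spec$power[idx], epsilon))
  co <- stats::coef(stats::lm.fit(cbind(1, lf), lp))
  structure(list(offset = unname(co[1]), exponent = unname(-co[2]),
                 fit_range = fit_range, excluded_bands = excluded),
            class = "aperiodic_fit")
}

#' @export
print.aperiodic_fit <- function(x, ...) {
  cat(sprintf("<aperiodic_fit> offset %.3f, exponent %.3f over %g-%g Hz\n",
              x$offset, x$exponent, x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' Aperiodic model prediction on a frequency grid
#'
#' @param fit An `"aperiodic_fit"`.
#' @param freqs Frequencies in Hz (> 0).
#' @return Predicted power (linear units) at each frequency.
#' @export
predict_aperiodic <- function(fit, freqs) {
  stopifnot(inherits(fit, "aperiodic_fit"), all(freqs > 0))
  10^(fit$offset - fit$exponent * log10(freqs))
}

#' 1/f-corrected band power (dB)
#'
#' Band power expressed relative to the aperiodic fit: the mean over band
#' bins of `10 * log10(power / predicted)`. Zero when the spectrum equals
#' the fit exactly. The correction is a power ratio (log-domain
#' subtraction), which makes it invariant to overall signal scaling.
#'
#' @param spec A `"spectrum_est"`.
#' @param fit An `"aperiodic_fit"` for the same spectrum.
#' @param band A [band_definition()].
#' @param epsilon Power floor (default 1e-15).
#' @return Scalar corrected power in dB.
#' @export
corrected_power <- function(spec, fit, band, epsilon = 1e-15) {
  idx <- band_bins(spec, band)
  if (length(idx) == 0) stop("corrected_power: band contains no frequency bins")
  idx <- idx[spec$freqs[idx] > 0]
  pred <- predict_aperiodic(fit, spec$freqs[idx])
  mean(10 * log10(pmax(spec$power[idx], epsilon) / pred))
}

#' Band signal-to-noise ratio (dB)
#'
#' The maximum over band bins of `10 * log10(power / predicted)`: how far the
#' strongest peak in the band rises above the fitted 1/f background.
#'
#' @inheritParams corrected_power
#' @return Scalar SNR in dB.
#' @export
snr_db <- function(spec, fit, band, epsilon = 1e-15) {
  idx <- band_bins(spec, band)
  if (length(idx) == 0) stop("snr_db: band contains no frequency bins")
  idx <- idx[spec$freqs[idx] > 0]
  pred <- predict_aperiodic(fit, spec$freqs[idx])
  max(10 * log10(pmax(spec$power[idx], epsilon) / pred))
}
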