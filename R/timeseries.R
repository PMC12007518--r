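#' Construct a sampled multichannel time series
#'
#' The basic container for all stages of the analysis: a channels-by-time
#' matrix of voltages (conventionally microvolts) with a sampling rate and
#' channel labels.
#'
#' @param samples Numeric matrix, channels x time, or a numeric vector for a
#'   single channel. All values must be finite.
#' @param rate Sampling rate in Hz (> 0).
#' @param channel_labels Character vector of channel names, one per row of
#'   `samples`. Defaults to `"ch1"`, `"ch2"`, ...
#' @param meta Optional named list of provenance information (generator
#'   parameters, seeds, source file).
#'
#' @return An object of class `"eeg_ts"`: a list with elements `samples`,
#'   `rate`, `channel_labels`, `meta`.
#' @export
#'
#' @examples
#' ts <- time_series(sin(2 * pi * 10 * (0:999) / 250), rate = 250)
#' n_channels(ts)
#' duration(ts)
time_series <- function(samples, rate, channel_labels = NULL, meta = list()) {
  if (is.vector(samples) && is.numeric(samples)) {
    samples <- matrix(samples, nrow = 1L)
  }
  stopifnot(is.matrix(samples), is.numeric(samples))
  if (!all(is.finite(samples))) {
    stop("time_series: all samples must be finite")
  }
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("time_series: rate must be a single positive number (Hz)")
  }
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(nrow(samples)))
  }
  if (length(channel_labels) != nrow(samples)) {
    stop("time_series: channel count must equal label count")
  }
  structure(
    list(
      samples = samples,
      rate = as.numeric(rate),
      channel_labels = as.character(channel_labels),
      meta = meta
    ),
    class = "eeg_ts"
  )
}

#' @export
print.eeg_ts <- function(x, ...) {
  cat(sprintf(
    "<eeg_ts> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
    nrow(x$samples), ncol(x$samples), x$rate, duration(x)
  ))
  cat("  channels:", paste(utils::head(x$channel_labels, 8), collapse = ", "),
      if (length(x$channel_labels) > 8) "..." else "", "\n")
  invisible(x)
}

#' Number of channels of a time series
#' @param ts An `eeg_ts` object.
#' @return Integer channel count.
#' @export
n_channels <- function(ts) nrow(ts$samples)

#' Duration of a time series in seconds
#' @param ts An `eeg_ts` object.
#' @return Duration in seconds.
#' @export
duration <- function(ts) ncol(ts$samples) / ts$rate

#' Extract a single channel as a one-channel time series
#'
#' @param ts An `eeg_ts` object.
#' @param channel Channel label (character) or index (integer). For a
#'   one-channel input, `NULL` returns the input unchanged.
#' @return A one-channel `eeg_ts`.
#' @export
select_channel <- function(ts, channel = NULL) {
  stopifnot(inherits(ts, "eeg_ts"))
  if (is.null(channel)) {
    if (n_channels(ts) == 1L) return(ts)
    stop("select_channel: multichannel input requires an explicit channel")
  }
  if (is.character(channel)) {
    idx <- match(channel, ts$channel_labels)
    if (is.na(idx)) {
      stop(sprintf("select_channel: channel '%s' not found (available: %s)",
                   channel, paste(ts$channel_labels, collapse = ", ")))
    }
  } else {
    idx <- as.integer(channel)
    if (idx < 1L || idx > n_channels(ts)) stop("select_channel: index out of range")
  }
  time_series(ts$samples[idx, , drop = FALSE], ts$rate,
              ts$channel_labels[idx], ts$meta)
}

#' Define a frequency band
#'
#' @param name Band name, e.g. `"alpha"`.
#' @param f_lo,f_hi Band edges in Hz, `0 < f_lo < f_hi`. The upper edge is
#'   checked against the Nyquist frequency wherever the band meets a spectrum.
#' @return An object of class `"band"` with fields `name`, `f_lo`, `f_hi`.
#' @export
#'
#' @examples
#' band_definition("beta", 16, 30)
band_definition <- function(name, f_lo, f_hi) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(f_lo) || !is.numeric(f_hi) || f_lo <= 0 || f_hi <= f_lo) {
    stop("band_definition: need 0 < f_lo < f_hi")
  }
  structure(list(name = name, f_lo = as.numeric(f_lo), f_hi = as.numeric(f_hi)),
            class = "band")
}

#' @export
print.band <- function(x, ...) {
  cat(sprintf("<band> %s: %g-%g Hz\n", x$name, x$f_lo, x$f_hi))
  invisible(x)
}

#' Canonical alpha band (8-13 Hz)
#' @param f_lo,f_hi Band edges in Hz.
#' @return A `"band"` object.
#' @export
alpha_band <- function(f_lo = 8, f_hi = 13) band_definition("alpha", f_lo, f_hi)

#' Canonical beta band (16-30 Hz)
#' @param f_lo,f_hi Band edges in Hz.
#' @return A `"band"` object.
#' @export
beta_band <- function(f_lo = 16, f_hi = 30) band_definition("beta", f_lo, f_hi)
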