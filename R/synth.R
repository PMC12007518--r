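#' Specify a rhythm with optional phase-locked harmonics
#'
#' A rhythm is a base sinusoid plus, for each harmonic, a sinusoid at an
#' integer multiple of the base frequency whose phase is locked to the base
#' phase (`phase(m * f0) = m * phase(f0) + phase_lag`). All components are
#' multiplied by a common amplitude envelope, so harmonic power co-varies
#' perfectly with base power -- the signature of a nonsinusoidal waveform.
#'
#' @param base_freq Base frequency in Hz (> 0).
#' @param harmonics List of harmonics, each a list with elements `multiple`
#'   (integer >= 2), `rel_amplitude` (>= 0, relative to the base amplitude)
#'   and `phase_lag` (radians, default 0). Multiples must be distinct.
#' @param envelope An envelope descriptor from [envelope_constant()] or
#'   [envelope_random()].
#' @param amplitude Base sinusoid amplitude (microvolts), default 1.
#' @param freq_jitter Standard deviation (Hz) of slow random drift of the
#'   instantaneous base frequency (default 0: fixed frequency). Nonzero
#'   values broaden the spectral peak to the 1-2 Hz width typical of real
#'   alpha rhythms; harmonics follow the drift with their phase locking
#'   intact (a harmonic's instantaneous frequency is always `multiple` times
#'   the base's).
#' @param jitter_cutoff Low-pass cutoff (Hz) of the frequency drift
#'   (default 0.1).
#'
#' @return An object of class `"rhythm_spec"`.
#' @export
#'
#' @examples
#' # arc-shaped mu-like rhythm: 10 Hz base with a 20 Hz harmonic at half amplitude
#' rhythm_spec(10, harmonics = list(harmonic(2, 0.5)))
rhythm_spec <- function(base_freq, harmonics = list(),
                        envelope = envelope_constant(), amplitude = 1,
                        freq_jitter = 0, jitter_cutoff = 0.1) {
  if (!is.numeric(base_freq) || length(base_freq) != 1L || base_freq <= 0) {
    stop("rhythm_spec: base_freq must be a positive scalar (Hz)")
  }
  harmonics <- lapply(harmonics, function(h) {
    stopifnot(is.list(h), !is.null(h$multiple), !is.null(h$rel_amplitude))
    if (h$multiple < 2 || h$multiple != round(h$multiple)) {
      stop("rhythm_spec: harmonic multiples must be integers >= 2")
    }
    if (h$rel_amplitude < 0) stop("rhythm_spec: rel_amplitude must be >= 0")
    list(multiple = as.integer(h$multiple),
         rel_amplitude = as.numeric(h$rel_amplitude),
         phase_lag = as.numeric(if (is.null(h$phase_lag)) 0 else h$phase_lag))
  })
  mult <- vapply(harmonics, `[[`, integer(1), "multiple")
  if (anyDuplicated(mult)) stop("rhythm_spec: harmonic multiples must be distinct")
  stopifnot(inherits(envelope, "envelope_spec"), amplitude >= 0,
            freq_jitter >= 0, jitter_cutoff > 0)
  structure(list(base_freq = as.numeric(base_freq), harmonics = harmonics,
                 envelope = envelope, amplitude = as.numeric(amplitude),
                 freq_jitter = as.numeric(freq_jitter),
                 jitter_cutoff = as.numeric(jitter_cutoff)),
            class = "rhythm_spec")
}

#' @rdname rhythm_spec
#' @param multiple Integer harmonic multiple (>= 2).
#' @param rel_amplitude Amplitude relative to the base sinusoid (>= 0).
#' @param phase_lag Phase lag in radians relative to exact phase locking.
#' @export
harmonic <- function(multiple, rel_amplitude, phase_lag = 0) {
  list(multiple = multiple, rel_amplitude = rel_amplitude, phase_lag = phase_lag)
}

#' Amplitude envelope descriptors
#'
#' `envelope_constant()` keeps the rhythm amplitude fixed.
#' `envelope_random()` describes slow random amplitude modulation: Gaussian
#' noise low-pass filtered at `cutoff` Hz, standardized, exponentiated
#' (`exp(sigma * z)`) and normalized to mean 1. The envelope is therefore
#' log-normal, mimicking both the waxing and waning of resting-state rhythms
#' and the approximately log-normal distribution of EEG band power; `sigma`
#' sets the modulation depth (a band-power spread of roughly `8.7 * sigma`
#' dB across segments).
#'
#' @param cutoff Low-pass cutoff of the modulation in Hz (default 0.3).
#' @param sigma Log-amplitude standard deviation (default 1).
#' @param seed Optional integer seed for the envelope noise; when `NULL` the
#'   seed of the enclosing generator call is used.
#' @return An object of class `"envelope_spec"`.
#' @export
envelope_constant <- function() {
  structure(list(type = "constant"), class = "envelope_spec")
}

#' @rdname envelope_constant
#' @export
envelope_random <- function(cutoff = 0.3, sigma = 1, seed = NULL) {
  stopifnot(cutoff > 0, sigma > 0)
  structure(list(type = "random", cutoff = cutoff, sigma = sigma, seed = seed),
            class = "envelope_spec")
}

#' Specify the 1/f background noise
#'
#' @param exponent Log-log slope magnitude of power vs frequency (>= 0);
#'   0 gives white noise.
#' @param scale Power spectral density (microvolts^2/Hz) at 1 Hz.
#' @param seed Integer seed.
#' @return An object of class `"noise_spec"`.
#' @export
noise_spec <- function(exponent = 1.5, scale = 0.5, seed = 1L) {
  if (exponent < 0) stop("noise_spec: exponent must be >= 0")
  if (scale <= 0) stop("noise_spec: scale must be > 0")
  structure(list(exponent = as.numeric(exponent), scale = as.numeric(scale),
                 seed = as.integer(seed)), class = "noise_spec")
}

# Realize an envelope as a length-n vector with mean 1. `negate` flips the
# sign of the slow Gaussian before exponentiation, yielding an envelope whose
# rank correlation with the non-negated realization is exactly -1 while
# keeping the same log-normal marginal.
realize_envelope <- function(env, n, rate, fallback_seed, negate = FALSE) {
  if (env$type == "constant") return(rep(1, n))
  seed <- if (is.null(env$seed)) fallback_seed else env$seed
  withr::with_seed(as.integer(seed), {
    z <- stats::rnorm(n)
  })
  zl <- fft_lowpass(z, rate, env$cutoff)
  s <- stats::sd(zl)
  if (s == 0) return(rep(1, n))
  zl <- zl / s
  if (negate) zl <- -zl
  e <- exp(env$sigma * zl)
  e / mean(e)
}

# Ideal low-pass by zeroing FFT bins above the cutoff (keeps DC).
fft_lowpass <- function(x, rate, cutoff) {
  n <- length(x)
  f <- fft_freqs(n, rate)
  X <- stats::fft(x)
  X[abs(f) > cutoff] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

# Two-sided FFT frequency grid (Hz), matching stats::fft bin order.
fft_freqs <- function(n, rate) {
  k <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1))
  k * rate / n
}

#' Generate 1/f ("pink") background noise
#'
#' White Gaussian noise is shaped in the frequency domain so that the expected
#' one-sided power spectral density equals `scale * f^(-exponent)` above 1 Hz
#' (and throughout (0, Nyquist)); `exponent = 0` yields white noise. The
#' shaping is exact in expectation and deterministic for a given seed.
#'
#' @param n_samples Number of samples (>= 2).
#' @param rate Sampling rate in Hz.
#' @param noise A [noise_spec()].
#' @return A one-channel [time_series()] labelled `"noise"`.
#' @export
#'
#' @examples
#' ns <- gen_pink_noise(2500, 250, noise_spec(exponent = 1, seed = 42))
gen_pink_noise <- function(n_samples, rate, noise = noise_spec()) {
  if (!is.numeric(n_samples) || n_samples < 2) {
    stop("gen_pink_noise: n_samples must be >= 2")
  }
  if (rate <= 0) stop("gen_pink_noise: rate must be positive")
  stopifnot(inherits(noise, "noise_spec"))
  n <- as.integer(n_samples)
  withr::with_seed(noise$seed, {
    z <- stats::rnorm(n)
  })
  f <- fft_freqs(n, rate)
  # unit-variance white noise has one-sided density 2/rate; shape to the target
  gain <- rep(0, n)
  nz <- f != 0
  gain[nz] <- sqrt(noise$scale * rate / 2) * abs(f[nz])^(-noise$exponent / 2)
  X <- stats::fft(z) * gain
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  time_series(x, rate, "noise",
              meta = list(generator = "gen_pink_noise", noise = unclass(noise)))
}

#' Generate a rhythm with phase-locked harmonics
#'
#' Realizes a [rhythm_spec()]: a base sinusoid at `base_freq` plus each
#' harmonic at `multiple * base_freq` with amplitude
#' `rel_amplitude * amplitude` and phase `multiple * base_phase + phase_lag`,
#' all multiplied by the common envelope. Phase locking between base and
#' harmonics is exact by construction.
#'
#' @param spec A [rhythm_spec()].
#' @param duration Duration in seconds.
#' @param rate Sampling rate in Hz.
#' @param seed Integer seed (drives the random envelope, if any, and the
#'   random initial base phase).
#' @param random_phase Draw the base initial phase uniformly from the seed
#'   (default) or start at phase 0.
#' @return A one-channel [time_series()].
#' @export
#'
#' @examples
#' ts <- gen_rhythm(rhythm_spec(10, list(harmonic(2, 0.5))), 10, 250, seed = 1)
gen_rhythm <- function(spec, duration, rate, seed = 1L, random_phase = TRUE) {
  stopifnot(inherits(spec, "rhythm_spec"))
  n <- floor(duration * rate)
  if (n < rate / spec$base_freq) {
    stop("gen_rhythm: duration must cover at least one base period")
  }
  t <- (seq_len(n) - 1) / rate
  phi0 <- 0
  if (random_phase) {
    withr::with_seed(as.integer(seed) + 1L, phi0 <- stats::runif(1, 0, 2 * pi))
  }
  f_inst <- rep(spec$base_freq, n)
  if (spec$freq_jitter > 0) {
    withr::with_seed(as.integer(seed) + 2L, zj <- stats::rnorm(n))
    zj <- fft_lowpass(zj, rate, spec$jitter_cutoff)
    sj <- stats::sd(zj)
    if (sj > 0) f_inst <- f_inst + spec$freq_jitter * zj / sj
  }
  # base phase integrates the instantaneous frequency; harmonics use exact
  # integer multiples of it, so phase locking survives the drift
  theta <- 2 * pi * cumsum(f_inst) / rate + phi0
  x <- sin(theta)
  for (h in spec$harmonics) {
    x <- x + h$rel_amplitude * sin(h$multiple * theta + h$phase_lag)
  }
  env <- realize_envelope(spec$envelope, n, rate, fallback_seed = seed)
  x <- spec$amplitude * env * x
  time_series(x, rate, "rhythm",
              meta = list(generator = "gen_rhythm", base_freq = spec$base_freq,
                          n_harmonics = length(spec$harmonics), seed = seed))
}

#' Generate a broadband (genuine) beta rhythm
#'
#' A genuine beta rhythm has its own generator and a broader spectral peak
#' than the narrow harmonic peaks of a nonsinusoidal alpha rhythm. It is
#' realized as Gaussian noise shaped in the frequency domain by a Gaussian
#' bump centred at `center` with standard deviation `halfwidth / 2`
#' (truncated at `center +/- 1.5 * halfwidth`), scaled to the RMS of a
#' sinusoid with the given amplitude, and multiplied by the amplitude
#' envelope. The smooth bump mimics the rounded, several-Hz-wide peaks of
#' genuine beta rhythms.
#'
#' @param center Center frequency in Hz.
#' @param halfwidth Half width of the spectral bump in Hz (default 3; twice
#'   the Gaussian standard deviation).
#' @param amplitude Equivalent sinusoid amplitude (microvolts).
#' @param envelope An envelope descriptor.
#' @param duration Duration in seconds.
#' @param rate Sampling rate in Hz.
#' @param seed Integer seed.
#' @return A one-channel [time_series()].
#' @export
gen_broadband_rhythm <- function(center, halfwidth = 3, amplitude = 1,
                                 envelope = envelope_constant(),
                                 duration, rate, seed = 1L) {
  stopifnot(center > 0, halfwidth > 0, amplitude >= 0)
  if (center + 1.5 * halfwidth >= rate / 2) {
    stop("gen_broadband_rhythm: band exceeds the Nyquist frequency")
  }
  n <- floor(duration * rate)
  if (n < 2) stop("gen_broadband_rhythm: duration too short")
  withr::with_seed(as.integer(seed), z <- stats::rnorm(n))
  f <- fft_freqs(n, rate)
  X <- stats::fft(z)
  sd_f <- halfwidth / 2
  gain <- exp(-((abs(f) - center)^2) / (2 * sd_f^2))
  gain[abs(abs(f) - center) > 1.5 * halfwidth] <- 0
  X <- X * gain
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x <- x * (amplitude / sqrt(2)) / s
  env <- realize_envelope(envelope, n, rate, fallback_seed = seed)
  time_series(env * x, rate, "beta",
              meta = list(generator = "gen_broadband_rhythm", center = center,
                          halfwidth = halfwidth, seed = seed))
}

#' Specify a simulated alpha/beta coupling scenario
#'
#' Three regimes of dependence between alpha- and beta-band power:
#' \describe{
#'   \item{`"harmonic"`}{a single nonsinusoidal alpha rhythm whose beta-band
#'     content is solely its phase-locked harmonic; alpha- and beta-power are
#'     positively correlated by construction. `beta_rhythm` must be absent.}
#'   \item{`"anticorrelated"`}{a sinusoidal alpha rhythm and a genuine beta
#'     rhythm whose envelope is the rank reflection of the alpha envelope
#'     (the same slow Gaussian with its sign flipped before exponentiation),
#'     so the source amplitudes have rank correlation exactly -1.}
#'   \item{`"independent"`}{sinusoidal alpha and genuine beta with
#'     independently seeded envelopes.}
#' }
#' 1/f background noise is added in all regimes.
#'
#' @param regime One of `"anticorrelated"`, `"independent"`, `"harmonic"`.
#' @param alpha_rhythm A [rhythm_spec()]; must have no harmonics unless
#'   `regime = "harmonic"`.
#' @param beta_rhythm For the two-rhythm regimes, a list describing the
#'   genuine beta source: `center` (Hz; `NULL` draws uniformly from
#'   `center_range`), `halfwidth` (Hz), `amplitude`. Must be `NULL` for the
#'   harmonic regime.
#' @param noise A [noise_spec()].
#' @param duration Duration in seconds (default 300, i.e. 5 minutes of
#'   resting-state data).
#' @param rate Sampling rate in Hz (default 250).
#' @param seed Integer seed; all randomness (envelopes, noise, beta center
#'   frequency) derives from it deterministically.
#' @return An object of class `"scenario_spec"`.
#' @export
#'
#' @examples
#' sc <- scenario_spec("harmonic", seed = 7)
#' out <- gen_scenario(sc)
#' out$ground_truth$regime
scenario_spec <- function(regime = c("harmonic", "anticorrelated", "independent"),
                          alpha_rhythm = NULL, beta_rhythm = NULL,
                          noise = NULL, duration = 300, rate = 250, seed = 1L) {
  regime <- match.arg(regime)
  seed <- as.integer(seed)
  if (is.null(alpha_rhythm)) {
    # 10 Hz alpha with log-normal amplitude modulation and slow frequency
    # drift giving a realistic ~1 Hz wide spectral peak
    harmonics <- if (regime == "harmonic") list(harmonic(2, 0.5)) else list()
    alpha_rhythm <- rhythm_spec(10, harmonics,
                                envelope_random(cutoff = 0.2, sigma = 1),
                                freq_jitter = 0.25, jitter_cutoff = 1.0)
  }
  stopifnot(inherits(alpha_rhythm, "rhythm_spec"))
  if (regime == "harmonic") {
    if (!is.null(beta_rhythm)) {
      stop("scenario_spec: harmonic regime must not carry an independent beta rhythm")
    }
    if (length(alpha_rhythm$harmonics) == 0) {
      stop("scenario_spec: harmonic regime requires alpha harmonics")
    }
  } else {
    if (length(alpha_rhythm$harmonics) > 0) {
      stop("scenario_spec: non-harmonic regimes require a sinusoidal alpha rhythm")
    }
    if (is.null(beta_rhythm)) {
      beta_rhythm <- list(center = NULL, center_range = c(18, 26),
                          halfwidth = 3, amplitude = 0.5)
    }
    beta_rhythm <- utils::modifyList(
      list(center = NULL, center_range = c(18, 26), halfwidth = 3, amplitude = 0.5),
      beta_rhythm)
    if (beta_rhythm$amplitude <= 0 && alpha_rhythm$amplitude <= 0) {
      stop("scenario_spec: degenerate scenario with no rhythms")
    }
  }
  if (is.null(noise)) noise <- noise_spec(seed = seed + 1000L)
  stopifnot(inherits(noise, "noise_spec"), duration > 0, rate > 0)
  structure(list(regime = regime, alpha_rhythm = alpha_rhythm,
                 beta_rhythm = beta_rhythm, noise = noise,
                 duration = duration, rate = rate, seed = seed),
            class = "scenario_spec")
}

#' Generate a synthetic EEG scenario with ground truth
#'
#' Realizes a [scenario_spec()] as a one-channel time series (alpha source +
#' genuine beta source where applicable + 1/f noise) together with the ground
#' truth: the regime, the expected sign of the alpha/beta power correlation,
#' and the source amplitude envelopes.
#'
#' @param spec A [scenario_spec()].
#' @return A list with elements `ts` (one-channel [time_series()]) and
#'   `ground_truth` (list: `regime`, `expected_regime_call`, `alpha_envelope`,
#'   `beta_envelope`, `beta_center`).
#' @export
gen_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  n <- floor(spec$duration * spec$rate)
  seed <- spec$seed

  alpha_spec <- spec$alpha_rhythm
  if (alpha_spec$envelope$type == "random" && is.null(alpha_spec$envelope$seed)) {
    alpha_spec$envelope$seed <- seed
  }
  env_a <- realize_envelope(alpha_spec$envelope, n, spec$rate, fallback_seed = seed)

  alpha_ts <- gen_rhythm(alpha_spec, spec$duration, spec$rate, seed = seed)
  x <- alpha_ts$samples[1, ]
  env_b <- NULL
  beta_center <- NA_real_

  if (spec$regime != "harmonic") {
    b <- spec$beta_rhythm
    beta_center <- b[["center"]]  # exact match: "center" may be absent
    if (is.null(beta_center)) {
      withr::with_seed(seed + 2L,
        beta_center <- stats::runif(1, b$center_range[1], b$center_range[2]))
    }
    env_b <- switch(spec$regime,
      # same slow Gaussian as the alpha envelope with its sign flipped:
      # rank correlation with env_a is exactly -1, marginal unchanged
      anticorrelated = realize_envelope(alpha_spec$envelope, n, spec$rate,
                                        fallback_seed = seed, negate = TRUE),
      independent = realize_envelope(envelope_random(seed = seed + 3L),
                                     n, spec$rate, fallback_seed = seed + 3L)
    )
    carrier <- gen_broadband_rhythm(beta_center, b$halfwidth, b$amplitude,
                                    envelope_constant(), spec$duration,
                                    spec$rate, seed = seed + 4L)
    x <- x + env_b * carrier$samples[1, ]
  } else {
    # for the harmonic regime the beta envelope IS the alpha envelope
    env_b <- env_a
  }

  ns <- gen_pink_noise(n, spec$rate, spec$noise)
  x <- x + ns$samples[1, ]

  expected <- switch(spec$regime, harmonic = "positive",
                     anticorrelated = "anticorrelated",
                     independent = "independent")
  ts <- time_series(x, spec$rate, "C3",
                    meta = list(generator = "gen_scenario", regime = spec$regime,
                                seed = seed, beta_center = beta_center))
  list(ts = ts,
       ground_truth = list(regime = spec$regime,
                           expected_regime_call = expected,
                           alpha_envelope = env_a,
                           beta_envelope = env_b,
                           beta_center = beta_center))
}

#' Mix source time series into sensor channels
#'
#' Forward model for testing the spatial-filtering stage: sensor channels are
#' a linear mixture of the sources plus optional white sensor noise.
#'
#' @param sources An `eeg_ts` with one row per source.
#' @param mixing Numeric matrix, channels x sources.
#' @param sensor_noise Standard deviation of i.i.d. Gaussian sensor noise
#'   added to each channel (0 for none).
#' @param seed Integer seed for the sensor noise.
#' @param channel_labels Optional sensor labels.
#' @return A multichannel [time_series()].
#' @export
mix_forward <- function(sources, mixing, sensor_noise = 0, seed = 1L,
                        channel_labels = NULL) {
  stopifnot(inherits(sources, "eeg_ts"), is.matrix(mixing))
  if (ncol(mixing) != n_channels(sources)) {
    stop("mix_forward: mixing column count must equal the number of sources")
  }
  y <- mixing %*% sources$samples
  if (sensor_noise > 0) {
    withr::with_seed(as.integer(seed),
      y <- y + matrix(stats::rnorm(length(y), sd = sensor_noise), nrow = nrow(y)))
  }
  time_series(y, sources$rate, channel_labels,
              meta = list(generator = "mix_forward", n_sources = n_channels(sources)))
}
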