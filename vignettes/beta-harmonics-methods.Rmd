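---
title: "Screening beta-band peaks for alpha harmonics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening beta-band peaks for alpha harmonics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(betaharmonics)
```

## The problem

Human resting-state EEG is dominated by alpha-band rhythms (8–13 Hz) that
are often nonsinusoidal: the arc-shaped sensorimotor mu rhythm is the
canonical example, and many posterior alpha rhythms share the property. A
nonsinusoidal periodic waveform has Fourier energy at integer multiples of
its base frequency, so a 10 Hz rhythm with a non-sine shape contributes a
narrow, phase-locked spectral peak at 20 Hz — squarely inside the canonical
beta band (16–30 Hz). Band-pass filtering at 16–30 Hz cannot tell this
harmonic apart from a genuine beta oscillation with its own generator, and
any beta-band measure computed downstream (burst statistics, biomarkers,
coupling estimates) will conflate the two. The stronger the alpha rhythm,
the stronger its harmonic, simply by linearity of the Fourier transform.

This package implements a screening workflow for that confound:

1. **Percentile spectra.** The recording is cut into fixed-length segments;
   segments are sorted into groups by beta-band power and the mean spectrum
   of each group is computed. If the beta content is harmonic, alpha power
   rises in lockstep with beta power across groups.
2. **1/f-corrected rank correlation.** For each group, an aperiodic (1/f)
   power-law is fitted to the group-mean spectrum and alpha- and beta-band
   power are expressed in dB above the fit. The Spearman rank correlation
   `rho` of the corrected powers across groups is thresholded into three
   regimes: positive (harmonic-like), anticorrelated, independent.
3. **Harmonic peak rule.** On the mean spectrum of the top-20% high-alpha
   segments, the alpha and beta peak frequencies are located on the
   corrected spectrum; the beta peak is called *harmonic* when
   `|f_beta - 2 f_alpha| <= 1 bin`, provided the alpha SNR exceeds 5 dB.
4. **SSD.** For multichannel input, spatio-spectral decomposition extracts
   the spatial component with the highest alpha-band SNR before steps 1–3.

## Spectral estimation

Each segment's spectrum is a mean-removed, Hann-windowed one-sided
periodogram with density normalization, so that the integral of power over
frequency approximates the segment variance and the frequency resolution is
`1/seg_len`. No Welch overlap or multitaper variants are used: percentile
sorting needs one spectrum per disjoint segment. The implementation is
tested bin-by-bin against a naive direct DFT reference at `1e-10` relative
tolerance, and for Parseval consistency at 1%.

The default segment length is 3 s (resolution 1/3 Hz). A 2 s segment length
is an equally defensible convention and is exposed via
`analysis_config(seg_len = )`; the package treats the choice as
configuration, and `seglen_sweep()` checks conclusions across 0.5–4 s. At
0.5 s the bins are 2 Hz wide and the one-bin harmonic tolerance becomes
permissive, so sweep output at that resolution is reported but should not
be over-read.

## Aperiodic (1/f) correction

The aperiodic component is fitted by ordinary least squares of
`log10(power)` on `log10(frequency)` over 1–45 Hz, excluding the alpha and
beta bands (widened by 2 bins) so oscillatory peaks do not bias the slope.
On noiseless power-law input the fit is exact to machine precision; on
pink noise the exponent is recovered within ±0.1 when at least 50 segments
are averaged. No knee-parameter model is fitted: over 1–45 Hz, resting EEG
background is adequately log-log linear for screening purposes.

Correction is performed in the log-power domain: corrected band power is
the mean over band bins of `10 log10(power / fit)` dB. "Subtracting" the
1/f estimate could equally be read as linear-domain subtraction; the
log-domain form was chosen because it is scale-invariant (a gain change in
the recording cancels exactly, absorbed by the fit offset — asserted by a
property test) and because it makes corrected power and the dB SNR gate two
readings of the same quantity (mean vs. max over band bins). Zero-power
bins are floored at `1e-15` before logs.

The alpha band default is 8–13 Hz, the beta band 16–30 Hz, both
configurable. Band membership is a closed interval on both edges, with a
`1e-6`-bin tolerance absorbing floating-point grid error.

## Percentile spectra and the regime call

Segments are ranked by beta band power (ties broken by segment index, so
the construction is deterministic) and assigned to contiguous rank blocks;
when the segment count is not a multiple of the group count the extra
segments go to the lowest groups. Group-mean sort-band power is
non-decreasing by construction and asserted on every run. The correlation
is computed across the 20 group-level corrected powers, not across
individual segments: per-segment spectra of 3 s are too noisy for a stable
per-segment correction, and group averaging is what makes the percentile
spectrum interpretable in the first place.

The regime thresholds (`rho >= 0.5` positive, `rho <= -0.5`
anticorrelated, otherwise independent) are a package convention: the
substantive claim in the underlying analysis is the *sign pattern*, and no
numeric cutoff separates the scenarios in principle. The thresholds are
configurable and every regime call carries its `rho`, so users can apply
their own judgement. No p-values or confidence intervals are attached: with
20 ordered groups the sampling distribution of `rho` is not the textbook
null, and the measure is a screen, not a test.

## Harmonic verdict

Peak finding operates on the 1/f-corrected mean spectrum of the selected
high-alpha segments, and a peak must be a strict local maximum of corrected
power; a band whose corrected power decreases monotonically has no peak,
which prevents band-edge argmax artifacts. Ties between equal local maxima
go to the lower frequency. Recordings whose alpha SNR (max corrected dB in
the alpha band) is at or below 5 dB are *excluded*: without a clear alpha
rhythm the harmonic question is moot. A recording passing the gate but
showing no beta local maximum is reported as `no-beta-peak` (counted as
non-harmonic in cohort percentages, but kept as its own category so cohort
audits can see it).

Defaults — top fraction 0.2, SNR threshold 5 dB, tolerance 1 bin — are the
conventional settings for this analysis and are all exposed in
`analysis_config()`.

## The synthetic generator

The generator is first-class, tested code: it defines the conditions under
which the pipeline's recovery properties are demonstrated.

* **Background**: 1/f noise synthesized by frequency-domain shaping of
  white Gaussian noise, one-sided density `scale * f^-exponent` (defaults:
  exponent 1.5, scale 0.5 µV²/Hz at 1 Hz — a typical resting-EEG
  background). Shaping is exact in expectation and seedable.
* **Rhythms**: a base sinusoid plus optional harmonics at integer
  multiples, each with a relative amplitude and phase lag; harmonic phase
  is `multiple × base phase + lag` by construction, so phase locking is
  exact even when the base frequency drifts. Scenario alpha rhythms use a
  10 Hz base with a 0.25 Hz-SD slow frequency drift (low-passed at 1 Hz),
  which gives the ~1 Hz-wide alpha peak seen in real EEG rather than the
  single-bin line of a fixed sinusoid. The nonsinusoidal (harmonic-regime)
  alpha carries a single 2× harmonic at relative amplitude 0.5.
* **Envelopes**: slow amplitude modulation `exp(sigma * z)`, with `z`
  Gaussian noise low-passed at 0.2 Hz and standardized, normalized to mean
  1. The log-normal form mirrors the approximately log-normal distribution
  of EEG band power and yields a wide, evenly spaced dynamic range of band
  power across percentile groups (about `8.7 * sigma` dB; default
  `sigma = 1`).
* **Genuine beta**: Gaussian noise shaped by a Gaussian spectral bump
  (default center drawn uniformly in 18–26 Hz per seed, half-width 3 Hz,
  amplitude 0.5), amplitude-modulated like the other rhythms. The rounded,
  several-Hz-wide bump reproduces the broad peaks of genuine beta rhythms,
  in contrast to narrow harmonic peaks.
* **Regimes**: *harmonic* — one nonsinusoidal alpha rhythm, beta content
  solely its harmonic; *anticorrelated* — sinusoidal alpha plus genuine
  beta whose envelope uses the sign-flipped latent Gaussian of the alpha
  envelope, making the source-amplitude rank correlation exactly −1;
  *independent* — independently seeded envelopes. Identical scenario
  specifications (including seeds) produce bit-identical output.

What the generator does *not* emulate: multiple simultaneous alpha
generators, non-stationary 1/f dynamics, line noise, artifacts
(ocular/muscular), or mixtures of harmonic and genuine beta in one
recording. Passing recovery tests therefore demonstrates that the pipeline
measures what it claims under clean, single-mechanism conditions — not that
real recordings are unambiguous. In particular, a genuine beta generator
that happens to sit at twice the alpha peak is indistinguishable from a
harmonic by peak geometry alone; the simulations quantify exactly this
(regime recovery uses randomly placed beta centers, verdict recovery uses a
22 Hz center two bins clear of the harmonic location).

## SSD

`ssd_decompose()` maximizes alpha-band covariance against the summed
covariance of two flanking bands (defaults: signal 8–13 Hz, flanks 6–7 and
14–15 Hz) via a generalized symmetric eigendecomposition, solved by
whitening the flank covariance. The flank covariance is shrunk toward the
trace-scaled identity (coefficient `1e-6`) for numerical stability, and a
rank-deficient flank covariance is handled by restriction to its principal
subspace with a warning. Every returned filter/eigenvalue pair satisfies
the generalized eigenvalue equation with residual below `1e-8`
(asserted in tests). Following the analysis this package supports, the
component passed downstream is the one with the highest *measured*
alpha-band SNR of its own spectrum, not the one with the largest
eigenvalue — the two usually coincide, but the SNR criterion is the
substantive one.

Butterworth order-4 forward–backward filtering (`signal::filtfilt`)
provides the zero-phase band-passes.

## Problem sizes and numerical choices

Simulation studies in the tests and the acceptance script use 5-minute
single-channel recordings at 250 Hz (100 segments of 3 s), 50 seeds per
condition, and 2-minute 8-channel mixtures for SSD benchmarks. These sizes
mirror typical resting-state blocks and give stable percentile groups
(5 segments per group at 20 groups).

Degenerate inputs are rejected with messages rather than coerced:
recordings shorter than one segment, bands with no bins or beyond Nyquist,
fewer than 5 bins left for the aperiodic fit, more groups than segments,
scenario specifications whose regime contradicts their rhythm content.
Determinism is part of the contract: identical input and configuration
produce byte-identical CSV/JSON outputs, and run records echo every
numeric parameter that affects results (and deliberately contain no
timestamps).

## A worked example

```{r example}
out <- gen_scenario(scenario_spec("harmonic", seed = 7))
res <- run_recording(out$ts)
res$regime
res$verdict
```

```{r figure}
plot_percentile_spectrum(
  build_percentile_spectrum(segment(out$ts, 3), n_groups = 5))
```

The five curves are the group-mean spectra after sorting segments by
beta-band power: in the harmonic regime the 10 Hz alpha peak and the 20 Hz
peak rise together across groups.

## Known limitations

* The regime call reduces a rich dependence structure to one coefficient;
  concurrent harmonic and genuine beta, or power-coupled distinct
  generators, can produce positive `rho` without the beta peak being a
  harmonic. The harmonic verdict is the sharper instrument; the regime call
  is a screen.
* Phase-based confirmation (bicoherence, cross-frequency lagged coherence,
  instantaneous-frequency tracking) is out of scope; the package's calls
  are based on power and peak geometry only.
* The aperiodic model has no knee; fits over ranges much wider than
  1–45 Hz, or on recordings with strong low-frequency artifacts, need a
  different fit range.
* EDF/BrainVision/FIF readers are not included; multichannel data enter
  through the TSV + JSON sidecar format or in-memory `time_series()`
  objects.
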