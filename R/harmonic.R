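#' Select the segments with the highest alpha-band power
#'
#' Keeps the `ceiling(fraction * n)` segments with the highest alpha band
#' power (top 20% by default, matching the high-alpha episodes on which peak
#' frequencies are estimated). Ties are broken by segment index (stable).
#'
#' @param segset A [segment()] result.
#' @param alpha Alpha [band_definition()] (default 8-13 Hz).
#' @param fraction Proportion of segments to keep, in (0, 1].
#' @return A `"segment_set"` holding the selected segments (in original
#'   order).
#' @export
select_high_alpha_segments <- function(segset, alpha = alpha_band(),
                                       fraction = 0.2) {
  stopifnot(inherits(segset, "segment_set"))
  if (fraction <= 0 || fraction > 1) {
    stop("select_high_alpha_segments: fraction must be in (0, 1]")
  }
  n <- nrow(segset$segments)
  k <- ceiling(fraction * n)
  spectra <- segment_spectra(segset)
  apow <- vapply(spectra, band_power, numeric(1), band = alpha)
  keep <- sort(order(apow, decreasing = TRUE)[seq_len(k)])
  out <- segset
  out$segments <- segset$segments[keep, , drop = FALSE]
  out
}

#' Locate the spectral peak of a band on the 1/f-corrected spectrum
#'
#' Among band bins that are local maxima of the corrected power (strictly
#' greater than both neighbouring bins), returns the frequency of the bin
#' with the largest corrected power; ties go to the lower frequency. Returns
#' `NA` when the band contains no local maximum, which prevents a
#' monotonically decreasing spectrum from yielding a spurious band-edge
#' "peak".
#'
#' @param spec A `"spectrum_est"`.
#' @param band A [band_definition()].
#' @param fit An `"aperiodic_fit"` for the same spectrum.
#' @param epsilon Power floor (default 1e-15).
#' @return Peak frequency in Hz, or `NA_real_` if absent.
#' @export
find_peak <- function(spec, band, fit, epsilon = 1e-15) {
  stopifnot(inherits(spec, "spectrum_est"), inherits(band, "band"),
            inherits(fit, "aperiodic_fit"))
  pos <- which(spec$freqs > 0)
  corr <- 10 * log10(pmax(spec$power[pos], epsilon) /
                       predict_aperiodic(fit, spec$freqs[pos]))
  freqs <- spec$freqs[pos]
  eps <- spec$resolution * 1e-6
  in_band <- freqs >= band$f_lo - eps & freqs <= band$f_hi + eps
  if (!any(in_band)) stop("find_peak: band contains no frequency bins")
  m <- length(corr)
  is_locmax <- c(FALSE, corr[2:(m - 1)] > corr[1:(m - 2)] &
                        corr[2:(m - 1)] > corr[3:m], FALSE)
  cand <- which(in_band & is_locmax)
  if (length(cand) == 0) return(NA_real_)
  # ties (within 1e-9 dB, absorbing float rounding) go to the lower frequency
  best <- cand[corr[cand] >= max(corr[cand]) - 1e-9][1]
  freqs[best]
}

#' Harmonic classification of a beta peak
#'
#' A beta peak is called harmonic when it sits at twice the alpha peak
#' frequency, allowing a deviation of `tol_bins` frequency bins from the
#' exact 2:1 relationship: `|f_beta - 2 * f_alpha| <= tol_bins * bin_width`.
#'
#' @param f_alpha,f_beta Peak frequencies in Hz.
#' @param bin_width Spectral resolution in Hz (1 / segment length).
#' @param tol_bins Allowed deviation in bins (default 1).
#' @return Logical.
#' @export
#'
#' @examples
#' classify_harmonic(10, 20, 1 / 3)        # TRUE
#' classify_harmonic(10, 20.33, 1 / 3)     # TRUE (within one bin)
#' classify_harmonic(10, 25, 1 / 3)        # FALSE
classify_harmonic <- function(f_alpha, f_beta, bin_width, tol_bins = 1) {
  stopifnot(is.numeric(f_alpha), is.numeric(f_beta), bin_width > 0,
            tol_bins >= 0)
  abs(f_beta - 2 * f_alpha) <= tol_bins * bin_width + bin_width * 1e-6
}

#' Harmonic verdict for one recording
#'
#' Full single-recording pipeline: segment, keep the top-fraction high-alpha
#' segments, average their spectra, fit the aperiodic component, gate on the
#' alpha-band SNR (recordings at or below the threshold are `"excluded"`),
#' locate the alpha and beta peaks on the corrected mean spectrum, and apply
#' the one-bin harmonic rule.
#'
#' @param ts A one-channel [time_series()].
#' @param cfg An [analysis_config()]; its `seg_len`, `alpha`, `beta`,
#'   `top_fraction`, `snr_threshold_db`, `tol_bins`, `fit_range`,
#'   `fit_margin_bins` fields are used.
#' @return An object of class `"harmonic_verdict"`: list with `f_alpha`,
#'   `f_beta`, `ratio`, `bin_width`, `tol_bins`, `alpha_snr`, `is_harmonic`
#'   (logical, `NA` when excluded), and `verdict`, one of `"harmonic"`,
#'   `"non-harmonic"`, `"no-beta-peak"`, `"excluded"`.
#' @export
#'
#' @examples
#' sc <- gen_scenario(scenario_spec("harmonic", seed = 11, duration = 120))
#' participant_verdict(sc$ts)
participant_verdict <- function(ts, cfg = analysis_config()) {
  stopifnot(inherits(ts, "eeg_ts"), inherits(cfg, "analysis_config"))
  segset <- segment(ts, cfg$seg_len)
  n <- nrow(segset$segments)
  if (n < ceiling(1 / cfg$top_fraction)) {
    stop(sprintf(
      "participant_verdict: too few segments (%d) for top-%g%% selection",
      n, 100 * cfg$top_fraction))
  }
  high <- select_high_alpha_segments(segset, cfg$alpha, cfg$top_fraction)
  sp <- mean_spectrum(segment_spectra(high))
  bin_width <- sp$resolution
  margin <- cfg$fit_margin_bins * bin_width
  excl <- list(
    band_definition("alpha", max(cfg$alpha$f_lo - margin, bin_width),
                    cfg$alpha$f_hi + margin),
    band_definition("beta", max(cfg$beta$f_lo - margin, bin_width),
                    cfg$beta$f_hi + margin)
  )
  fit <- fit_aperiodic(sp, fit_range = cfg$fit_range, excluded = excl)
  alpha_snr <- snr_db(sp, fit, cfg$alpha)

  verdict <- list(f_alpha = NA_real_, f_beta = NA_real_, ratio = NA_real_,
                  bin_width = bin_width, tol_bins = cfg$tol_bins,
                  alpha_snr = alpha_snr, is_harmonic = NA, verdict = "excluded")
  class(verdict) <- "harmonic_verdict"

  if (alpha_snr <= cfg$snr_threshold_db) return(verdict)
  f_alpha <- find_peak(sp, cfg$alpha, fit)
  if (is.na(f_alpha)) return(verdict)  # no alpha rhythm to speak of

  verdict$f_alpha <- f_alpha
  f_beta <- find_peak(sp, cfg$beta, fit)
  if (is.na(f_beta)) {
    verdict$is_harmonic <- FALSE
    verdict$verdict <- "no-beta-peak"
    return(verdict)
  }
  verdict$f_beta <- f_beta
  verdict$ratio <- f_beta / f_alpha
  verdict$is_harmonic <- classify_harmonic(f_alpha, f_beta, bin_width,
                                           cfg$tol_bins)
  verdict$verdict <- if (verdict$is_harmonic) "harmonic" else "non-harmonic"
  verdict
}

#' @export
print.harmonic_verdict <- function(x, ...) {
  cat(sprintf(
    "<harmonic_verdict> %s | alpha %.2f Hz, beta %s Hz, alpha SNR %.1f dB\n",
    x$verdict, x$f_alpha,
    if (is.na(x$f_beta)) "--" else sprintf("%.2f", x$f_beta), x$alpha_snr))
  invisible(x)
}

#' Summarize harmonic verdicts across a cohort
#'
#' @param verdicts A list of `"harmonic_verdict"` objects.
#' @return A list with counts per category, `n`, `n_included`
#'   (non-excluded), and `pct_harmonic` — the percentage of harmonic
#'   classifications among included recordings (`NA` if all are excluded).
#' @export
#'
#' @examples
#' # 3 harmonic + 1 non-harmonic + 1 excluded -> 75% harmonic
cohort_summary <- function(verdicts) {
  if (length(verdicts) == 0) stop("cohort_summary: empty verdict list")
  stopifnot(all(vapply(verdicts, inherits, logical(1), "harmonic_verdict")))
  v <- vapply(verdicts, `[[`, character(1), "verdict")
  counts <- c(harmonic = sum(v == "harmonic"),
              `non-harmonic` = sum(v == "non-harmonic"),
              `no-beta-peak` = sum(v == "no-beta-peak"),
              excluded = sum(v == "excluded"))
  n_inc <- length(v) - counts[["excluded"]]
  pct <- if (n_inc > 0) 100 * counts[["harmonic"]] / n_inc else NA_real_
  list(counts = counts, n = length(v), n_included = n_inc,
       pct_harmonic = pct)
}
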