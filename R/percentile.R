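#' Build a percentile spectrum
#'
#' Segments are ranked by their power in a sorting band (typically beta,
#' 16-30 Hz), assigned to contiguous rank groups, and the group-mean spectrum
#' is computed per group. The resulting family of spectra shows how power in
#' every other frequency band varies with the sorting band's power: a
#' beta-sorted percentile spectrum in which alpha power rises with beta power
#' hints at a harmonic relationship.
#'
#' Group sizes differ by at most one; when `n_segments` is not a multiple of
#' `n_groups` the extra segments go to the lowest-rank groups. Ties in band
#' power are broken by segment index (stable sort).
#'
#' @param segset A [segment()] result.
#' @param sort_band [band_definition()] whose power orders the segments
#'   (default beta, 16-30 Hz).
#' @param n_groups Number of percentile groups (>= 2, <= number of segments).
#' @return An object of class `"percentile_spectrum"`: list with `n_groups`,
#'   `sort_band`, `group_mean_spectra` (list of `"spectrum_est"`, ascending
#'   sort-band power), `group_sizes`, `group_sort_power` (mean sort-band
#'   power per group), `segment_sort_power`, `seg_len`, `rate`.
#' @export
#'
#' @examples
#' sc <- gen_scenario(scenario_spec("harmonic", seed = 3, duration = 60))
#' ps <- build_percentile_spectrum(segment(sc$ts, 3), n_groups = 5)
#' ps$group_sort_power  # non-decreasing
build_percentile_spectrum <- function(segset, sort_band = beta_band(),
                                      n_groups = 20) {
  stopifnot(inherits(segset, "segment_set"), inherits(sort_band, "band"))
  n_seg <- nrow(segset$segments)
  if (n_groups < 2) stop("build_percentile_spectrum: n_groups must be >= 2")
  if (n_groups > n_seg) {
    stop("build_percentile_spectrum: more groups than segments")
  }
  spectra <- segment_spectra(segset)
  sort_power <- vapply(spectra, band_power, numeric(1), band = sort_band)
  ord <- order(sort_power)  # stable: ties keep segment order

  base <- n_seg %/% n_groups
  extra <- n_seg %% n_groups
  sizes <- rep(base, n_groups) + c(rep(1L, extra), rep(0L, n_groups - extra))
  grp_end <- cumsum(sizes)
  grp_start <- c(1L, utils::head(grp_end, -1) + 1L)

  group_spectra <- vector("list", n_groups)
  group_power <- numeric(n_groups)
  for (g in seq_len(n_groups)) {
    members <- ord[grp_start[g]:grp_end[g]]
    group_spectra[[g]] <- mean_spectrum(spectra[members])
    group_power[g] <- mean(sort_power[members])
  }
  stopifnot(!is.unsorted(group_power))  # monotone by construction

  structure(list(n_groups = as.integer(n_groups), sort_band = sort_band,
                 group_mean_spectra = group_spectra,
                 group_sizes = sizes, group_sort_power = group_power,
                 segment_sort_power = sort_power,
                 seg_len = segset$seg_len, rate = segset$rate),
            class = "percentile_spectrum")
}

#' @export
print.percentile_spectrum <- function(x, ...) {
  cat(sprintf("<percentile_spectrum> %d groups sorted by %s power (%g-%g Hz)\n",
              x$n_groups, x$sort_band$name, x$sort_band$f_lo, x$sort_band$f_hi))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties, as used to quantify the
#' dependence between 1/f-corrected alpha- and beta-power across percentile
#' groups.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("spearman_rho: inputs must have equal length")
  if (length(x) < 3) stop("spearman_rho: need at least 3 observations")
  stats::cor(x, y, method = "spearman")
}

#' Classify the alpha/beta power-coupling regime of a percentile spectrum
#'
#' For each percentile group, the aperiodic (1/f) component is fitted to the
#' group-mean spectrum and the corrected alpha- and beta-band powers (dB above
#' the fit) are computed. The Spearman rank correlation `rho` of the two
#' across groups is thresholded into one of three regimes: `"positive"`
#' (`rho >= threshold`, consistent with a harmonic relationship),
#' `"anticorrelated"` (`rho <= -threshold`), else `"independent"`.
#'
#' @param ps A [build_percentile_spectrum()] result.
#' @param alpha,beta Analysis bands (defaults 8-13 and 16-30 Hz).
#' @param fit_range Aperiodic fit range in Hz.
#' @param fit_margin_bins Number of frequency bins by which the excluded
#'   alpha/beta bands are widened before the fit (default 2).
#' @param threshold Regime threshold on `|rho|` (default 0.5; the sign
#'   pattern, not the cutoff, is the substantive claim).
#' @return An object of class `"regime_call"`: list with `rho`, `regime`,
#'   `threshold`, `alpha_db`, `beta_db` (per-group corrected powers).
#' @export
alpha_beta_dependence <- function(ps, alpha = alpha_band(), beta = beta_band(),
                                  fit_range = c(1, 45), fit_margin_bins = 2,
                                  threshold = 0.5) {
  stopifnot(inherits(ps, "percentile_spectrum"))
  if (ps$n_groups < 3) {
    stop("alpha_beta_dependence: need at least 3 groups for a rank correlation")
  }
  res <- ps$group_mean_spectra[[1]]$resolution
  margin <- fit_margin_bins * res
  excl <- list(
    band_definition(alpha$name, max(alpha$f_lo - margin, res), alpha$f_hi + margin),
    band_definition(beta$name, max(beta$f_lo - margin, res), beta$f_hi + margin)
  )
  alpha_db <- beta_db <- numeric(ps$n_groups)
  for (g in seq_len(ps$n_groups)) {
    sp <- ps$group_mean_spectra[[g]]
    fit <- fit_aperiodic(sp, fit_range = fit_range, excluded = excl)
    alpha_db[g] <- corrected_power(sp, fit, alpha)
    beta_db[g] <- corrected_power(sp, fit, beta)
  }
  rho <- spearman_rho(alpha_db, beta_db)
  regime <- if (rho >= threshold) "positive"
            else if (rho <= -threshold) "anticorrelated"
            else "independent"
  structure(list(rho = rho, regime = regime, threshold = threshold,
                 alpha_db = alpha_db, beta_db = beta_db),
            class = "regime_call")
}

#' @export
print.regime_call <- function(x, ...) {
  cat(sprintf("<regime_call> rho = %.3f -> %s (|rho| threshold %.2f)\n",
              x$rho, x$regime, x$threshold))
  invisible(x)
}
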