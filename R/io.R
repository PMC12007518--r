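#' Write / read a time series as a TSV matrix with a JSON sidecar
#'
#' Plain-text round-tripping: samples go to a tab-separated matrix (one row
#' per channel, full double precision) and rate, channel labels, and
#' provenance metadata go to a `.json` sidecar next to it.
#'
#' @param ts A [time_series()].
#' @param path Output path for the matrix (the sidecar gets `.json`
#'   appended).
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "eeg_ts"))
  utils::write.table(format(ts$samples, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  sidecar <- list(rate = ts$rate, channel_labels = ts$channel_labels,
                  n_channels = n_channels(ts), n_samples = ncol(ts$samples),
                  meta = ts$meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(sidecar_path)) {
    stop("read_timeseries: missing matrix or sidecar for ", path)
  }
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  x <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(x) <- NULL
  meta <- if (is.null(sc$meta)) list() else as.list(sc$meta)
  time_series(x, sc$rate, sc$channel_labels, meta)
}

#' Export a spectrum as CSV
#'
#' Two columns, `freq` and `power`.
#'
#' @param spec A `"spectrum_est"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum_est"))
  utils::write.csv(data.frame(freq = spec$freqs, power = spec$power),
                   path, row.names = FALSE)
  invisible(path)
}

#' Export a percentile spectrum as long-format CSV
#'
#' Columns `group`, `freq`, `power`, one row per group and frequency bin.
#'
#' @param ps A [build_percentile_spectrum()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_percentile_csv <- function(ps, path) {
  stopifnot(inherits(ps, "percentile_spectrum"))
  df <- do.call(rbind, lapply(seq_len(ps$n_groups), function(g) {
    sp <- ps$group_mean_spectra[[g]]
    data.frame(group = g, freq = sp$freqs, power = sp$power)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a regime call as JSON
#'
#' @param rc An [alpha_beta_dependence()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_regime_json <- function(rc, path) {
  stopifnot(inherits(rc, "regime_call"))
  jsonlite::write_json(unclass(rc), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export harmonic verdicts as CSV
#'
#' One row per recording: `id`, `f_alpha`, `f_beta`, `ratio`,
#' `alpha_snr_db`, `verdict`.
#'
#' @param verdicts A list of `"harmonic_verdict"` objects.
#' @param path Output CSV path.
#' @param ids Optional recording identifiers (defaults to list names or
#'   indices).
#' @return `path`, invisibly.
#' @export
write_verdicts_csv <- function(verdicts, path, ids = NULL) {
  stopifnot(length(verdicts) > 0)
  if (is.null(ids)) {
    ids <- if (!is.null(names(verdicts))) names(verdicts)
           else as.character(seq_along(verdicts))
  }
  df <- do.call(rbind, Map(function(v, id) {
    data.frame(id = id, f_alpha = v$f_alpha, f_beta = v$f_beta,
               ratio = v$ratio, alpha_snr_db = v$alpha_snr,
               verdict = v$verdict)
  }, verdicts, ids))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a run record (config echo and stage counts) as JSON
#'
#' @param res A [run_recording()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_record <- function(res, path) {
  stopifnot(inherits(res, "run_result"))
  jsonlite::write_json(res$record, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
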