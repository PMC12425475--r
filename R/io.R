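# Plain-text interchange: TSV for tabular data (pRF tables, time series,
# fit results), JSON for schedules and ground truth, YAML for pipeline
# configuration.  Readers validate schemas strictly and name the offending
# column on failure.

PRF_COLUMNS <- c("voxel_id", "roi", "polar_angle", "eccentricity",
                 "prf_size", "prf_r2")

check_columns <- function(df, need, what) {
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "))
  }
}

#' Write / read a pRF voxel table (TSV)
#'
#' @param prfs a pRF table data frame.
#' @param path file path.
#' @export
write_prf_table <- function(prfs, path) {
  check_columns(prfs, PRF_COLUMNS, "pRF table")
  utils::write.table(prfs[, PRF_COLUMNS], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_prf_table
#' @param strict if `TRUE`, out-of-range polar angles are an error; if
#'   `FALSE` (default) they are wrapped to `[0, 360)` with a warning.
#' @return `read_prf_table`: a validated pRF data frame.
#' @export
read_prf_table <- function(path, strict = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, PRF_COLUMNS, "pRF table")
  bad_roi <- setdiff(unique(df$roi), c("V1", "V2", "V3"))
  if (length(bad_roi) > 0) {
    stop("pRF table column `roi` has unknown label(s): ",
         paste(bad_roi, collapse = ", "))
  }
  out_of_range <- df$polar_angle < 0 | df$polar_angle >= 360
  if (any(out_of_range)) {
    if (strict) {
      stop("pRF table column `polar_angle` has ", sum(out_of_range),
           " value(s) outside [0, 360); first offending row: ",
           which(out_of_range)[1])
    }
    warning("wrapped ", sum(out_of_range),
            " polar angle(s) into [0, 360)")
    df$polar_angle <- wrap_angle(df$polar_angle)
  }
  if (any(df$eccentricity < 0)) {
    stop("pRF table column `eccentricity` has negative value(s)")
  }
  if (any(df$prf_size <= 0)) {
    stop("pRF table column `prf_size` has nonpositive value(s)")
  }
  if (any(df$prf_r2 < 0 | df$prf_r2 > 1)) {
    stop("pRF table column `prf_r2` has value(s) outside [0, 1]")
  }
  df
}

#' Write / read a voxel time-series table (TSV)
#'
#' Wide TSV: one row per voxel, first column `voxel_id`, remaining columns
#' named `r<run>_t<tr>` so the run structure round-trips through the
#' header.  A `units` comment is not stored; pass `units` on read.
#'
#' @param ts a [timeseries_table()].
#' @param path file path.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "timeseries_table"))
  tr_within <- stats::ave(seq_along(ts$run), ts$run, FUN = seq_along)
  cn <- sprintf("r%d_t%03d", ts$run, tr_within)
  df <- data.frame(voxel_id = ts$voxel_id, ts$signal, check.names = FALSE)
  names(df) <- c("voxel_id", cn)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @param units units flag of the stored values (`"raw"` or `"psc"`).
#' @return `read_timeseries`: a [timeseries_table()].
#' @export
read_timeseries <- function(path, units = c("raw", "psc")) {
  units <- match.arg(units)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "voxel_id") {
    stop("time-series table must start with a `voxel_id` column")
  }
  cn <- names(df)[-1]
  m <- regmatches(cn, regexec("^r([0-9]+)_t([0-9]+)$", cn))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop("malformed TR column name(s): ", paste(cn[bad][1], collapse = ", "))
  }
  run <- as.integer(vapply(m, `[`, character(1), 2))
  timeseries_table(as.matrix(df[, -1, drop = FALSE]), run = run,
                   voxel_id = df$voxel_id, units = units)
}

#' Write / read a cue schedule (JSON)
#'
#' @param schedule a [build_cue_schedule()] data frame.
#' @param path file path.
#' @export
write_schedule <- function(schedule, path) {
  jsonlite::write_json(as.data.frame(schedule), path, digits = NA)
  invisible(path)
}

#' @rdname write_schedule
#' @return `read_schedule`: the schedule data frame.
#' @export
read_schedule <- function(path) {
  df <- jsonlite::fromJSON(path)
  check_columns(df, c("block_id", "run_id", "cue_center", "cue_width",
                      "tr_start", "tr_end"), "schedule")
  class(df) <- c("cue_schedule", "data.frame")
  df
}

#' Write / read ground truth (JSON)
#'
#' @param truth a [default_field_truth()]-style data frame.
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(as.data.frame(truth), path, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @return `read_truth`: the truth data frame.
#' @export
read_truth <- function(path) {
  df <- jsonlite::fromJSON(path)
  check_columns(df, c("block_id", "mu_true", "sigma_true", "beta_true",
                      "gain_true", "baseline_true"), "truth table")
  df
}

FIT_COLUMNS <- c("block_id", "roi", "n_trs", "cue_width", "mu", "sigma",
                 "beta", "gain", "baseline", "fwhm", "r2",
                 "angular_error", "abs_angular_error", "flags")

#' Write / read a fit-results table (TSV)
#'
#' @param fits a data frame of per-block fit results (see
#'   [fits_to_table()]).
#' @param path file path.
#' @export
write_fits <- function(fits, path) {
  check_columns(fits, FIT_COLUMNS, "fit table")
  utils::write.table(fits, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_fits
#' @return `read_fits`: the fit-results data frame.
#' @export
read_fits <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, FIT_COLUMNS, "fit table")
  df
}

#' Collect attfield fits into a tidy table
#'
#' @param fits a list of `attfield` objects.
#' @param roi,n_trs,cue_width metadata recycled across fits.
#' @return a data frame with one row per fit (columns of `FIT_COLUMNS`).
#' @export
fits_to_table <- function(fits, roi = NA_character_, n_trs = NA_integer_,
                          cue_width = NA_real_) {
  rows <- mapply(function(f, r, nt, w) {
    p <- f$params
    data.frame(
      block_id = f$profile$block_id, roi = r, n_trs = nt, cue_width = w,
      mu = p$mu, sigma = p$sigma, beta = p$beta, gain = p$gain,
      baseline = p$baseline, fwhm = f$fwhm, r2 = f$r2,
      angular_error = f$angular_error,
      abs_angular_error = f$abs_angular_error,
      flags = if (length(f$flags) > 0) paste(f$flags, collapse = ";") else ""
    )
  }, fits, rep_len(roi, length(fits)), rep_len(n_trs, length(fits)),
  rep_len(cue_width, length(fits)), SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror the arguments of
#'   [pipeline_config()] (top-level blocks `paradigm`, `simulation`,
#'   `analysis`, `stats`).
#' @return a `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, c(
    if (!is.null(y$paradigm)) list(paradigm = do.call(paradigm_config, y$paradigm)),
    y$simulation, y$analysis, y$stats
  ))
}
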