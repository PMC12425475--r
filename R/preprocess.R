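# Preprocessing of voxel time series: percent-signal-change conversion,
# DCT high-pass detrending, and collapsing TRs into per-block responses
# with a hemodynamic lag and optional TR subsampling.

#' Voxel-by-TR time-series table
#'
#' A light container for a voxels x TRs signal matrix with run structure
#' and a units flag.  Runs are concatenated along columns; the `run` vector
#' assigns every TR (column) to its run.  The units flag (`"raw"` or
#' `"psc"`) guards against double application of the percent-signal-change
#' conversion.
#'
#' @param signal numeric matrix, voxels x TRs.
#' @param run integer vector of run ids, one per column.
#' @param voxel_id character vector of voxel ids, one per row.
#' @param units `"raw"` or `"psc"`.
#' @return an object of class `timeseries_table`.
#' @export
timeseries_table <- function(signal, run, voxel_id = rownames(signal),
                             units = c("raw", "psc")) {
  units <- match.arg(units)
  signal <- as.matrix(signal)
  if (length(run) != ncol(signal)) {
    stop("`run` must have one entry per TR (column)")
  }
  if (is.null(voxel_id)) voxel_id <- paste0("v", seq_len(nrow(signal)))
  if (length(voxel_id) != nrow(signal)) {
    stop("`voxel_id` must have one entry per voxel (row)")
  }
  if (anyNA(signal)) stop("time series contains missing TRs")
  runs <- unique(run)
  lens <- table(run)
  structure(
    list(signal = unname(signal), run = as.integer(run),
         voxel_id = as.character(voxel_id), units = units),
    class = "timeseries_table"
  )
}

#' @export
print.timeseries_table <- function(x, ...) {
  cat("timeseries_table:", nrow(x$signal), "voxels x", ncol(x$signal),
      "TRs,", length(unique(x$run)), "run(s), units =", x$units, "\n")
  invisible(x)
}

#' Convert raw time series to percent signal change
#'
#' Per voxel and per run: `100 * (y - mean(y)) / mean(y)`.  The output has
#' zero mean per voxel per run and carries `units = "psc"`; applying the
#' conversion twice is refused.
#'
#' @param ts a [timeseries_table()] with `units = "raw"`.
#' @return a [timeseries_table()] with `units = "psc"`.
#' @export
percent_signal_change <- function(ts) {
  stopifnot(inherits(ts, "timeseries_table"))
  if (ts$units != "raw") {
    stop("time series already in percent-signal-change units")
  }
  out <- ts$signal
  for (r in unique(ts$run)) {
    cols <- which(ts$run == r)
    m <- rowMeans(ts$signal[, cols, drop = FALSE])
    bad <- which(m <= 0)
    if (length(bad) > 0) {
      stop("nonpositive mean signal in run ", r, " for voxel(s): ",
           paste(utils::head(ts$voxel_id[bad], 5), collapse = ", "))
    }
    out[, cols] <- 100 * (ts$signal[, cols, drop = FALSE] - m) / m
  }
  timeseries_table(out, ts$run, ts$voxel_id, units = "psc")
}

#' High-pass detrend via discrete-cosine basis projection
#'
#' Removes slow drift by regressing out, per voxel and per run, the
#' discrete-cosine basis functions with frequency below `cutoff_hz`
#' (the k-th DCT regressor over an N-sample run at sampling interval
#' `tr_seconds` has frequency `k / (2 N tr_seconds)`), together with the
#' run mean and a linear trend term.  This removes linear drift exactly
#' and has no filter edge ringing.
#'
#' When a `protect` design matrix is supplied (e.g. the lagged block
#' indicators from [block_design_matrix()]), the drift basis is first
#' orthogonalized against it, so only drift components orthogonal to the
#' task design are removed — the standard GLM treatment of nuisance
#' regressors, which prevents the filter from eating design-correlated
#' signal in a design whose spectrum extends below the cutoff.
#'
#' @param ts a [timeseries_table()] (any units).
#' @param cutoff_hz high-pass cutoff in Hz (default 0.005).
#' @param tr_seconds sampling interval in seconds.
#' @param protect optional TRs x q design matrix (rows spanning all runs)
#'   whose column space is protected from removal.
#' @return a detrended [timeseries_table()] with the same units flag.
#' @export
highpass_detrend <- function(ts, cutoff_hz = 0.005, tr_seconds = 1.55,
                             protect = NULL) {
  stopifnot(inherits(ts, "timeseries_table"))
  if (cutoff_hz <= 0) stop("cutoff_hz must be positive")
  if (!is.null(protect) && nrow(protect) != ncol(ts$signal)) {
    stop("`protect` must have one row per TR")
  }
  out <- ts$signal
  for (r in unique(ts$run)) {
    cols <- which(ts$run == r)
    n <- length(cols)
    k_max <- floor(2 * n * tr_seconds * cutoff_hz)
    t_idx <- seq_len(n) - 0.5
    basis <- cbind(rep(1, n), t_idx - mean(t_idx))
    if (k_max >= 1) {
      for (k in seq_len(k_max)) {
        basis <- cbind(basis, cos(pi * k * t_idx / n))
      }
    }
    if (!is.null(protect)) {
      d <- cbind(1, protect[cols, , drop = FALSE])
      d <- d[, qr(d)$pivot[seq_len(qr(d)$rank)], drop = FALSE]
      basis <- basis - d %*% qr.solve(d, basis)
      keep <- colSums(basis^2) > 1e-10
      basis <- cbind(rep(1, n), basis[, keep, drop = FALSE])
    }
    proj <- basis %*% solve(crossprod(basis), t(basis))
    seg <- ts$signal[, cols, drop = FALSE]
    out[, cols] <- seg - seg %*% t(proj)
  }
  timeseries_table(out, ts$run, ts$voxel_id, units = ts$units)
}

#' Reference percent-signal-change series to the run baseline
#'
#' Percent-signal-change conversion centers each voxel on its run mean,
#' which includes the task modulation itself; the unmodulated (baseline)
#' TRs of a run therefore sit below zero by the voxel's mean modulation, a
#' spatially structured offset that leaks into every block profile.
#' Subtracting, per voxel and per run, the mean over TRs outside every
#' lagged block window re-expresses responses relative to the task-free
#' baseline and cancels that background.
#'
#' @param ts a [timeseries_table()] with `units = "psc"`.
#' @param design a TRs x blocks indicator matrix from
#'   [block_design_matrix()]; TRs with an all-zero row count as baseline.
#' @return the baseline-referenced [timeseries_table()].
#' @export
reference_to_baseline <- function(ts, design) {
  stopifnot(inherits(ts, "timeseries_table"))
  if (ts$units != "psc") {
    stop("baseline referencing expects percent-signal-change input")
  }
  if (nrow(design) != ncol(ts$signal)) {
    stop("`design` must have one row per TR")
  }
  is_base <- rowSums(design) == 0
  out <- ts$signal
  for (r in unique(ts$run)) {
    cols <- which(ts$run == r)
    base_cols <- cols[is_base[cols]]
    if (length(base_cols) == 0) {
      stop("run ", r, " has no baseline TRs to reference against")
    }
    out[, cols] <- ts$signal[, cols, drop = FALSE] -
      rowMeans(ts$signal[, base_cols, drop = FALSE])
  }
  timeseries_table(out, ts$run, ts$voxel_id, units = "psc")
}

#' Lagged block-indicator design matrix
#'
#' One indicator column per scheduled block, marking its hemodynamically
#' lagged TR window (the window [block_average()] averages).  Used as the
#' `protect` argument of [highpass_detrend()] so drift removal leaves
#' block-locked signal untouched.
#'
#' @param blocks a [build_cue_schedule()] data frame.
#' @param ts a [timeseries_table()] (supplies total TRs and run lengths).
#' @param lag_trs hemodynamic lag in TRs (default 3).
#' @return a TRs x blocks 0/1 matrix.
#' @export
block_design_matrix <- function(blocks, ts, lag_trs = 3L) {
  n_tr <- ncol(ts$signal)
  run_start <- match(unique(ts$run), ts$run)
  names(run_start) <- unique(ts$run)
  run_len <- table(ts$run)
  d <- matrix(0, n_tr, nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    bl <- blocks[i, ]
    tpr <- run_len[[as.character(bl$run_id)]]
    window <- (bl$tr_start + lag_trs):(bl$tr_end + lag_trs - 1L)
    window <- window[window < tpr]
    d[run_start[[as.character(bl$run_id)]] + window, i] <- 1
  }
  d
}

#' Collapse TRs into per-block voxel responses
#'
#' For each block, averages the voxelwise percent-signal-change values over
#' the hemodynamically lagged window `[tr_start + lag, tr_start + lag +
#' 10)` (TR indices within the run).  With `n_trs < 10`, that window is
#' instead subsampled: `n_trs` TRs are drawn uniformly without replacement,
#' one draw per block, reproducible under `seed`.  Windows overrunning the
#' run end are truncated to the available TRs with a warning.
#'
#' @param ts a [timeseries_table()] with `units = "psc"`.
#' @param blocks a [build_cue_schedule()] data frame.
#' @param lag_trs hemodynamic lag in TRs (default 3).
#' @param n_trs TRs per block entering the average; one of 1, 2, 3, 5, 10.
#' @param seed integer seed for the TR subsample (ignored for `n_trs = 10`).
#' @return an object of class `block_response`: a list with `response`
#'   (voxels x blocks matrix), `block_id`, `voxel_id`, `n_trs`.
#' @export
block_average <- function(ts, blocks, lag_trs = 3L, n_trs = 10L,
                          seed = NULL) {
  stopifnot(inherits(ts, "timeseries_table"))
  if (ts$units != "psc") {
    stop("block_average expects percent-signal-change input; run ",
         "percent_signal_change() first")
  }
  if (!n_trs %in% c(1L, 2L, 3L, 5L, 10L)) {
    stop("n_trs must be one of 1, 2, 3, 5, 10")
  }
  run_len <- table(ts$run)
  resp <- matrix(NA_real_, nrow(ts$signal), nrow(blocks))
  n_used <- integer(nrow(blocks))
  truncated <- FALSE
  for (i in seq_len(nrow(blocks))) {
    bl <- blocks[i, ]
    tpr <- run_len[[as.character(bl$run_id)]]
    window <- (bl$tr_start + lag_trs):(bl$tr_start + lag_trs + 9L)
    window <- window[window < tpr]
    if (length(window) == 0) {
      stop("block ", bl$block_id, ": lagged window falls entirely outside ",
           "run ", bl$run_id)
    }
    if (length(window) < 10L) truncated <- TRUE
    take <- if (n_trs < 10L) {
      if (n_trs > length(window)) window else {
        with_seed(derive_seed(seed, bl$block_id),
                  sort(sample(window, n_trs)))
      }
    } else {
      window
    }
    cols <- which(ts$run == bl$run_id)[take + 1L]
    resp[, i] <- rowMeans(ts$signal[, cols, drop = FALSE])
    n_used[i] <- length(take)
  }
  if (truncated) {
    warning("some lagged block windows overran the run end and were ",
            "truncated to the available TRs")
  }
  structure(
    list(response = resp, block_id = blocks$block_id,
         voxel_id = ts$voxel_id, n_trs = as.integer(n_trs),
         n_trs_used = n_used),
    class = "block_response"
  )
}

#' @export
print.block_response <- function(x, ...) {
  cat("block_response:", nrow(x$response), "voxels x",
      ncol(x$response), "blocks (n_trs =", x$n_trs, ")\n")
  invisible(x)
}
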