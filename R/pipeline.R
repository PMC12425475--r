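# End-to-end pipeline driver: simulate -> preprocess -> profiles -> fit
# -> (optionally) group stats, with recovery diagnostics against the
# simulator's ground truth.

#' Pipeline configuration
#'
#' Bundles every tunable of the simulation-and-recovery pipeline.  All
#' randomness is controlled by the single `seed`; per-stage streams are
#' derived from it, so a config maps to exactly one report.
#'
#' @param paradigm a [paradigm_config()].
#' @param n_subjects simulated subjects (default 1; group statistics
#'   require >= 2).
#' @param n_runs runs per subject (default 2).
#' @param n_voxels_per_roi voxels per ROI (default 600).
#' @param noise_sd voxel-TR noise sd, percent signal change (default 3).
#' @param hemodynamic_lag true lag of the simulator, TRs (default 3).
#' @param s0 raw baseline signal level (default 1000).
#' @param ar1 AR(1) noise coefficient (default 0).
#' @param fwhm_range true field FWHM at the narrowest/widest cue
#'   (default `c(103, 179)` deg).
#' @param beta_true,gain_true,baseline_true true field shape, gain,
#'   baseline.
#' @param roi_gain_scale named multipliers of the true gain per ROI;
#'   the default (V1 0.8, V2 1.0, V3 1.2) makes modulation strengthen up
#'   the visual hierarchy.
#' @param lag_trs analysis lag in TRs (default 3).
#' @param cutoff_hz high-pass cutoff (default 0.005).
#' @param smooth logical: smooth profiles before fitting (default TRUE).
#' @param n_trs_levels TR counts per block average, subset of
#'   `c(1, 2, 3, 5, 10)` (default 10 only).
#' @param fwhm_mode `"closed"` or `"normalized"`.
#' @param exclude_prop pooled-R2 exclusion fraction (default 0.2).
#' @param alpha significance level for the slope tests.
#' @param predictors slope-test predictors (`"width"` or
#'   `c("width", "n_trs")`).
#' @param seed master integer seed.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(paradigm = paradigm_config(),
                            n_subjects = 1L,
                            n_runs = 2L,
                            n_voxels_per_roi = 600L,
                            noise_sd = 3,
                            hemodynamic_lag = 3L,
                            s0 = 1000,
                            ar1 = 0,
                            fwhm_range = c(103, 179),
                            beta_true = 4,
                            gain_true = 1,
                            baseline_true = 0,
                            roi_gain_scale = c(V1 = 0.8, V2 = 1, V3 = 1.2),
                            lag_trs = 3L,
                            cutoff_hz = 0.005,
                            smooth = TRUE,
                            n_trs_levels = 10L,
                            fwhm_mode = "closed",
                            exclude_prop = 0.2,
                            alpha = 0.05,
                            predictors = "width",
                            seed = 1L) {
  if (!all(n_trs_levels %in% c(1L, 2L, 3L, 5L, 10L))) {
    stop("n_trs_levels must be a subset of {1, 2, 3, 5, 10}")
  }
  stopifnot(inherits(paradigm, "paradigm_config"),
            all(c("V1", "V2", "V3") %in% names(roi_gain_scale)))
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:", x$n_subjects, "subject(s) x", x$n_runs,
      "run(s),", x$n_voxels_per_roi, "voxels/ROI, noise sd", x$noise_sd,
      "%sc, seed", x$seed, "\n")
  invisible(x)
}

# Run one subject through simulate -> preprocess -> profile -> fit.
# Returns the fit table (one row per block x ROI x n_trs level) plus the
# truth table used.
run_subject <- function(cfg, subject_id, seed) {
  pd <- cfg$paradigm
  schedule <- build_cue_schedule(pd, n_runs = cfg$n_runs,
                                 seed = derive_seed(seed, 1))
  truth <- default_field_truth(schedule, fwhm_range = cfg$fwhm_range,
                               beta_true = cfg$beta_true,
                               gain_true = cfg$gain_true,
                               baseline_true = cfg$baseline_true)
  prfs <- simulate_prf_table(cfg$n_voxels_per_roi, pd,
                             seed = derive_seed(seed, 2))
  fit_tabs <- list()
  for (roi in c("V1", "V2", "V3")) {
    roi_prfs <- prfs[prfs$roi == roi, , drop = FALSE]
    roi_truth <- truth
    roi_truth$gain_true <- truth$gain_true * cfg$roi_gain_scale[[roi]]
    ts <- simulate_timeseries(roi_prfs, schedule, roi_truth, pd,
                              noise_sd = cfg$noise_sd,
                              hemodynamic_lag = cfg$hemodynamic_lag,
                              s0 = cfg$s0, ar1 = cfg$ar1,
                              seed = derive_seed(seed, 10 + match(roi, c("V1", "V2", "V3"))))
    design <- block_design_matrix(schedule, ts, cfg$lag_trs)
    psc <- highpass_detrend(percent_signal_change(ts),
                            cutoff_hz = cfg$cutoff_hz,
                            tr_seconds = pd$tr_seconds,
                            protect = design)
    psc <- reference_to_baseline(psc, design)
    sel <- select_voxels(roi_prfs, pd)
    sel_idx <- match(sel$voxel_id, psc$voxel_id)
    for (nt in cfg$n_trs_levels) {
      br <- block_average(psc, schedule, lag_trs = cfg$lag_trs,
                          n_trs = nt, seed = derive_seed(seed, 100 + nt))
      fits <- lapply(seq_len(ncol(br$response)), function(i) {
        prof <- bin_profile_1d(br$response[sel_idx, i], sel,
                               block_id = schedule$block_id[i], roi = roi)
        prof <- recenter_profile(prof, schedule$cue_center[i])
        if (cfg$smooth) prof <- smooth_profile(prof)
        attfield_fit(prof, true_center = 0, fwhm_mode = cfg$fwhm_mode)
      })
      tab <- fits_to_table(fits, roi = roi, n_trs = nt,
                           cue_width = schedule$cue_width)
      fit_tabs[[length(fit_tabs) + 1L]] <- tab
    }
  }
  fits <- do.call(rbind, fit_tabs)
  fits$subject_id <- subject_id
  list(fits = fits, truth = truth, schedule = schedule)
}

#' Run the full simulation-and-recovery pipeline
#'
#' Simulates `n_subjects` subjects under the configured paradigm and known
#' ground-truth fields, preprocesses the raw series (percent signal
#' change, high-pass detrend), builds per-block 1D profiles (voxel
#' selection, 60-bin median, recenter, optional smoothing), fits the
#' generalized Gaussian to every block in every ROI at every configured TR
#' count, and derives recovery diagnostics against the truth.  With at
#' least two subjects, pooled-R2 exclusion and group slope tests of each
#' metric on cue width are added.
#'
#' @param config a [pipeline_config()].
#' @return an object of class `attfield_report`: list with `config`,
#'   `fits` (tidy table over subjects x blocks x ROIs x TR counts),
#'   `truth`, `recovery` (per-fit truth-vs-estimate comparison), `stats`
#'   (slope tests per metric x ROI, or `NULL`), and `summary` (named
#'   numeric headline values).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  subjects <- lapply(seq_len(config$n_subjects), function(s) {
    run_subject(config, s, derive_seed(config$seed, 1000 * s))
  })
  fits <- do.call(rbind, lapply(subjects, `[[`, "fits"))
  truth <- do.call(rbind, lapply(seq_along(subjects), function(s) {
    tr <- subjects[[s]]$truth
    tr$subject_id <- s
    tr
  }))
  fits <- exclude_low_r2(fits, prop = config$exclude_prop)
  key_f <- paste(fits$subject_id, fits$block_id)
  key_t <- paste(truth$subject_id, truth$block_id)
  idx <- match(key_f, key_t)
  recovery <- data.frame(
    subject_id = fits$subject_id, block_id = fits$block_id,
    roi = fits$roi, n_trs = fits$n_trs, cue_width = fits$cue_width,
    included = fits$included,
    mu_error = fits$angular_error,
    abs_mu_error = fits$abs_angular_error,
    fwhm_est = fits$fwhm, fwhm_true = truth$fwhm_true[idx],
    fwhm_error = fits$fwhm - truth$fwhm_true[idx],
    gain_est = fits$gain, r2 = fits$r2
  )
  stats_out <- NULL
  if (config$n_subjects >= 2) {
    metrics <- c("abs_angular_error", "fwhm", "gain", "baseline")
    stats_out <- list()
    for (roi in c("V1", "V2", "V3")) {
      for (m in metrics) {
        stats_out[[paste(m, roi, sep = ".")]] <-
          slope_test(fits, m, roi = roi, predictors = config$predictors)
      }
    }
  }
  incl <- recovery[recovery$included & recovery$n_trs == max(config$n_trs_levels), ]
  summary_vals <- c(
    n_fits = nrow(fits),
    median_abs_mu_error = stats::median(incl$abs_mu_error),
    median_abs_fwhm_error = stats::median(abs(incl$fwhm_error)),
    mean_r2 = mean(incl$r2)
  )
  structure(
    list(config = config, fits = fits, truth = truth, recovery = recovery,
         stats = stats_out, summary = summary_vals),
    class = "attfield_report"
  )
}

#' @export
print.attfield_report <- function(x, ...) {
  cat("attfield pipeline report:", nrow(x$fits), "fits (",
      x$config$n_subjects, "subject(s) x",
      length(unique(x$fits$block_id)), "blocks x 3 ROIs x",
      length(x$config$n_trs_levels), "TR level(s))\n")
  cat(sprintf("  median |angular error| %.2f deg; median |FWHM error| %.2f deg; mean R2 %.3f\n",
              x$summary[["median_abs_mu_error"]],
              x$summary[["median_abs_fwhm_error"]],
              x$summary[["mean_r2"]]))
  if (!is.null(x$stats)) {
    cat("  group slope tests (metric ~ cue width):\n")
    for (nm in names(x$stats)) {
      st <- x$stats[[nm]]
      cat(sprintf("    %-28s slope %8.4f  t(%d) = %6.2f  p = %.4g\n",
                  nm, st$mean_slope, st$df, st$t, st$p))
    }
  }
  invisible(x)
}
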