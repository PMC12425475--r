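# Synthetic data with known ground truth: voxel pRF tables tiling the
# visual field and raw BOLD time series whose blockwise polar-angle
# modulation is a scaled generalized Gaussian.  Every downstream stage of
# the pipeline can therefore be validated by parameter recovery without any
# external recording.

PROFILE_BIN_WIDTH <- 6
PROFILE_N_BINS <- 60L

#' Centers of the 60 polar-angle profile bins
#'
#' The 1D spatial profile uses 60 bins of 6 deg with half-open edges
#' `[6k, 6k + 6)`; their centers are 3, 9, ..., 357 deg.
#'
#' @return numeric vector of 60 bin centers in degrees.
#' @export
profile_bin_centers <- function() {
  PROFILE_BIN_WIDTH * (seq_len(PROFILE_N_BINS) - 1L) + PROFILE_BIN_WIDTH / 2
}

#' Simulate a voxelwise pRF table
#'
#' Draws `n_voxels_per_roi` voxels for each of V1, V2, and V3.  Polar
#' angles are uniform on the circle (re-drawn, at most 20 times, until all
#' sixty 6-deg bins are occupied so profile construction is well posed);
#' eccentricities concentrate near the stimulated annulus with a broader
#' uniform component covering 0.5-9.5 deg; pRF size grows with eccentricity
#' on average, with a steeper slope ascending the visual hierarchy; pRF
#' model fit R-squared is beta-distributed on `[0, 1]`.
#'
#' A `violation_fraction` of voxels per ROI is deliberately assigned values
#' violating each voxel-selection rule (eccentricity out of stimulus
#' bounds, near-zero pRF size, poor model fit) so the selection filters are
#' exercised; set it to 0 for a fully clean table.
#'
#' @param n_voxels_per_roi voxels per ROI (>= 60 recommended).
#' @param config a [paradigm_config()] (supplies the annulus bounds).
#' @param seed integer seed.
#' @param violation_fraction fraction in `[0, 0.5)` of voxels per rule given
#'   rule-violating values (default 0.05).
#' @return a data frame with columns `voxel_id`, `roi`, `polar_angle`,
#'   `eccentricity`, `prf_size`, `prf_r2`.
#' @export
simulate_prf_table <- function(n_voxels_per_roi = 600L,
                               config = paradigm_config(),
                               seed = NULL,
                               violation_fraction = 0.05) {
  stopifnot(n_voxels_per_roi >= 1, violation_fraction >= 0,
            violation_fraction < 0.5)
  mid <- (config$annulus_inner + config$annulus_outer) / 2
  rois <- c("V1", "V2", "V3")
  size_slope <- c(V1 = 0.15, V2 = 0.22, V3 = 0.30)
  with_seed(seed, {
    tabs <- lapply(rois, function(roi) {
      n <- n_voxels_per_roi
      ang <- stats::runif(n, 0, 360)
      # guarantee occupancy of all 60 profile bins when n allows it
      if (n >= PROFILE_N_BINS) {
        for (attempt in 1:20) {
          occ <- tabulate(floor(wrap_angle(ang) / PROFILE_BIN_WIDTH) + 1L,
                          PROFILE_N_BINS)
          if (all(occ > 0)) break
          ang <- stats::runif(n, 0, 360)
        }
      }
      near <- stats::runif(n) < 0.75
      ecc <- ifelse(near,
                    pmin(pmax(stats::rnorm(n, mid, 1.0), 0.8), 9.0),
                    stats::runif(n, 0.5, 9.5))
      sz <- pmax(0.05, 0.15 + size_slope[[roi]] * ecc +
                   stats::rnorm(n, 0, 0.15))
      r2 <- stats::rbeta(n, 5, 2)
      # inject rule violations in disjoint random subsets
      n_bad <- floor(violation_fraction * n)
      if (n_bad > 0) {
        idx <- sample.int(n, min(3L * n_bad, n))
        bad_ecc <- idx[seq_len(n_bad)]
        bad_sz <- idx[seq_len(n_bad) + n_bad]
        bad_r2 <- idx[seq_len(n_bad) + 2L * n_bad]
        lo <- stats::runif(length(bad_ecc)) < 0.5
        ecc[bad_ecc] <- ifelse(lo, stats::runif(length(bad_ecc), 0.05, 0.6),
                               stats::runif(length(bad_ecc), 9.2, 11))
        sz[bad_sz] <- 0.005
        r2[bad_r2] <- stats::runif(length(bad_r2), 0, 0.09)
      }
      data.frame(
        voxel_id = paste0(roi, "_", seq_len(n)),
        roi = roi,
        polar_angle = wrap_angle(ang),
        eccentricity = ecc,
        prf_size = sz,
        prf_r2 = pmin(pmax(r2, 0), 1)
      )
    })
    out <- do.call(rbind, tabs)
    rownames(out) <- NULL
    out
  })
}

#' Default ground-truth attentional field per block
#'
#' Maps each scheduled cue to the true field the simulator imposes: the
#' field is centered on the cue (`mu_true = cue_center`) and its full width
#' at half maximum interpolates linearly from `fwhm_range[1]` at the
#' narrowest cue (18 deg) to `fwhm_range[2]` at the widest (162 deg) —
#' substantially broader than the cue itself, as observed empirically for
#' covert attention.  The scale parameter is derived from the target FWHM
#' via the closed form `sigma = fwhm / (2 log(2)^(1/beta))`.
#'
#' @param schedule a [build_cue_schedule()] data frame.
#' @param fwhm_range true field FWHM (deg) at cue widths 18 and 162.
#' @param beta_true shape parameter of the true field.
#' @param gain_true peak-to-trough modulation depth, percent signal change.
#' @param baseline_true trough-level offset, percent signal change.
#' @return a data frame keyed by `block_id` with columns `mu_true`,
#'   `sigma_true`, `beta_true`, `gain_true`, `baseline_true`, `fwhm_true`.
#' @export
default_field_truth <- function(schedule, fwhm_range = c(103, 179),
                                beta_true = 4, gain_true = 1,
                                baseline_true = 0) {
  stopifnot(length(fwhm_range) == 2, fwhm_range[1] > 0,
            fwhm_range[2] >= fwhm_range[1])
  w <- schedule$cue_width
  fwhm <- fwhm_range[1] +
    (w - 18) / (162 - 18) * (fwhm_range[2] - fwhm_range[1])
  data.frame(
    block_id = schedule$block_id,
    cue_width = w,
    mu_true = schedule$cue_center,
    sigma_true = fwhm / (2 * log(2)^(1 / beta_true)),
    beta_true = beta_true,
    gain_true = gain_true,
    baseline_true = baseline_true,
    fwhm_true = fwhm
  )
}

#' Simulate raw voxel time series under a known attentional field
#'
#' For TRs inside a block's hemodynamically lagged window, each voxel's
#' expected raw signal is
#' `S0 * (1 + (baseline_true + gain_true * NormGG(polar_angle)) / 100)`,
#' where `NormGG` is the min-max normalized generalized Gaussian of the
#' block's true field (normalization constants taken over the standard
#' 60-bin profile grid, matching the fitting convention) evaluated at the
#' voxel's pRF polar angle.  Baseline TRs carry no modulation.  I.i.d.
#' Gaussian noise with standard deviation `noise_sd` (percent-signal-change
#' units) is added; an optional AR(1) coefficient induces temporal
#' autocorrelation at the same stationary sd.  The hemodynamic delay is a
#' pure `hemodynamic_lag`-TR shift (no HRF convolution), matching the
#' shift-and-average analysis convention.
#'
#' @param prfs a pRF table (see [simulate_prf_table()]); only `voxel_id`
#'   and `polar_angle` are used.
#' @param schedule a [build_cue_schedule()] data frame.
#' @param truth a [default_field_truth()]-style data frame with one row per
#'   scheduled block.
#' @param config a [paradigm_config()].
#' @param noise_sd noise sd per voxel-TR, percent-signal-change units
#'   (default 3, a typical single-voxel level at 3T).
#' @param hemodynamic_lag delay in TRs (default 3).
#' @param s0 raw baseline signal level, arbitrary units (default 1000).
#' @param ar1 AR(1) coefficient of the noise (default 0, i.i.d.).
#' @param seed integer seed.
#' @return a `timeseries_table` (see [timeseries_table()]) with
#'   `units = "raw"`, voxels in the row order of `prfs`.
#' @export
simulate_timeseries <- function(prfs, schedule, truth,
                                config = paradigm_config(),
                                noise_sd = 3, hemodynamic_lag = 3L,
                                s0 = 1000, ar1 = 0, seed = NULL) {
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (abs(ar1) >= 1) stop("ar1 must lie in (-1, 1)")
  miss <- setdiff(schedule$block_id, truth$block_id)
  if (length(miss) > 0) {
    stop("truth is missing block(s): ", paste(miss, collapse = ", "))
  }
  n_runs <- max(schedule$run_id)
  tpr <- config$trs_per_run
  n_tr <- n_runs * tpr
  n_vox <- nrow(prfs)
  grid <- profile_bin_centers()
  mod <- matrix(0, n_vox, n_tr)
  for (i in seq_len(nrow(schedule))) {
    bl <- schedule[i, ]
    tr <- truth[match(bl$block_id, truth$block_id), ]
    g <- gen_gaussian(grid, tr$mu_true, tr$sigma_true, tr$beta_true)
    rng <- range(g)
    gv <- gen_gaussian(prfs$polar_angle, tr$mu_true, tr$sigma_true,
                       tr$beta_true)
    ngg <- if (rng[2] - rng[1] <= .Machine$double.eps * 4) {
      rep(0, n_vox)
    } else {
      pmin(pmax((gv - rng[1]) / (rng[2] - rng[1]), 0), 1)
    }
    amp <- tr$baseline_true + tr$gain_true * ngg
    a <- bl$tr_start + hemodynamic_lag
    b <- min(bl$tr_end + hemodynamic_lag, tpr) - 1L
    if (b >= a) {
      cols <- (bl$run_id - 1L) * tpr + (a:b) + 1L
      mod[, cols] <- mod[, cols] + amp
    }
  }
  eps <- with_seed(seed, {
    if (noise_sd == 0) {
      matrix(0, n_vox, n_tr)
    } else if (ar1 == 0) {
      matrix(stats::rnorm(n_vox * n_tr, 0, noise_sd), n_vox, n_tr)
    } else {
      innov_sd <- noise_sd * sqrt(1 - ar1^2)
      e <- matrix(stats::rnorm(n_vox * n_tr, 0, innov_sd), n_vox, n_tr)
      # recursive AR(1) within each run, stationary start
      for (r in seq_len(n_runs)) {
        cols <- (r - 1L) * tpr + seq_len(tpr)
        e[, cols[1]] <- e[, cols[1]] / sqrt(1 - ar1^2)
        for (j in cols[-1]) e[, j] <- ar1 * e[, j - 1L] + e[, j]
      }
      e
    }
  })
  signal <- s0 * (1 + (mod + eps) / 100)
  timeseries_table(signal, run = rep(seq_len(n_runs), each = tpr),
                   voxel_id = prfs$voxel_id, units = "raw")
}
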