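# Construction of spatial profiles of BOLD modulation: voxel selection
# against the stimulated annulus, 60-bin circular 1D profiles over
# preferred polar angle, recentering on the cue, moving-average smoothing,
# and 2D visual-field reconstruction for quality control.

#' Select annulus-overlapping voxels
#'
#' Retains voxels passing all of: preferred eccentricity within the pRF
#' stimulus bounds (0.7-9.1 deg), pRF size at least 0.01 deg, pRF model fit
#' R-squared at least 0.10, and pRF overlap with the noise annulus (either
#' the preferred eccentricity lies within the annulus bounds, or the pRF
#' extends into it: `ecc + size >= inner` and `ecc - size <= outer`).
#'
#' @param prfs a pRF table (data frame with `polar_angle`, `eccentricity`,
#'   `prf_size`, `prf_r2`).
#' @param config a [paradigm_config()] carrying the annulus bounds.
#' @param ecc_bounds pRF stimulus eccentricity bounds, deg (default
#'   `c(0.7, 9.1)`).
#' @param min_size,min_r2 minimum pRF size (deg) and model fit.
#' @return the retained rows of `prfs`.
#' @export
select_voxels <- function(prfs, config = paradigm_config(),
                          ecc_bounds = c(0.7, 9.1), min_size = 0.01,
                          min_r2 = 0.10) {
  need <- c("polar_angle", "eccentricity", "prf_size", "prf_r2")
  miss <- setdiff(need, names(prfs))
  if (length(miss) > 0) {
    stop("pRF table lacks column(s): ", paste(miss, collapse = ", "))
  }
  ok_ecc <- prfs$eccentricity >= ecc_bounds[1] &
    prfs$eccentricity <= ecc_bounds[2]
  ok_size <- prfs$prf_size >= min_size
  ok_r2 <- prfs$prf_r2 >= min_r2
  inside <- prfs$eccentricity >= config$annulus_inner &
    prfs$eccentricity <= config$annulus_outer
  overlap <- inside |
    (prfs$eccentricity + prfs$prf_size >= config$annulus_inner &
       prfs$eccentricity - prfs$prf_size <= config$annulus_outer)
  keep <- ok_ecc & ok_size & ok_r2 & overlap
  if (!any(keep)) {
    removed <- c(eccentricity_bounds = sum(!ok_ecc),
                 prf_size = sum(!ok_size),
                 prf_r2 = sum(!ok_r2),
                 annulus_overlap = sum(!overlap))
    worst <- names(removed)[which.max(removed)]
    stop("no voxels survive selection; the most exclusions (",
         max(removed), "/", nrow(prfs), ") came from the ", worst,
         " filter")
  }
  prfs[keep, , drop = FALSE]
}

#' Construct a spatial-profile object
#'
#' @param values 60 percent-signal-change values, one per 6-deg bin.
#' @param block_id,roi identifiers carried along for bookkeeping.
#' @param recentered,smoothed processing flags.
#' @param interpolated logical vector marking bins filled by interpolation.
#' @return an object of class `spatial_profile`.
#' @export
spatial_profile <- function(values, block_id = NA, roi = NA_character_,
                            recentered = FALSE, smoothed = FALSE,
                            interpolated = rep(FALSE, length(values))) {
  if (length(values) != PROFILE_N_BINS) {
    stop("a spatial profile has exactly ", PROFILE_N_BINS, " bins")
  }
  structure(
    list(bin_centers = profile_bin_centers(), values = as.numeric(values),
         block_id = block_id, roi = roi, recentered = isTRUE(recentered),
         smoothed = isTRUE(smoothed), interpolated = interpolated,
         cue_center = NA_real_),
    class = "spatial_profile"
  )
}

#' @export
print.spatial_profile <- function(x, ...) {
  cat("spatial_profile: 60 bins x 6 deg",
      if (!is.na(x$block_id)) paste0(", block ", x$block_id),
      if (!is.na(x$roi)) paste0(", ", x$roi),
      if (x$recentered) ", recentered",
      if (x$smoothed) ", smoothed", "\n", sep = "")
  cat("  range [", round(min(x$values), 4), ", ",
      round(max(x$values), 4), "] %sc\n", sep = "")
  invisible(x)
}

#' Bin voxel responses into a 1D polar-angle profile
#'
#' Groups voxels into 60 polar-angle bins with half-open edges
#' `[6k, 6k + 6)` and takes the median response within each bin.  Bins with
#' no voxel are filled by circular linear interpolation between the nearest
#' occupied neighbors and flagged; more than 20% empty bins is an error
#' (the pRF table undersamples the circle).
#'
#' @param values per-voxel responses (percent signal change), aligned with
#'   the rows of `prfs`.
#' @param prfs the selected pRF table (see [select_voxels()]).
#' @param block_id,roi identifiers stored on the profile.
#' @return a [spatial_profile()].
#' @export
bin_profile_1d <- function(values, prfs, block_id = NA,
                           roi = NA_character_) {
  stopifnot(length(values) == nrow(prfs))
  if (length(values) == 0) stop("no selected voxels to bin")
  bin <- floor(wrap_angle(prfs$polar_angle) / PROFILE_BIN_WIDTH) + 1L
  med <- rep(NA_real_, PROFILE_N_BINS)
  agg <- tapply(values, bin, stats::median)
  med[as.integer(names(agg))] <- agg
  empty <- is.na(med)
  if (mean(empty) > 0.2) {
    stop(sum(empty), "/60 profile bins are empty; the pRF table ",
         "undersamples polar angle")
  }
  if (any(empty)) {
    med <- fill_circular(med)
  }
  spatial_profile(med, block_id = block_id, roi = roi,
                  interpolated = empty)
}

# Fill NA entries of a circular vector by linear interpolation between the
# nearest non-NA neighbors (distance measured in bins around the circle).
fill_circular <- function(v) {
  n <- length(v)
  occ <- which(!is.na(v))
  for (i in which(is.na(v))) {
    d_prev <- (i - occ) %% n
    d_next <- (occ - i) %% n
    p <- occ[which.min(replace(d_prev, d_prev == 0, n))]
    q <- occ[which.min(replace(d_next, d_next == 0, n))]
    dp <- (i - p) %% n
    dq <- (q - i) %% n
    v[i] <- (v[p] * dq + v[q] * dp) / (dp + dq)
  }
  v
}

#' Recenter a profile on the cue
#'
#' Circularly rotates the bin values so the cue center maps to 0 deg:
#' after recentering, bin k holds the response of voxels preferring
#' `cue_center + 6k + 3` degrees.  The cue center must be an integer
#' number of 6-deg bins (all 18-deg cue positions are).  A pure
#' permutation: the multiset of values is unchanged.
#'
#' @param p a [spatial_profile()].
#' @param cue_center cue center in degrees (multiple of 6).
#' @return the recentered [spatial_profile()].
#' @export
recenter_profile <- function(p, cue_center) {
  stopifnot(inherits(p, "spatial_profile"))
  shift <- cue_center / PROFILE_BIN_WIDTH
  if (abs(shift - round(shift)) > 1e-9) {
    stop("cue center ", cue_center, " deg is not an integer number of ",
         PROFILE_BIN_WIDTH, "-deg bins")
  }
  shift <- as.integer(round(shift)) %% PROFILE_N_BINS
  idx <- ((seq_len(PROFILE_N_BINS) - 1L + shift) %% PROFILE_N_BINS) + 1L
  p$values <- p$values[idx]
  p$interpolated <- p$interpolated[idx]
  p$recentered <- TRUE
  p$cue_center <- wrap_angle(cue_center)
  p
}

#' Smooth a profile with a circular moving average
#'
#' Uniform moving average of width `width_deg` (a multiple of the 6-deg bin
#' width yielding an odd number of bins; the default 18 deg averages each
#' bin with its two neighbors), with wrap-around at 0/360.  The profile
#' mean is conserved exactly.
#'
#' @param p a [spatial_profile()].
#' @param width_deg filter width in degrees (default 18).
#' @return the smoothed [spatial_profile()].
#' @export
smooth_profile <- function(p, width_deg = 18) {
  stopifnot(inherits(p, "spatial_profile"))
  w <- width_deg / PROFILE_BIN_WIDTH
  if (abs(w - round(w)) > 1e-9) {
    stop("smoothing width must be a multiple of the ", PROFILE_BIN_WIDTH,
         "-deg bin width")
  }
  w <- as.integer(round(w))
  if (w %% 2 == 0) {
    stop("smoothing window spans an even number of bins (", w,
         "); an odd count is required for symmetric centering")
  }
  h <- (w - 1L) %/% 2L
  n <- PROFILE_N_BINS
  out <- numeric(n)
  for (k in -h:h) {
    out <- out + p$values[((seq_len(n) - 1L + k) %% n) + 1L]
  }
  p$values <- out / w
  p$smoothed <- TRUE
  p
}

#' Reconstruct a 2D visual-field map of block modulation
#'
#' Projects each voxel's response to its pRF position in the visual field
#' (`x = ecc * cos(angle)`, `y = ecc * sin(angle)`), rotates positions so
#' the cue center lies at 0 deg polar angle (right horizontal meridian),
#' interpolates the scattered responses onto a square grid covering +/-
#' `extent` deg by Gaussian-kernel local averaging over nearby pRFs,
#' masks cells far from any voxel, and z-scores the defined cells.  These
#' maps are for visualization and quality control; model fitting consumes
#' the 1D profiles.
#'
#' @param values per-voxel responses aligned with `prfs`.
#' @param prfs the selected pRF table.
#' @param cue_center cue center in degrees (rotation target).
#' @param grid_step grid resolution, deg visual angle (default 0.1).
#' @param extent half-width of the grid, deg (default 9).
#' @return an object of class `field_map`: list with `x`, `y` (grid axes),
#'   `z` (matrix of z-scored values, `NA` outside the data hull),
#'   `rotation` (deg applied).
#' @export
reconstruct_field_2d <- function(values, prfs, cue_center = 0,
                                 grid_step = 0.1, extent = 9) {
  stopifnot(length(values) == nrow(prfs))
  if (nrow(prfs) < 3) stop("need at least 3 pRF positions")
  ang <- (prfs$polar_angle - cue_center) * pi / 180
  px <- prfs$eccentricity * cos(ang)
  py <- prfs$eccentricity * sin(ang)
  # collinearity guard: effective rank of centered coordinates
  cc <- cbind(px - mean(px), py - mean(py))
  sv <- svd(cc, nu = 0, nv = 0)$d
  if (sv[2] <= sv[1] * 1e-8) {
    stop("degenerate pRF geometry: positions are collinear")
  }
  gx <- seq(-extent, extent, by = grid_step)
  gy <- gx
  # bandwidth from the typical nearest-neighbor spacing
  n <- length(px)
  area <- (max(px) - min(px)) * (max(py) - min(py))
  bw <- max(0.3, 1.5 * sqrt(area / n))
  z <- matrix(NA_real_, length(gx), length(gy))
  dx2 <- outer(gx, px, function(a, b) (a - b)^2)
  for (j in seq_along(gy)) {
    dy2 <- (gy[j] - py)^2
    d2 <- sweep(dx2, 2, dy2, "+")
    wmat <- exp(-d2 / (2 * bw^2))
    wmat[d2 > (3 * bw)^2] <- 0
    wsum <- rowSums(wmat)
    ok <- wsum > 0
    z[ok, j] <- (wmat[ok, , drop = FALSE] %*% values) / wsum[ok]
  }
  defined <- !is.na(z)
  if (sum(defined) > 1) {
    s <- stats::sd(z[defined])
    m <- mean(z[defined])
    z[defined] <- if (s > .Machine$double.eps * 4) (z[defined] - m) / s else 0
  }
  structure(list(x = gx, y = gy, z = z, rotation = wrap_angle(cue_center)),
            class = "field_map")
}

#' @export
print.field_map <- function(x, ...) {
  cat("field_map:", length(x$x), "x", length(x$y), "grid,",
      sum(!is.na(x$z)), "defined cells, rotation", x$rotation, "deg\n")
  invisible(x)
}

#' @export
plot.field_map <- function(x, ...) {
  graphics::image(x$x, x$y, x$z, asp = 1, xlab = "x (deg)",
                  ylab = "y (deg)", useRaster = TRUE, ...)
  invisible(x)
}
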