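# The generalized Gaussian (exponential power) curve on the circle, and the
# summary metrics derived from a fitted curve.  This family spans
# Laplace-like (beta < 2), Gaussian (beta = 2), and near-uniform
# (beta -> Inf) shapes, which is what makes it a convenient single model for
# attentional fields that range from a narrow spotlight to a broad swath.

#' Evaluate the generalized Gaussian on the circle
#'
#' Computes `exp(-(d / sigma)^beta)` where `d` is the wrapped angular
#' distance between `x` and `mu` (so the curve is periodic with period 360
#' degrees and attains its maximum of 1 at `x = mu`).
#'
#' @param x numeric vector of polar angles (degrees).
#' @param mu location parameter (degrees, any real; used circularly).
#' @param sigma scale parameter (degrees, > 0).
#' @param beta shape parameter (dimensionless, > 0); `beta = 2` is Gaussian,
#'   smaller values have heavier tails, larger values approach a boxcar.
#' @return values in `(0, 1]`.
#' @export
#' @examples
#' gen_gaussian(0, mu = 0, sigma = 30, beta = 2)   # 1
#' gen_gaussian(30, mu = 0, sigma = 30, beta = 4)  # exp(-1)
gen_gaussian <- function(x, mu, sigma, beta) {
  stopifnot(sigma > 0, beta > 0)
  d <- angular_distance(x, mu)
  exp(-(d / sigma)^beta)
}

#' Min-max normalized generalized Gaussian over a grid
#'
#' The raw curve is rescaled to span exactly `[0, 1]` over the evaluation
#' grid: `(G - min G) / (max G - min G)`, with min/max taken over
#' `bin_centers`.  Under this convention the gain parameter of
#' [predict_profile()] is the peak-to-trough modulation depth and the
#' baseline is the trough level.  A degenerate curve (constant over the
#' grid) normalizes to all zeros.
#'
#' @param bin_centers angles (degrees) at which the profile is evaluated.
#' @inheritParams gen_gaussian
#' @return numeric vector of the same length as `bin_centers`, in `[0, 1]`.
#' @export
norm_gen_gaussian <- function(bin_centers, mu, sigma, beta) {
  g <- gen_gaussian(bin_centers, mu, sigma, beta)
  rng <- range(g)
  if (rng[2] - rng[1] <= .Machine$double.eps * 4) {
    return(rep(0, length(g)))
  }
  (g - rng[1]) / (rng[2] - rng[1])
}

#' Predicted spatial profile from field parameters
#'
#' `yhat = gain * NormGG + baseline`, where `NormGG` is the min-max
#' normalized generalized Gaussian over `bin_centers`
#' (see [norm_gen_gaussian()]).
#'
#' @param params named list or vector with elements `mu`, `sigma`, `beta`,
#'   `gain`, `baseline`.
#' @param bin_centers angles (degrees) of the profile grid.
#' @return predicted percent-signal-change values, one per bin center.
#' @export
predict_profile <- function(params, bin_centers) {
  p <- as.list(params)
  p$gain * norm_gen_gaussian(bin_centers, p$mu, p$sigma, p$beta) + p$baseline
}

#' Full width at half maximum of the generalized Gaussian
#'
#' Closed form on the unnormalized curve: the half-maximum is reached at
#' angular distance `sigma * log(2)^(1/beta)` from the peak, so
#' `FWHM = 2 * sigma * log(2)^(1/beta)`, capped at 360 degrees (the full
#' circle).  With `mode = "normalized"` the width is instead measured on the
#' min-max normalized curve over a 60-bin grid: the width of the region
#' where the normalized curve exceeds 0.5, found by root bracketing.  The
#' two agree when the curve's minimum over the grid is near zero and differ
#' for very broad fields.
#'
#' @param sigma scale parameter (degrees).
#' @param beta shape parameter.
#' @param mode `"closed"` (default) or `"normalized"`.
#' @return width in degrees, `<= 360`.
#' @export
#' @examples
#' compute_fwhm(50, 2)  # 2 * 50 * sqrt(log(2)) ~ 83.26
compute_fwhm <- function(sigma, beta, mode = c("closed", "normalized")) {
  mode <- match.arg(mode)
  stopifnot(sigma > 0, beta > 0)
  if (mode == "closed") {
    return(pmin(2 * sigma * log(2)^(1 / beta), 360))
  }
  # Half height between the curve's min and max over the standard 60-bin
  # grid; the half-crossing distance solves G(d) = (1 + Gmin) / 2.
  grid <- seq(0, 354, by = 6)
  g <- gen_gaussian(grid, 0, sigma, beta)
  gmin <- min(g)
  half <- (1 + gmin) / 2
  f <- function(d) exp(-(d / sigma)^beta) - half
  if (f(180) > 0) return(360)  # never drops below half height
  d_half <- stats::uniroot(f, c(0, 180), tol = 1e-10)$root
  min(2 * d_half, 360)
}

#' Signed angular error of an estimated field center
#'
#' Wrapped signed difference (estimated minus true) mapped to
#' `(-180, 180]`; positive values are counterclockwise of the cue.
#'
#' @param estimated_mu estimated location (degrees).
#' @param true_center true cue center (degrees).
#' @return signed error in degrees.
#' @export
angular_error <- function(estimated_mu, true_center) {
  angular_difference(estimated_mu, true_center)
}

#' Coefficient of determination for a spatial profile fit
#'
#' `R^2 = 1 - SS_res / SS_tot` on the profile values; may be negative for a
#' fit worse than the mean.  A zero-variance observed profile has no defined
#' R-squared and returns `NA` with a warning.
#'
#' @param y observed values.
#' @param yhat fitted values.
#' @return fraction of explained variance (can be negative), or `NA`.
#' @export
r_squared <- function(y, yhat) {
  stopifnot(length(y) == length(yhat))
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot <= .Machine$double.eps * 4) {
    warning("observed profile has zero variance; R-squared undefined")
    return(NA_real_)
  }
  1 - sum((y - yhat)^2) / ss_tot
}
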