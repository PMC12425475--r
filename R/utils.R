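# Circular helpers shared across the package.  All angles are degrees of
# polar angle; 0 deg is the right horizontal meridian, increasing
# counterclockwise.

#' Wrap angles to [0, 360)
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped to `[0, 360)`.
#' @export
wrap_angle <- function(x) {
  out <- x %% 360
  # `%%` can return 360 for tiny negative inputs due to rounding
  out[out >= 360] <- 0
  out
}

#' Signed wrapped angular difference
#'
#' Signed circular difference `a - b` mapped to `(-180, 180]`. The exact
#' antipodal case maps to +180 by convention.
#'
#' @param a,b numeric vectors of angles in degrees (recycled).
#' @return signed differences in `(-180, 180]`.
#' @export
angular_difference <- function(a, b) {
  d <- (a - b) %% 360
  d[d > 180] <- d[d > 180] - 360
  d[d == -180] <- 180
  d
}

#' Absolute wrapped angular distance
#'
#' @param a,b numeric vectors of angles in degrees (recycled).
#' @return distances in `[0, 180]`.
#' @export
angular_distance <- function(a, b) {
  abs(angular_difference(a, b))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so seeded helpers stay composable.  A NULL
# seed uses (and advances) the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a distinct but reproducible child seed from a base seed; keeps all
# derived seeds within the 32-bit integer range.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1103L + as.numeric(offset) * 12345) %% 2147483647)
}
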