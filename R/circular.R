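## Circular statistics on angles in degrees.
##
## Convention used throughout the package: head direction is 0 deg when the
## fly faces the visual cue, positive angles are clockwise, and all wrapped
## angles live in the half-open interval (-180, 180].

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

## rho below this is treated as a vanishing resultant: the circular mean is
## then numerically arbitrary and is flagged undefined.
RHO_UNDEFINED_TOL <- 1e-9

#' Wrap angles into (-180, 180] degrees
#'
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector congruent to \code{x} modulo 360, in
#'   \code{(-180, 180]}. \code{NA} values propagate.
#' @examples
#' wrapDeg(c(190, -180, 725))  # -170, 180, 5
#' @export
wrapDeg <- function(x) {
  if (!is.numeric(x)) {
    stop("angles must be numeric")
  }
  if (any(is.infinite(x))) {
    stop("angles must be finite")
  }
  w <- x - 360 * floor(x / 360)   # [0, 360)
  ifelse(w > 180, w - 360, w)
}

#' Signed shortest-arc difference between two angles
#'
#' Computes \code{wrapDeg(a - b)}; the absolute value is the angular
#' distance along the shorter arc.
#'
#' @param a,b Angles in degrees (recycled to a common length).
#' @return Signed difference in degrees, in \code{(-180, 180]}.
#' @export
circDistDeg <- function(a, b) {
  wrapDeg(a - b)
}

#' Circular mean direction
#'
#' Treats each angle as a unit vector, sums the vectors and returns the
#' direction of the resultant via the two-argument arctangent.
#'
#' @param theta Angles in degrees; must be non-empty after removing
#'   \code{NA} when \code{na.rm = TRUE}.
#' @param na.rm Drop \code{NA} values first.
#' @return Mean direction in degrees in \code{(-180, 180]}, or \code{NA}
#'   with a warning when the resultant length is numerically zero (the mean
#'   of e.g. two antipodal angles is undefined).
#' @seealso [circRho()], [circSummary()]
#' @export
circMeanDeg <- function(theta, na.rm = FALSE) {
  s <- circSummary(theta, na.rm = na.rm)
  if (s$undefined) {
    warning("resultant length ~ 0: circular mean is undefined")
    return(NA_real_)
  }
  s$meanDirection
}

#' Consistency of heading (mean resultant length)
#'
#' The mean resultant length rho of a set of unit vectors: 1 when all
#' angles are identical, 0 when they uniformly sample the circle.
#'
#' @inheritParams circMeanDeg
#' @return rho in \code{[0, 1]}.
#' @export
circRho <- function(theta, na.rm = FALSE) {
  circSummary(theta, na.rm = na.rm)$rho
}

#' Circular summary: mean direction, consistency and sample count
#'
#' @inheritParams circMeanDeg
#' @return A list with components \code{meanDirection} (degrees,
#'   \code{NA} when undefined), \code{rho}, \code{n} and \code{undefined}
#'   (TRUE when the resultant length is below tolerance, in which case the
#'   mean direction is not meaningful).
#' @export
circSummary <- function(theta, na.rm = FALSE) {
  if (!is.numeric(theta)) {
    stop("angles must be numeric")
  }
  if (na.rm) {
    theta <- theta[!is.na(theta)]
  }
  if (length(theta) == 0L) {
    stop("empty angle vector")
  }
  if (anyNA(theta) || any(is.infinite(theta))) {
    stop("angles must be finite (use na.rm = TRUE to drop NA)")
  }
  rad <- theta * DEG2RAD
  cbar <- mean(cos(rad))
  sbar <- mean(sin(rad))
  rho <- sqrt(cbar^2 + sbar^2)
  undefined <- rho < RHO_UNDEFINED_TOL
  list(
    meanDirection = if (undefined) NA_real_ else wrapDeg(atan2(sbar, cbar) * RAD2DEG),
    rho = rho,
    n = length(theta),
    undefined = undefined
  )
}

#' Deterministic argmax with ties broken toward the smallest index
#'
#' Internal helper shared by tuning-curve and goal-inference code: ties in
#' a binned maximum are resolved toward the smallest bin index so results
#' are reproducible.
#' @param x Numeric vector (NA allowed, never selected unless all-NA).
#' @return Integer index of the first maximum, or NA if all values are NA.
#' @keywords internal
argmaxFirst <- function(x) {
  if (all(is.na(x))) {
    return(NA_integer_)
  }
  which.max(x)  # which.max already returns the first maximum
}
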