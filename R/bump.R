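## Sinusoidal bump fitting across columnar brain space.
##
## Columnar structures (protocerebral bridge, fan-shaped body) carry a
## roughly sinusoidal spatial profile of population activity ("the bump").
## Each time point's ROI profile is fit with
##     activity = a * sin(x - u) + c
## over one full cycle of brain space x. The bump phase is the brain-space
## position of the sinusoid's peak: +180 deg = rightmost ROI, -180 deg =
## leftmost. The fit is solved by linear least squares on a sin/cos basis
## (closed form, deterministic); a negative fitted amplitude cannot occur
## in this parameterization because a = sqrt(b1^2 + b2^2) >= 0.

#' ROI angular coordinates across brain space
#'
#' ROI centres are placed uniformly over one cycle of brain space,
#' \code{(-180, 180]} degrees, with the last ROI at +180 (rightmost),
#' whatever the ROI count (10 protocerebral-bridge glomeruli, 9
#' fan-shaped-body columns, or model units).
#'
#' @param n Number of ROIs (>= 1).
#' @return Numeric vector of n angles in degrees.
#' @export
roiAngleGrid <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("n must be a positive count")
  }
  seq_len(n) * (360 / n) - 180
}

#' Fit a sinusoid to a single brain-space activity profile
#'
#' Least-squares fit of \code{a * sin(x - u) + c} to one time point's
#' profile of (typically z-scored dF/F) values across ROIs.
#'
#' @param profile Numeric vector of activity values, one per ROI.
#' @param roiAngles ROI centre angles in degrees (default: uniform grid
#'   over one cycle).
#' @param r2Threshold Adjusted r^2 below which the fit is flagged invalid
#'   (default 0.1).
#' @return A list with \code{amplitude} (>= 0), \code{phase} (brain-space
#'   peak position, degrees, \code{NA} when the profile is flat),
#'   \code{offset}, \code{adjR2} and \code{valid}.
#' @examples
#' x <- roiAngleGrid(10)
#' f <- fitBump(2 * sin((x - 40) * pi / 180) + 1, x)
#' f$amplitude  # 2
#' @export
fitBump <- function(profile, roiAngles = roiAngleGrid(length(profile)),
                    r2Threshold = 0.1) {
  out <- fitBumpSeries(matrix(profile, ncol = 1L), roiAngles, r2Threshold)
  list(amplitude = out$amplitude, phase = out$phase, offset = out$offset,
       adjR2 = out$adjR2, valid = out$valid)
}

#' Fit the bump sinusoid independently at every time point
#'
#' Vectorized companion to [fitBump()]: one least-squares solve serves all
#' time points because the design matrix over ROI angles is shared.
#'
#' @param values ROI x time matrix of activity values.
#' @param roiAngles ROI centre angles in degrees.
#' @param r2Threshold Adjusted r^2 validity threshold.
#' @return A data.frame with one row per time point: \code{amplitude},
#'   \code{phase}, \code{offset}, \code{adjR2}, \code{valid}.
#' @export
fitBumpSeries <- function(values, roiAngles = roiAngleGrid(nrow(values)),
                          r2Threshold = 0.1) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (n < 4L) {
    stop("need at least 4 ROIs to fit the 3-parameter sinusoid")
  }
  if (length(roiAngles) != n) {
    stop("roiAngles length must match the ROI count")
  }
  x <- roiAngles * DEG2RAD
  X <- cbind(1, sin(x), cos(x))
  ## closed-form LS: coef = (X'X)^-1 X' y, shared across columns of values
  proj <- solve(crossprod(X), t(X))
  beta <- proj %*% values                      # 3 x T
  fitted <- X %*% beta
  resid <- values - fitted
  rss <- colSums(resid^2)
  tss <- colSums(sweep(values, 2, colMeans(values), "-")^2)
  r2 <- ifelse(tss > 0, 1 - rss / tss, 0)
  adjR2 <- 1 - (1 - r2) * (n - 1) / (n - 3)
  a <- sqrt(beta[2L, ]^2 + beta[3L, ]^2)
  ## y = c + b1 sin(x) + b2 cos(x) = c + a sin(x - u) with
  ## b1 = a cos(u), b2 = -a sin(u); peak at x = u + 90 deg
  u <- atan2(-beta[3L, ], beta[2L, ]) * RAD2DEG
  phase <- ifelse(a < 1e-12, NA_real_, wrapDeg(u + 90))
  data.frame(
    amplitude = a,
    phase = phase,
    offset = beta[1L, ],
    adjR2 = adjR2,
    valid = adjR2 >= r2Threshold,
    row.names = NULL
  )
}
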