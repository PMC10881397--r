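## Static (open-loop) network operations: sinusoidal inputs, population
## rates and descending-neuron outputs.

#' Sinusoidal head-direction input over the preferred-direction grid
#'
#' The lumped EPG/Delta7 head-direction signal delivered to a PFL
#' population whose map is shifted by \code{shift}:
#' \code{cos(theta - theta0 - h + shift)} per unit.
#'
#' @param theta Head direction, degrees.
#' @param theta0 Map offset, degrees.
#' @param shift Map shift, degrees (+67.5 PFL3R, -67.5 PFL3L, 180 PFL2,
#'   0 for the unshifted reference).
#' @param h Preferred-direction grid uniformly tiling 360 degrees.
#' @return Per-unit input values in \code{[-1, 1]}.
#' @export
headInput <- function(theta, theta0, shift, h) {
  if (length(h) == 0L) stop("empty preferred-direction grid")
  cos((theta - theta0 - h + shift) * DEG2RAD)
}

#' Sinusoidal goal input over the preferred-direction grid
#'
#' \code{A * cos(theta_g - theta0 - h)}: the goal is encoded like a head
#' direction, with the same map offset, so a shift of theta0 moves both
#' representations together.
#'
#' @param thetaG Goal direction, degrees.
#' @param theta0 Map offset, degrees.
#' @param A Goal amplitude (>= 0).
#' @param h Preferred-direction grid.
#' @return Per-unit input values in \code{[-A, A]}.
#' @export
goalInput <- function(thetaG, theta0, A, h) {
  if (length(h) == 0L) stop("empty preferred-direction grid")
  if (A < 0) stop("goal amplitude A must be >= 0")
  A * cos((thetaG - theta0 - h) * DEG2RAD)
}

#' PFL population rates for a given head direction and goal
#'
#' Sums head-direction and goal inputs per unit, scales by S and passes
#' the result through the calibrated activation.
#'
#' @param theta Head direction, degrees.
#' @param thetaG Goal direction, degrees.
#' @param params A \linkS4class{ModelParams}.
#' @param cal Calibration from [calibrateModel()] (computed when missing).
#' @param S Scale factor override (default \code{params@S}).
#' @return List with per-unit rate vectors \code{pfl2}, \code{pfl3r},
#'   \code{pfl3l}.
#' @export
pflRates <- function(theta, thetaG, params, cal = calibrateModel(params),
                     S = params@S) {
  h <- cal$h
  t0 <- params@theta0
  A <- params@goalAmplitude
  g <- goalInput(thetaG, t0, A, h)
  list(
    pfl2 = eluActivation(S * (headInput(theta, t0, params@shiftPfl2, h) + g),
                         cal$pfl2, cal$kind),
    pfl3r = eluActivation(S * (headInput(theta, t0, params@shiftPfl3, h) + g),
                          cal$pfl3r, cal$kind),
    pfl3l = eluActivation(S * (headInput(theta, t0, -params@shiftPfl3, h) + g),
                          cal$pfl3l, cal$kind)
  )
}

#' Descending-neuron outputs from PFL rates
#'
#' DNa03R/L take PFL3 input from their own side plus the bilaterally
#' symmetric PFL2 input (weight 4); DNa02R/L take same-side PFL3 (direct
#' pathway) plus DNa03 (indirect pathway, weight 12). The \code{pathway}
#' argument zeroes the other pathway's term at the DNa02 summation while
#' keeping the calibrated activation fixed.
#'
#' @param activity List from [pflRates()].
#' @param params A \linkS4class{ModelParams}.
#' @param cal Calibration from [calibrateModel()].
#' @param pathway "full", "direct" (PFL3 -> DNa02 only) or "indirect"
#'   (PFL2/PFL3 -> DNa03 -> DNa02 only).
#' @return List with scalars \code{dna03r}, \code{dna03l}, \code{dna02r},
#'   \code{dna02l}.
#' @export
descendingOutputs <- function(activity, params, cal = calibrateModel(params),
                              pathway = c("full", "direct", "indirect")) {
  pathway <- match.arg(pathway)
  sc <- cal$popScale
  p2 <- params@wP2D3 * sc * sum(activity$pfl2)
  d3r <- eluActivation(params@wP3D3 * sc * sum(activity$pfl3r) + p2,
                       cal$dna03, cal$kind)
  d3l <- eluActivation(params@wP3D3 * sc * sum(activity$pfl3l) + p2,
                       cal$dna03, cal$kind)
  directR <- params@wP3D2 * sc * sum(activity$pfl3r)
  directL <- params@wP3D2 * sc * sum(activity$pfl3l)
  indirectR <- params@wD3D2 * d3r
  indirectL <- params@wD3D2 * d3l
  inR <- switch(pathway, full = directR + indirectR, direct = directR,
                indirect = indirectR)
  inL <- switch(pathway, full = directL + indirectL, direct = directL,
                indirect = indirectL)
  list(dna03r = d3r, dna03l = d3l,
       dna02r = eluActivation(inR, cal$dna02, cal$kind),
       dna02l = eluActivation(inL, cal$dna02, cal$kind))
}

#' Steering drive from descending outputs
#'
#' The rotational-velocity command: \code{gain * (DNa02R - DNa02L) +
#' epsilon}, positive = clockwise (rightward).
#'
#' @param dna List from [descendingOutputs()].
#' @param cal Calibration (supplies the resolved gain).
#' @param epsilon Additive noise term, degrees/s.
#' @return Degrees/s.
#' @export
steeringDrive <- function(dna, cal, epsilon = 0) {
  cal$gain * (dna$dna02r - dna$dna02l) + epsilon
}

#' Open-loop activity and drive profiles versus directional error
#'
#' Evaluates the model at a fixed goal over a grid of directional errors,
#' returning summed population activities, the PFL2 bump amplitude
#' (sinusoid fit across units) and the steering drive decomposed by
#' pathway.
#'
#' @param params A \linkS4class{ModelParams}.
#' @param errorGrid Directional errors in degrees (default 1-deg grid over
#'   \code{(-180, 180]}).
#' @param cal Calibration from [calibrateModel()].
#' @return A data.frame with columns \code{error_deg}, \code{sum_pfl3r},
#'   \code{sum_pfl3l}, \code{pfl3_diff}, \code{sum_pfl2}, \code{pfl2_amp},
#'   \code{drive_full}, \code{drive_direct}, \code{drive_indirect}.
#' @export
openLoopProfiles <- function(params, errorGrid = seq(-179, 180, by = 1),
                             cal = calibrateModel(params)) {
  if (length(errorGrid) == 0L) stop("empty error grid")
  sc <- cal$popScale
  rows <- lapply(errorGrid, function(e) {
    act <- pflRates(e, 0, params, cal)
    amp <- bumpAmplitudeFromProjector(act$pfl2, cal$bumpProj)
    dFull <- descendingOutputs(act, params, cal, "full")
    dDir <- descendingOutputs(act, params, cal, "direct")
    dInd <- descendingOutputs(act, params, cal, "indirect")
    c(error_deg = e,
      sum_pfl3r = sc * sum(act$pfl3r), sum_pfl3l = sc * sum(act$pfl3l),
      pfl3_diff = sc * (sum(act$pfl3r) - sum(act$pfl3l)),
      sum_pfl2 = sc * sum(act$pfl2), pfl2_amp = amp,
      drive_full = steeringDrive(dFull, cal),
      drive_direct = steeringDrive(dDir, cal),
      drive_indirect = steeringDrive(dInd, cal))
  })
  as.data.frame(do.call(rbind, rows))
}

## amplitude of the fitted sinusoid given the precomputed LS projector
bumpAmplitudeFromProjector <- function(profile, proj) {
  beta <- proj %*% profile
  sqrt(beta[2L, 1L]^2 + beta[3L, 1L]^2)
}
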