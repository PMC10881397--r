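## Activation-function calibration for the steering network.
##
## Every unit uses the same nonlinearity f. Its input M is first affinely
## mapped so that, over the calibration ensemble (all head directions, all
## goal directions, all configured S values and all unit indices), M spans
## exactly [-1, 1]; f is applied; and the result is affinely mapped so the
## ensemble output spans exactly [0, 1]. The ensemble is evaluated per cell
## type. Because the preferred-direction grid h uniformly tiles 360 deg,
## the input extrema over a (theta, theta_g) grid depend only on the
## directional error theta - theta_g, so the calibration sweep runs over a
## 1-degree error grid crossed with the unit grid and the S values.

## Real cell count per PFL population (hemibrain): population sums are
## scaled by CELLS_PER_POP / nUnits so the model's unit count is a pure
## discretization resolution and the 1/4/12 per-connection weights keep
## their anatomical meaning whatever nUnits is.
CELLS_PER_POP <- 12

.eluRaw <- function(m) ifelse(m >= 0, m, exp(m) - 1)

.activationRaw <- function(m, kind) {
  switch(kind,
    elu = .eluRaw(m),
    relu = pmax(m, 0),
    ## expansive logistic: inflection at the calibrated maximum, so the
    ## operating range [-1, 1] lies on the convex limb. (A logistic
    ## centred on the range is odd-symmetric, which makes population
    ## sums over a full-cycle sinusoid amplitude-independent and
    ## abolishes the error signal entirely.)
    sigmoid = 1 / (1 + exp(-3 * (m - 1))),
    stop("unknown activation: ", kind)
  )
}

## output range of the raw activation over m in [-1, 1] (all three choices
## are monotone increasing, so the range is [f(-1), f(1)])
.activationOutRange <- function(kind) {
  .activationRaw(c(-1, 1), kind)
}

#' Apply the calibrated activation function
#'
#' Maps inputs to \code{[-1, 1]} using the calibration extrema, applies
#' the activation, and rescales so the calibrated ensemble output spans
#' \code{[0, 1]}. With \code{kind = "identity"} the input is returned
#' unchanged (the linear reference case in which the shared PFL2 drive
#' cancels out of the DNa02 right-left difference).
#'
#' @param M Numeric input array (weighted sum of synaptic inputs).
#' @param calRange Length-2 numeric: the ensemble min and max of M.
#' @param kind "elu", "relu", "sigmoid" or "identity".
#' @return Rates; within \code{[0, 1]} for inputs inside the calibrated
#'   range (non-identity kinds).
#' @export
eluActivation <- function(M, calRange, kind = "elu") {
  if (kind == "identity") {
    return(M)
  }
  if (length(calRange) != 2L || !all(is.finite(calRange))) {
    stop("calRange must be two finite numbers")
  }
  if (diff(calRange) <= 0) {
    stop("degenerate calibration: min must be < max")
  }
  m <- 2 * (M - calRange[1L]) / (calRange[2L] - calRange[1L]) - 1
  v <- .activationRaw(m, kind)
  r <- .activationOutRange(kind)
  (v - r[1L]) / (r[2L] - r[1L])
}

#' Calibrate the network's activation functions and steering gain
#'
#' Computes, per cell type, the extrema of the summed synaptic input over
#' the calibration ensemble (error grid x unit grid x \code{calibrationS}),
#' and the steering gain when \code{params@steeringGain} is \code{NA}
#' (chosen so the peak noise-free open-loop drive of the full model at
#' S = 1 is 200 deg/s).
#'
#' @param params A \linkS4class{ModelParams}.
#' @param pathway "full" (default), "direct" or "indirect": which model
#'   variant's input ensemble calibrates the DNa02 activation. Ablated
#'   closed-loop runs use their own ensemble; the steering gain is always
#'   resolved on the full model.
#' @return A list with the unit grid \code{h}, per-cell-type input ranges
#'   (\code{pfl2}, \code{pfl3r}, \code{pfl3l}, \code{dna03},
#'   \code{dna02}), the resolved \code{gain}, the activation \code{kind},
#'   the population scale and the bump-fit projector for the unit grid.
#' @export
calibrateModel <- function(params,
                           pathway = c("full", "direct", "indirect")) {
  stopifnot(is(params, "ModelParams"))
  pathway <- match.arg(pathway)
  n <- params@nUnits
  h <- roiAngleGrid(n)
  popScale <- CELLS_PER_POP / n
  kind <- params@activation
  A <- params@goalAmplitude
  sVals <- sort(unique(params@calibrationS))
  errGrid <- seq(-179, 180, by = 1)

  ## per-unit head/goal input profiles as error x unit matrices
  ## (theta = err, theta_g = 0, theta0 = 0: extrema are invariant to the
  ## absolute angles because h tiles the circle uniformly)
  prof <- function(shift) {
    hd <- cos(outer(errGrid, h, function(e, hh) (e - hh + shift) * DEG2RAD))
    gl <- A * cos(outer(rep(0, length(errGrid)), h, function(g, hh)
      (g - hh) * DEG2RAD))
    hd + gl
  }
  m2 <- prof(params@shiftPfl2)
  m3r <- prof(params@shiftPfl3)
  m3l <- prof(-params@shiftPfl3)

  rangeOverS <- function(m) range(outer(range(m), sVals))
  cal <- list(
    h = h,
    kind = kind,
    popScale = popScale,
    pathway = pathway,
    pfl2 = rangeOverS(m2),
    pfl3r = rangeOverS(m3r),
    pfl3l = rangeOverS(m3l)
  )
  if (kind == "identity") {
    cal$dna03 <- cal$dna02 <- c(-1, 1)  # unused for identity
  } else {
    ## DNa input extrema depend nonlinearly on S: sweep S explicitly
    sums <- lapply(sVals, function(s) {
      list(p2 = popScale * rowSums(eluActivation(s * m2, cal$pfl2, kind)),
           p3r = popScale * rowSums(eluActivation(s * m3r, cal$pfl3r, kind)),
           p3l = popScale * rowSums(eluActivation(s * m3l, cal$pfl3l, kind)))
    })
    cal$dna03 <- range(unlist(lapply(sums, function(x) {
      range(params@wP3D3 * c(x$p3r, x$p3l) + params@wP2D3 * c(x$p2, x$p2))
    })))
    cal$dna02 <- range(unlist(lapply(sums, function(x) {
      d3 <- eluActivation(params@wP3D3 * c(x$p3r, x$p3l) +
                            params@wP2D3 * c(x$p2, x$p2), cal$dna03, kind)
      direct <- params@wP3D2 * c(x$p3r, x$p3l)
      indirect <- params@wD3D2 * d3
      range(switch(pathway, full = direct + indirect, direct = direct,
                   indirect = indirect))
    })))
  }

  ## bump-fit projector over the unit grid (shared design matrix)
  x <- h * DEG2RAD
  X <- cbind(1, sin(x), cos(x))
  cal$bumpProj <- solve(crossprod(X), t(X))

  ## steering gain: peak open-loop |DNa02R - DNa02L| at S = 1, full model
  if (is.na(params@steeringGain)) {
    calFull <- cal
    if (pathway != "full" && kind != "identity") {
      calFull$dna02 <- range(unlist(lapply(sums, function(x) {
        d3 <- eluActivation(params@wP3D3 * c(x$p3r, x$p3l) +
                              params@wP2D3 * c(x$p2, x$p2), cal$dna03, kind)
        range(params@wP3D2 * c(x$p3r, x$p3l) + params@wD3D2 * d3)
      })))
    }
    pk <- max(abs(vapply(errGrid, function(e) {
      act <- pflRates(e, 0, params, calFull, S = 1)
      d <- descendingOutputs(act, params, calFull, "full")
      d$dna02r - d$dna02l
    }, numeric(1))))
    cal$gain <- if (pk > 0) 200 / pk else 0
  } else {
    cal$gain <- params@steeringGain
  }
  cal
}
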