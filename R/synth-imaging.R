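## Synthetic columnar calcium imaging: sinusoidal bumps phase-locked to
## heading, with a controlled amplitude law and Gaussian noise on the
## z-scored scale.

#' Generate synthetic ROI fluorescence with a controlled bump
#'
#' Produces a sinusoidal brain-space profile at each imaging frame. The
#' bump phase moves opposite to heading (the fly turning clockwise moves
#' the bump leftward/counterclockwise in brain space), and the bump
#' amplitude follows one of three laws of directional error: "pfl2"
#' (minimal at the goal, maximal at the anti-goal, scaling with
#' 1 - cos(theta - theta_g)), "pfl3" (the reverse) or "constant".
#'
#' @param heading Heading series, degrees.
#' @param sampleRate Hz of the heading series.
#' @param thetaG Goal direction, degrees.
#' @param region "PB" (10 ROIs), "FB" (9) or "LAL" (2; see
#'   [synthLalFromModel()] for model-linked LAL signals).
#' @param amplitudeLaw "pfl2", "pfl3" or "constant".
#' @param ampMax,ampMin Amplitude extremes, z-units.
#' @param offset Vertical offset c, z-units.
#' @param noiseSd Gaussian noise SD on the z scale (0 for exact
#'   recovery).
#' @param frameRate Imaging rate, Hz (6-8 in the emulated recordings).
#' @param phaseOffset Brain-space phase at heading 0 (degrees).
#' @param lagMs Delay of the bump phase behind heading, ms (for lag
#'   recovery tests).
#' @param seed Integer seed.
#' @return A list: \code{roi} (an \linkS4class{RoiTimeSeries} whose
#'   \code{raw} assay is an affine embedding of the profile into
#'   plausible fluorescence counts, with a \code{zscored} assay holding
#'   the noiseless-scale profile plus noise), \code{groundTruth}
#'   (per-frame amplitude and phase, heading at frames, theta_g).
#' @export
synthCalcium <- function(heading, sampleRate, thetaG, region = "PB",
                         amplitudeLaw = c("pfl2", "pfl3", "constant"),
                         ampMax = 2, ampMin = 0.3, offset = 1,
                         noiseSd = 0.2, frameRate = 7, phaseOffset = 0,
                         lagMs = 0, seed = 1L) {
  amplitudeLaw <- match.arg(amplitudeLaw)
  nRoi <- .regionRoiCount[[region]]
  tEnd <- (length(heading) - 1) / sampleRate
  ft <- seq(0, tEnd, by = 1 / frameRate)
  idx <- pmin(pmax(round((ft - lagMs / 1000) * sampleRate) + 1L, 1L),
              length(heading))
  hF <- heading[idx]
  err <- circDistDeg(hF, thetaG)
  amp <- switch(amplitudeLaw,
    pfl2 = ampMin + (ampMax - ampMin) * (1 - cos(err * DEG2RAD)) / 2,
    pfl3 = ampMin + (ampMax - ampMin) * (1 + cos(err * DEG2RAD)) / 2,
    constant = rep(ampMax, length(ft)))
  phase <- wrapDeg(phaseOffset - hF)
  x <- roiAngleGrid(nRoi) * DEG2RAD
  u <- (phase - 90) * DEG2RAD
  prof <- vapply(seq_along(ft), function(k) {
    amp[k] * sin(x - u[k]) + offset
  }, numeric(nRoi))
  set.seed(seed)
  if (noiseSd > 0) {
    prof <- prof + matrix(rnorm(length(prof), sd = noiseSd),
                          nrow = nRoi)
  }
  roi <- roiTimeSeries(50 * (1 + 0.2 * prof), region = region,
                       frameRate = frameRate, time = ft)
  SummarizedExperiment::assay(roi, "zscored") <- prof
  list(roi = roi,
       groundTruth = list(time = ft, amplitude = amp, phase = phase,
                          heading = hF, theta_g = thetaG,
                          amplitude_law = amplitudeLaw,
                          amp_range = max(amp) - min(amp), seed = seed))
}

#' Synthetic right/left LAL signals from the model's open-loop curves
#'
#' Evaluates the network's summed PFL3R and PFL3L activity (the
#' right/left LAL readout) at each frame's directional error and embeds
#' them as a 2-ROI LAL series (plus optional noise).
#'
#' @param params \linkS4class{ModelParams}.
#' @param heading Heading series, degrees.
#' @param sampleRate Hz of the heading series.
#' @param thetaG Goal direction, degrees.
#' @param what "pfl3" for right/left PFL3 sums (difference readout) or
#'   "pfl2" to place the summed PFL2 signal in both ROIs (sum readout).
#' @param frameRate Imaging rate, Hz.
#' @param noiseSd Gaussian noise SD.
#' @param seed Integer seed.
#' @return A list: \code{roi} (LAL \linkS4class{RoiTimeSeries} with a
#'   \code{zscored} assay; row order L then R), \code{groundTruth}.
#' @export
synthLalFromModel <- function(params, heading, sampleRate, thetaG,
                              what = c("pfl3", "pfl2"), frameRate = 7,
                              noiseSd = 0, seed = 1L) {
  what <- match.arg(what)
  cal <- calibrateModel(params)
  tEnd <- (length(heading) - 1) / sampleRate
  ft <- seq(0, tEnd, by = 1 / frameRate)
  idx <- pmin(round(ft * sampleRate) + 1L, length(heading))
  hF <- heading[idx]
  err <- circDistDeg(hF, thetaG)
  uerr <- sort(unique(err))
  lut <- vapply(uerr, function(e) {
    act <- pflRates(e, 0, params, cal)
    sc <- cal$popScale
    if (what == "pfl3") {
      c(sc * sum(act$pfl3l), sc * sum(act$pfl3r))
    } else {
      rep(sc * sum(act$pfl2), 2L)
    }
  }, numeric(2))
  vals <- lut[, match(err, uerr), drop = FALSE]
  set.seed(seed)
  if (noiseSd > 0) {
    vals <- vals + matrix(rnorm(length(vals), sd = noiseSd), nrow = 2L)
  }
  roi <- roiTimeSeries(vals - min(vals) + 1, region = "LAL",
                       frameRate = frameRate, time = ft)
  SummarizedExperiment::assay(roi, "zscored") <- vals
  list(roi = roi,
       groundTruth = list(time = ft, heading = hF, theta_g = thetaG,
                          what = what, seed = seed))
}
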