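#' @import methods
#' @importFrom stats sd median mad approx lm coef cor cor.test rnorm runif
#'   rpois rexp setNames aggregate anova as.formula oneway.test complete.cases
#'   fivenum quantile
#' @importFrom utils read.csv write.csv packageVersion head tail
#' @importFrom tools md5sum
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom S4Vectors DataFrame
NULL

#' Parameters of the PFL-to-descending-neuron steering network
#'
#' Container for the firing-rate model of the head-direction-to-steering
#' pathway. Each of the PFL2/PFL3R/PFL3L populations receives a sinusoidal
#' head-direction input over a preferred-direction grid \code{h} that
#' uniformly tiles 360 degrees, plus a shared sinusoidal goal input of
#' amplitude \code{goalAmplitude}; the sum is scaled by \code{S} and passed
#' through a calibrated nonlinearity. PFL3 maps are shifted +/-67.5 degrees
#' and the PFL2 map by 180 degrees relative to the head-direction
#' reference. Descending outputs: DNa03 = f(PFL3 + 4 x PFL2),
#' DNa02 = f(PFL3 + 12 x DNa03); the right-left DNa02 difference, times
#' \code{steeringGain}, is the rotational-velocity command.
#'
#' @slot nUnits Units per population (default 1000; use 12 to mimic the
#'   true cell counts).
#' @slot shiftPfl3 Head-direction map shift for PFL3R in degrees (+67.5;
#'   PFL3L uses the negative).
#' @slot shiftPfl2 Head-direction map shift for PFL2 in degrees (180).
#' @slot goalAmplitude Goal-input amplitude A (default 1).
#' @slot S Input scale factor in [0, 1] (default 1).
#' @slot theta0 Arbitrary offset of the head-direction map in degrees.
#' @slot wP3D2,wP3D3,wP2D3,wD3D2 Connection weights (1, 1, 4, 12).
#' @slot steeringGain Degrees/s of turning per unit DNa02 right-left
#'   difference. \code{NA} (default) means: calibrate so the peak
#'   noise-free open-loop drive at S = 1 is 200 deg/s.
#' @slot dt Integration step in seconds (0.1, i.e. a 10 Hz update).
#' @slot duration Simulated time in seconds.
#' @slot noiseSd Standard deviation enforced on the noise term (degrees/s).
#' @slot noiseCutoff Low-pass cutoff for the noise in Hz (2).
#' @slot seed Integer seed for the frozen noise sample.
#' @slot activation Activation function: "elu" (default), "relu",
#'   "sigmoid" or "identity".
#' @slot calibrationS S values defining the activation-calibration
#'   ensemble (the model's "lifetime" range of S).
#' @seealso [modelParams()], [simulateClosedLoop()]
#' @export
setClass("ModelParams", representation(
  nUnits = "integer",
  shiftPfl3 = "numeric",
  shiftPfl2 = "numeric",
  goalAmplitude = "numeric",
  S = "numeric",
  theta0 = "numeric",
  wP3D2 = "numeric",
  wP3D3 = "numeric",
  wP2D3 = "numeric",
  wD3D2 = "numeric",
  steeringGain = "numeric",
  dt = "numeric",
  duration = "numeric",
  noiseSd = "numeric",
  noiseCutoff = "numeric",
  seed = "integer",
  activation = "character",
  calibrationS = "numeric"
))

setValidity("ModelParams", function(object) {
  msg <- character()
  if (object@nUnits < 3L) msg <- c(msg, "nUnits must be >= 3")
  w <- c(object@wP3D2, object@wP3D3, object@wP2D3, object@wD3D2)
  if (any(w < 0)) msg <- c(msg, "all weights must be >= 0")
  if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
  if (object@goalAmplitude < 0) msg <- c(msg, "goalAmplitude must be >= 0")
  if (object@S < 0) msg <- c(msg, "S must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (!object@activation %in% c("elu", "relu", "sigmoid", "identity")) {
    msg <- c(msg, "activation must be one of elu/relu/sigmoid/identity")
  }
  if (length(object@calibrationS) < 1L || any(object@calibrationS < 0)) {
    msg <- c(msg, "calibrationS must be non-negative and non-empty")
  }
  if (length(msg)) msg else TRUE
})

#' Construct steering-model parameters
#'
#' @param nUnits,shiftPfl3,shiftPfl2,goalAmplitude,S,theta0 See
#'   \linkS4class{ModelParams}.
#' @param wP3D2,wP3D3,wP2D3,wD3D2 Connection weights.
#' @param steeringGain Deg/s per unit DNa02 difference; \code{NA} to
#'   calibrate automatically (peak open-loop drive 200 deg/s at S = 1).
#' @param dt,duration,noiseSd,noiseCutoff,seed Simulation settings.
#' @param activation Activation function name.
#' @param calibrationS S values over which the activation is calibrated.
#' @return A validated \linkS4class{ModelParams} object.
#' @examples
#' p <- modelParams(S = 0.8, duration = 100, seed = 1L)
#' @export
modelParams <- function(nUnits = 1000L, shiftPfl3 = 67.5, shiftPfl2 = 180,
                        goalAmplitude = 1, S = 1, theta0 = 0,
                        wP3D2 = 1, wP3D3 = 1, wP2D3 = 4, wD3D2 = 12,
                        steeringGain = NA_real_, dt = 0.1, duration = 100,
                        noiseSd = 10, noiseCutoff = 2, seed = 1L,
                        activation = "elu",
                        calibrationS = seq(0, 1, by = 0.25)) {
  new("ModelParams", nUnits = as.integer(nUnits), shiftPfl3 = shiftPfl3,
      shiftPfl2 = shiftPfl2, goalAmplitude = goalAmplitude, S = S,
      theta0 = theta0, wP3D2 = wP3D2, wP3D3 = wP3D3, wP2D3 = wP2D3,
      wD3D2 = wD3D2, steeringGain = steeringGain, dt = dt,
      duration = duration, noiseSd = noiseSd, noiseCutoff = noiseCutoff,
      seed = as.integer(seed), activation = activation,
      calibrationS = calibrationS)
}

setMethod("show", "ModelParams", function(object) {
  cat("ModelParams:", object@nUnits, "units/population, S =", object@S,
      ", A =", object@goalAmplitude, ", activation =", object@activation,
      "\n  weights P3->D2/P3->D3/P2->D3/D3->D2:",
      paste(c(object@wP3D2, object@wP3D3, object@wP2D3, object@wD3D2),
            collapse = "/"),
      "\n  dt =", object@dt, "s, duration =", object@duration,
      "s, noise SD =", object@noiseSd, "deg/s @", object@noiseCutoff,
      "Hz, seed =", object@seed, "\n")
})

#' Closed-loop steering simulation result
#'
#' @slot time Time in seconds (length duration/dt + 1).
#' @slot theta Head direction series in degrees, wrapped.
#' @slot error Directional error theta - thetaGoal, degrees.
#' @slot dna02Diff DNa02 right-left difference per step.
#' @slot pfl2Amp PFL2 bump amplitude per step (sinusoid fit across units).
#' @slot noise Noise term per step, degrees/s.
#' @slot rho Consistency of head direction over the whole run.
#' @slot thetaGoal Goal direction used, degrees.
#' @slot pathway "full", "direct" or "indirect".
#' @slot params The \linkS4class{ModelParams} used.
#' @export
setClass("SimulationResult", representation(
  time = "numeric", theta = "numeric", error = "numeric",
  dna02Diff = "numeric", pfl2Amp = "numeric", noise = "numeric",
  rho = "numeric", thetaGoal = "numeric", pathway = "character",
  params = "ModelParams"
))

setValidity("SimulationResult", function(object) {
  n <- length(object@time)
  if (!all(lengths(list(object@theta, object@error, object@dna02Diff,
                        object@noise)) == n)) {
    return("time, theta, error, dna02Diff and noise must share a length")
  }
  if (length(object@rho) == 1L && (object@rho < 0 || object@rho > 1)) {
    return("rho must lie in [0, 1]")
  }
  TRUE
})

setMethod("show", "SimulationResult", function(object) {
  cat("SimulationResult:", length(object@time), "steps,",
      object@params@duration, "s at dt =", object@params@dt,
      "s\n  pathway =", object@pathway,
      ", S =", object@params@S,
      ", final |error| =", round(abs(tail(object@error, 1)), 2),
      "deg, rho =", round(object@rho, 4), "\n")
})

#' @describeIn SimulationResult-class Flatten to a data.frame (columns
#'   time_s, theta_deg, error_deg, dna02_diff, pfl2_amp, noise).
#' @param x A SimulationResult.
#' @param ... Ignored.
#' @export
setMethod("as.data.frame", "SimulationResult", function(x, ...) {
  data.frame(time_s = x@time, theta_deg = x@theta, error_deg = x@error,
             dna02_diff = x@dna02Diff,
             pfl2_amp = if (length(x@pfl2Amp)) x@pfl2Amp else NA_real_,
             noise = x@noise)
})

#' Processed ball-kinematics trace
#'
#' Sixty-hertz kinematics derived from spherical-treadmill tracking:
#' forward and sideways translation in mm/s, rotational (yaw) velocity in
#' deg/s, cumulative ball speed (|forward| + |sideways| + |rotational|) in
#' ball rad/s, wrapped heading in degrees and a per-sample mobility flag
#' (cumulative speed > 0.67 rad/s).
#'
#' @slot time Seconds.
#' @slot forward,sideways mm/s.
#' @slot rotational deg/s.
#' @slot cumulativeSpeed rad/s in the ball frame.
#' @slot heading Degrees in (-180, 180] (NA when not supplied).
#' @slot mobile Logical per sample.
#' @slot sampleRate Hz (60).
#' @export
setClass("KinematicsTrace", representation(
  time = "numeric", forward = "numeric", sideways = "numeric",
  rotational = "numeric", cumulativeSpeed = "numeric",
  heading = "numeric", mobile = "logical", sampleRate = "numeric"
))

setValidity("KinematicsTrace", function(object) {
  n <- length(object@time)
  if (!all(lengths(list(object@forward, object@sideways, object@rotational,
                        object@cumulativeSpeed, object@heading,
                        object@mobile)) == n)) {
    return("all channels must share the time length")
  }
  if (object@sampleRate <= 0) return("sampleRate must be positive")
  TRUE
})

setMethod("show", "KinematicsTrace", function(object) {
  cat("KinematicsTrace:", length(object@time), "samples @",
      object@sampleRate, "Hz (", round(diff(range(object@time)), 1),
      "s );", sum(object@mobile), "mobile samples\n")
})

#' @describeIn KinematicsTrace-class Flatten to a data.frame.
#' @param x A KinematicsTrace.
#' @param ... Ignored.
#' @export
setMethod("as.data.frame", "KinematicsTrace", function(x, ...) {
  data.frame(time_s = x@time, forward_mm_s = x@forward,
             sideways_mm_s = x@sideways, rotational_deg_s = x@rotational,
             cumulative_speed_rad_s = x@cumulativeSpeed,
             heading_deg = x@heading, mobile = x@mobile)
})

#' Membrane-potential trace
#'
#' Whole-cell recording at 1 kHz. The stored voltage is assumed
#' liquid-junction corrected (-13 mV applied at load time; see
#' [readVmCsv()]).
#'
#' @slot time Seconds.
#' @slot vm Membrane potential, mV.
#' @slot samplingRate Hz (1000).
#' @slot cellType "PFL2", "PFL3R" or "PFL3L".
#' @slot baseline Spike-free baseline Vm (filled by [baselineVm()];
#'   length 0 until then).
#' @slot spikeTimes Seconds, strictly increasing (filled by
#'   [detectSpikes()]).
#' @export
setClass("VmTrace", representation(
  time = "numeric", vm = "numeric", samplingRate = "numeric",
  cellType = "character", baseline = "numeric", spikeTimes = "numeric"
))

setValidity("VmTrace", function(object) {
  if (length(object@vm) != length(object@time)) {
    return("vm and time must share a length")
  }
  if (length(object@baseline) &&
      length(object@baseline) != length(object@vm)) {
    return("baseline must be empty or match vm length")
  }
  if (length(object@spikeTimes) > 1L &&
      any(diff(object@spikeTimes) <= 0)) {
    return("spikeTimes must be strictly increasing")
  }
  TRUE
})

setMethod("show", "VmTrace", function(object) {
  cat("VmTrace (", object@cellType, "): ", length(object@vm),
      " samples @ ", object@samplingRate, " Hz; ",
      length(object@spikeTimes), " spikes detected\n", sep = "")
})

#' ROI fluorescence time series
#'
#' A \linkS4class{SummarizedExperiment} with ROIs as rows (rowData column
#' \code{angle_deg}: brain-space ROI centre, +180 = rightmost) and imaging
#' frames as columns (colData column \code{time_s}). Assays: \code{raw},
#' plus \code{dff} and \code{zscored} after [zscoreDff()].
#'
#' @slot region "PB" (10 ROIs), "FB" (9) or "LAL" (2).
#' @slot frameRate Volumetric frame rate, Hz.
#' @export
setClass("RoiTimeSeries",
         contains = "SummarizedExperiment",
         representation(region = "character", frameRate = "numeric"))

.regionRoiCount <- c(PB = 10L, FB = 9L, LAL = 2L)

setValidity("RoiTimeSeries", function(object) {
  if (!object@region %in% names(.regionRoiCount)) {
    return("region must be one of PB, FB, LAL")
  }
  if (nrow(object) != .regionRoiCount[[object@region]]) {
    return(sprintf("region %s requires %d ROIs, got %d", object@region,
                   .regionRoiCount[[object@region]], nrow(object)))
  }
  if (object@frameRate <= 0) return("frameRate must be positive")
  if (!"time_s" %in% colnames(SummarizedExperiment::colData(object))) {
    return("colData must contain time_s")
  }
  TRUE
})

#' Construct an RoiTimeSeries
#'
#' @param values ROI x frame matrix of raw fluorescence.
#' @param region "PB", "FB" or "LAL".
#' @param frameRate Hz.
#' @param time Frame times in seconds (default: frame index / frameRate).
#' @return An \linkS4class{RoiTimeSeries}.
#' @export
roiTimeSeries <- function(values, region, frameRate = 7,
                          time = (seq_len(ncol(values)) - 1) / frameRate) {
  values <- as.matrix(values)
  rowDat <- S4Vectors::DataFrame(angle_deg = roiAngleGrid(nrow(values)))
  if (region == "LAL") {
    ## the two LAL ROIs are left/right readouts, not brain-space columns
    rowDat <- S4Vectors::DataFrame(angle_deg = c(NA_real_, NA_real_),
                                   side = c("L", "R"))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(raw = values),
    rowData = rowDat,
    colData = S4Vectors::DataFrame(time_s = time)
  )
  new("RoiTimeSeries", se, region = region, frameRate = frameRate)
}

#' @describeIn RoiTimeSeries-class Imaged brain region.
#' @param x An RoiTimeSeries.
#' @export
imagingRegion <- function(x) x@region

#' @describeIn RoiTimeSeries-class Volumetric frame rate in Hz.
#' @export
frameRate <- function(x) x@frameRate

#' @describeIn RoiTimeSeries-class Frame times in seconds.
#' @export
frameTimes <- function(x) SummarizedExperiment::colData(x)$time_s

#' @describeIn RoiTimeSeries-class ROI brain-space angles in degrees.
#' @export
roiAngles <- function(x) SummarizedExperiment::rowData(x)$angle_deg

#' @describeIn RoiTimeSeries-class Extract an assay layer ("raw", "dff" or
#'   "zscored") as an ROI x frame matrix.
#' @param layer Assay name.
#' @export
roiValues <- function(x, layer = "raw") {
  if (!layer %in% SummarizedExperiment::assayNames(x)) {
    stop("layer '", layer, "' not present; run zscoreDff() first?")
  }
  SummarizedExperiment::assay(x, layer)
}

setMethod("show", "RoiTimeSeries", function(object) {
  cat("RoiTimeSeries:", object@region, "region,", nrow(object), "ROIs x",
      ncol(object), "frames @", object@frameRate, "Hz; layers:",
      paste(SummarizedExperiment::assayNames(object), collapse = ", "),
      "\n")
})
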