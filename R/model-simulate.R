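## Closed-loop steering simulation.
##
## Forward-Euler integration of d(theta)/dt = gain * (DNa02R - DNa02L) +
## epsilon at a 10 Hz update (dt = 0.1 s by default), with heading wrapped
## after every step. The noise term epsilon is a frozen sample: Gaussian
## draws low-pass filtered at 2 Hz (second-order Butterworth applied
## forward-backward, zero phase) and then rescaled to an exact sample SD.

#' Generate the frozen low-pass-filtered noise sample
#'
#' @param duration Seconds of simulated time (the trace has
#'   \code{duration/dt + 1} samples).
#' @param dt Time step, seconds.
#' @param sd Standard deviation enforced on the output, degrees/s. 0 gives
#'   an all-zero trace.
#' @param cutoff Low-pass cutoff, Hz; must be below the Nyquist rate
#'   \code{1/(2 dt)}. Use 0 to skip filtering.
#' @param seed Integer seed; equal seeds give identical traces.
#' @return Numeric vector of degrees/s with sample SD exactly \code{sd}.
#' @export
generateNoise <- function(duration, dt = 0.1, sd = 10, cutoff = 2,
                          seed = 1L) {
  if (sd < 0) stop("noise sd must be >= 0")
  n <- round(duration / dt) + 1L
  if (sd == 0) return(numeric(n))
  if (cutoff > 0 && cutoff >= 0.5 / dt) {
    stop("noise cutoff must be below the Nyquist rate 1/(2 dt)")
  }
  if (n < 12L) stop("duration too short for the noise filter")
  set.seed(as.integer(seed))
  x <- rnorm(n)
  if (cutoff > 0) {
    bf <- signal::butter(2, cutoff / (0.5 / dt), type = "low")
    x <- signal::filtfilt(bf, x)
  }
  x * (sd / stats::sd(x))
}

#' Simulate closed-loop steering
#'
#' Runs the network in closed loop: the steering drive at each step is fed
#' back into the head direction at the next step. Cue jumps can be
#' injected as instantaneous heading offsets, and intervals can be frozen
#' (heading held; used by the synthetic-behavior generator to emulate
#' immobility).
#'
#' @param params A \linkS4class{ModelParams}; \code{duration}, \code{dt},
#'   noise settings and \code{seed} are taken from it.
#' @param thetaInit Initial head direction, degrees.
#' @param thetaGoal Goal direction, degrees (default 0, so error = theta).
#' @param pathway "full", "direct" or "indirect" (ablation of the other
#'   pathway at the DNa02 summation).
#' @param noise Optional noise trace (degrees/s, one value per step); by
#'   default generated from the params.
#' @param jumpTimes,jumpMagnitudes Cue-jump schedule: at each jump time
#'   the heading is offset by the magnitude (degrees) before that step's
#'   rates are computed.
#' @param freeze Optional 2-column matrix of (start, end) times in
#'   seconds; within these intervals the heading does not change.
#' @param cal Calibration from [calibrateModel()].
#' @param recordBump Record the PFL2 bump amplitude per step (sinusoid fit
#'   across units; small extra cost).
#' @return A \linkS4class{SimulationResult}.
#' @examples
#' p <- modelParams(S = 1, duration = 10, noiseSd = 0)
#' sim <- simulateClosedLoop(p, thetaInit = 60)
#' abs(tail(sim@error, 1))  # converges toward the goal
#' @export
simulateClosedLoop <- function(params, thetaInit, thetaGoal = 0,
                               pathway = c("full", "direct", "indirect"),
                               noise = NULL,
                               jumpTimes = numeric(),
                               jumpMagnitudes = numeric(),
                               freeze = NULL,
                               cal = NULL,
                               recordBump = TRUE) {
  pathway <- match.arg(pathway)
  if (is.null(cal)) {
    ## an ablated run is its own model: calibrate on its own ensemble
    cal <- calibrateModel(params, pathway)
  }
  dt <- params@dt
  nStep <- round(params@duration / dt)
  time <- (0:nStep) * dt
  if (is.null(noise)) {
    noise <- generateNoise(params@duration, dt, params@noiseSd,
                           params@noiseCutoff, params@seed)
  }
  if (length(noise) != nStep + 1L) {
    stop("noise trace must have duration/dt + 1 samples")
  }
  if (length(jumpTimes) != length(jumpMagnitudes)) {
    stop("jumpTimes and jumpMagnitudes must have equal length")
  }
  jumpStep <- round(jumpTimes / dt)
  frozen <- rep(FALSE, nStep + 1L)
  if (!is.null(freeze) && nrow(freeze) > 0L) {
    for (r in seq_len(nrow(freeze))) {
      frozen[time >= freeze[r, 1L] & time < freeze[r, 2L]] <- TRUE
    }
  }

  theta <- numeric(nStep + 1L)
  dna02Diff <- numeric(nStep + 1L)
  pfl2Amp <- if (recordBump) numeric(nStep + 1L) else numeric(0)
  th <- wrapDeg(thetaInit)
  for (i in 0:nStep) {
    k <- i + 1L
    hit <- which(jumpStep == i)
    if (length(hit)) {
      th <- wrapDeg(th + sum(jumpMagnitudes[hit]))
    }
    if (!is.finite(th)) {
      stop("numerical divergence at step ", i)
    }
    theta[k] <- th
    act <- pflRates(th, thetaGoal, params, cal)
    dna <- descendingOutputs(act, params, cal, pathway)
    dna02Diff[k] <- dna$dna02r - dna$dna02l
    if (recordBump) {
      pfl2Amp[k] <- bumpAmplitudeFromProjector(act$pfl2, cal$bumpProj)
    }
    if (i < nStep) {
      dth <- if (frozen[k]) 0 else
        dt * (cal$gain * dna02Diff[k] + noise[k])
      th <- wrapDeg(th + dth)
    }
  }
  new("SimulationResult", time = time, theta = theta,
      error = circDistDeg(theta, thetaGoal), dna02Diff = dna02Diff,
      pfl2Amp = pfl2Amp, noise = noise, rho = circRho(theta),
      thetaGoal = thetaGoal, pathway = pathway, params = params)
}

#' Sweep the input scale factor S across noise seeds
#'
#' For each (S, seed) pair, runs a closed-loop simulation and reports the
#' consistency of head direction (rho = 1 - circular variance of theta)
#' over the full run, and the PFL2 bump-amplitude range (max - min of the
#' error-binned bump amplitude).
#'
#' @param params Base \linkS4class{ModelParams} (its \code{duration}
#'   should be at least 100 s for sweep use).
#' @param sValues S values to sweep (non-empty).
#' @param nSeeds Number of noise seeds; seed i is \code{params@seed + i - 1},
#'   matched across S values so comparisons are seed-paired.
#' @param ampBinDeg Bin width (degrees of directional error) for the
#'   amplitude-range computation.
#' @param thetaInit Initial heading for every run.
#' @return A data.frame with columns \code{S}, \code{seed}, \code{rho},
#'   \code{amp_range}.
#' @export
scaleSweep <- function(params, sValues, nSeeds = 1L, ampBinDeg = 10,
                       thetaInit = 0) {
  if (length(sValues) == 0L) stop("empty S value list")
  cal <- calibrateModel(params)
  grid <- expand.grid(seed = params@seed + seq_len(nSeeds) - 1L,
                      S = sValues)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- params
    p@S <- grid$S[i]
    p@seed <- as.integer(grid$seed[i])
    sim <- simulateClosedLoop(p, thetaInit, cal = cal)
    edges <- seq(-180, 180, by = ampBinDeg)
    bin <- cut(sim@error, edges, include.lowest = TRUE)
    binned <- tapply(sim@pfl2Amp, bin, mean)
    binned <- binned[!is.na(binned)]
    data.frame(S = p@S, seed = p@seed, rho = sim@rho,
               amp_range = if (length(binned)) diff(range(binned)) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Write a simulation result to CSV with a JSON run manifest
#'
#' @param sim A \linkS4class{SimulationResult}.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
writeSimulation <- function(sim, dir, prefix = "simulation") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, paste0(prefix, ".csv"))
  manifest <- file.path(dir, paste0(prefix, "_manifest.json"))
  write.csv(as.data.frame(sim), csv, row.names = FALSE)
  p <- sim@params
  jsonlite::write_json(list(
    params = list(
      n_units = p@nUnits, shift_pfl3 = p@shiftPfl3,
      shift_pfl2 = p@shiftPfl2, goal_amplitude = p@goalAmplitude,
      S = p@S, theta0 = p@theta0,
      w_p3_d2 = p@wP3D2, w_p3_d3 = p@wP3D3, w_p2_d3 = p@wP2D3,
      w_d3_d2 = p@wD3D2, steering_gain = p@steeringGain, dt = p@dt,
      duration = p@duration, noise_sd = p@noiseSd,
      noise_cutoff = p@noiseCutoff, activation = p@activation
    ),
    seed = p@seed,
    pathway = sim@pathway,
    theta_goal = sim@thetaGoal,
    rho = sim@rho,
    package_version = as.character(packageVersion("flysteer"))
  ), manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE,
  na = "null")
  invisible(c(csv = csv, manifest = manifest))
}

#' Read steering-model parameters from a JSON file
#'
#' The JSON mirrors \linkS4class{ModelParams} field for field (snake_case
#' keys as written by [writeSimulation()] manifests); absent fields take
#' the defaults of [modelParams()].
#'
#' @param path JSON file path.
#' @return A \linkS4class{ModelParams}.
#' @export
readModelParams <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  seed <- j$seed
  if (!is.null(j$params)) j <- c(j$params, list(seed = seed))
  pick <- function(key, default) {
    v <- j[[key]]
    if (!is.null(v) && !is.na(v)) v else default
  }
  modelParams(
    nUnits = pick("n_units", 1000L),
    shiftPfl3 = pick("shift_pfl3", 67.5),
    shiftPfl2 = pick("shift_pfl2", 180),
    goalAmplitude = pick("goal_amplitude", 1),
    S = pick("S", 1),
    theta0 = pick("theta0", 0),
    wP3D2 = pick("w_p3_d2", 1), wP3D3 = pick("w_p3_d3", 1),
    wP2D3 = pick("w_p2_d3", 4), wD3D2 = pick("w_d3_d2", 12),
    steeringGain = pick("steering_gain", NA_real_),
    dt = pick("dt", 0.1), duration = pick("duration", 100),
    noiseSd = pick("noise_sd", 10), noiseCutoff = pick("noise_cutoff", 2),
    seed = pick("seed", 1L), activation = pick("activation", "elu")
  )
}
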