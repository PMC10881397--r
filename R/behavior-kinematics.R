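## Spherical-treadmill kinematics preprocessing.
##
## Raw machine-vision output is a wrapped ball-position signal per axis
## (radians). Processing: unwrap -> low-pass (second-order Butterworth,
## corner expressed as a fraction of Nyquist at the acquisition rate) ->
## differentiate -> clip artefactual velocities at 20 rad/s -> local
## quadratic smoothing over a 33 ms window -> resample to 60 Hz ->
## convert to mm/s (translation, via the 4.5 mm ball radius) and deg/s
## (yaw).

BALL_RADIUS_MM <- 4.5      # 9-mm-diameter foam ball
VELOCITY_CLIP_RAD_S <- 20
MOBILE_SPEED_RAD_S <- 0.67 # cumulative-speed threshold for "moving"

.unwrapRad <- function(x) {
  d <- diff(x)
  d <- d - 2 * pi * round(d / (2 * pi))
  x[1L] + c(0, cumsum(d))
}

.centralGradient <- function(x, dt) {
  n <- length(x)
  g <- numeric(n)
  g[1L] <- (x[2L] - x[1L]) / dt
  g[n] <- (x[n] - x[n - 1L]) / dt
  g[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / (2 * dt)
  g
}

## local quadratic (Savitzky-Golay) smoothing over a time window
.smoothLocal <- function(x, windowS, rate) {
  n <- round(windowS * rate)
  n <- max(5L, n + (1L - n %% 2L))  # odd, at least 5 points
  if (n >= length(x)) return(x)
  signal::sgolayfilt(x, p = 2, n = n)
}

#' Preprocess raw ball-position series into a kinematics trace
#'
#' @param raw A data.frame with columns \code{time_s} and wrapped ball
#'   positions in radians: \code{forward_rad}, \code{sideways_rad},
#'   \code{yaw_rad}. An optional \code{cue_deg} column (cue azimuth on
#'   the arena) is converted to heading via [cueToHeading()]; an optional
#'   \code{heading_deg} column is taken as-is.
#' @param sampleRate Acquisition rate, Hz (>= 60).
#' @param ballDiameter Ball diameter in mm (default 9).
#' @param butterCorner Low-pass corner as a fraction of Nyquist at the
#'   acquisition rate (default 0.003; the units are ambiguous in typical
#'   rig descriptions, so this is exposed).
#' @param outRate Output rate, Hz (default 60).
#' @return A \linkS4class{KinematicsTrace} at \code{outRate}.
#' @export
preprocessKinematics <- function(raw, sampleRate, ballDiameter = 9,
                                 butterCorner = 0.003, outRate = 60) {
  need <- c("time_s", "forward_rad", "sideways_rad", "yaw_rad")
  if (!all(need %in% names(raw))) {
    stop("raw must contain columns: ", paste(need, collapse = ", "))
  }
  if (any(diff(raw$time_s) <= 0)) {
    stop("time_s must be strictly increasing")
  }
  if (sampleRate < outRate) {
    stop("sampleRate must be >= ", outRate, " Hz")
  }
  if (nrow(raw) < 24L) {
    stop("trace too short for filtering")
  }
  dt <- 1 / sampleRate
  bf <- signal::butter(2, butterCorner, type = "low")
  vel <- lapply(c("forward_rad", "sideways_rad", "yaw_rad"), function(chn) {
    x <- .unwrapRad(raw[[chn]])
    x <- signal::filtfilt(bf, x)
    v <- .centralGradient(x, dt)
    v <- pmin(pmax(v, -VELOCITY_CLIP_RAD_S), VELOCITY_CLIP_RAD_S)
    .smoothLocal(v, 0.033, sampleRate)
  })
  tOut <- seq(raw$time_s[1L], raw$time_s[nrow(raw)], by = 1 / outRate)
  res <- lapply(vel, function(v) approx(raw$time_s, v, xout = tOut)$y)
  fwd <- res[[1L]]; side <- res[[2L]]; yaw <- res[[3L]]
  cum <- abs(fwd) + abs(side) + abs(yaw)
  heading <- rep(NA_real_, length(tOut))
  if ("heading_deg" %in% names(raw)) {
    heading <- approx(raw$time_s, raw$heading_deg, xout = tOut)$y
  } else if ("cue_deg" %in% names(raw)) {
    cue <- approx(raw$time_s, raw$cue_deg, xout = tOut)$y
    heading <- cueToHeading(cue)
  }
  new("KinematicsTrace",
      time = tOut,
      forward = fwd * (ballDiameter / 2),
      sideways = side * (ballDiameter / 2),
      rotational = yaw * RAD2DEG,
      cumulativeSpeed = cum,
      heading = heading,
      mobile = cum > MOBILE_SPEED_RAD_S,
      sampleRate = outRate)
}

#' Convert cue azimuth into head direction
#'
#' Convention: 0 deg when the fly directly faces the cue, +90 when the
#' fly's head direction is 90 deg clockwise of the cue. With cue azimuth
#' measured positive-clockwise from the fly's midline, heading is the
#' negated azimuth. The series is lightly smoothed and out-of-range
#' values are clamped to +/-180 (set \code{wrap = TRUE} to wrap instead;
#' circular statistics downstream always re-wrap).
#'
#' @param cueDeg Cue azimuth series, degrees.
#' @param smoothN Odd window (samples) for light smoothing; 1 disables.
#' @param wrap Wrap instead of clamping at +/-180.
#' @return Heading series in degrees.
#' @export
cueToHeading <- function(cueDeg, smoothN = 5, wrap = FALSE) {
  h <- -cueDeg
  if (smoothN > 1 && length(h) > smoothN) {
    h <- signal::sgolayfilt(h, p = 2, n = smoothN + (1 - smoothN %% 2))
  }
  if (wrap) wrapDeg(h) else pmin(pmax(h, -180), 180)
}

#' Cue displacement commanded by ball yaw in closed loop
#'
#' The virtual-reality coupling: cue displacement = yaw gain x ball yaw
#' displacement (gain 0.7 in the experiments emulated here).
#'
#' @param yawDeg Cumulative ball yaw displacement, degrees.
#' @param yawGain Closed-loop gain (> 0).
#' @return Cue displacement in degrees.
#' @export
closedLoopCue <- function(yawDeg, yawGain = 0.7) {
  if (yawGain <= 0) stop("yawGain must be > 0")
  yawGain * yawDeg
}
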