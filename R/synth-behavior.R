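## Synthetic closed-loop behaviour with recorded ground truth.
##
## Two fixation modes: "model" drives heading with the steering network
## in closed loop (so behavioural recovery tests are linked to model
## parameters such as S), and "scripted" uses a mean-reverting angular
## process toward the goal (so behaviour-pipeline tests do not depend on
## the network model). Cue jumps follow the experimental protocol: one
## jump every 60 s, cycling +90, 180, -90 degrees, with closed-loop yaw
## gain 0.7 between ball yaw and cue displacement.

#' Specification for a synthetic trial
#'
#' @param duration Trial length, seconds (default 600, a 10-min trial).
#' @param jumpPeriodS Seconds between cue jumps (60).
#' @param jumpSequence Jump magnitudes cycled in order (+90, 180, -90),
#'   expressed as the heading displacement in degrees.
#' @param goalSchedule data.frame with \code{start_s} and \code{theta_g}:
#'   the goal direction in force from each start time ("scripted" mode;
#'   "model" mode uses the first entry only).
#' @param mode "model" or "scripted".
#' @param S Scale factor for model mode.
#' @param reversionRate Mean-reversion rate toward the goal (1/s) for
#'   scripted mode; 0 gives an unsteered random walk.
#' @param headingNoiseSd Scripted-mode angular noise, deg/sqrt(s).
#' @param immobility data.frame with \code{start_s}, \code{end_s}:
#'   intervals in which the fly stands still.
#' @param forwardMean,forwardSd Forward-velocity statistics, mm/s
#'   (plausible walking values; not constrained by the emulated rig).
#' @param yawGain Closed-loop gain (0.7).
#' @param sampleRate Output rate, Hz (60).
#' @param seed Integer seed.
#' @return A list of class \code{"synthTrialSpec"}.
#' @export
synthTrialSpec <- function(duration = 600, jumpPeriodS = 60,
                           jumpSequence = c(90, 180, -90),
                           goalSchedule = data.frame(start_s = 0,
                                                     theta_g = 0),
                           mode = c("scripted", "model"), S = 0.8,
                           reversionRate = 1.5, headingNoiseSd = 30,
                           immobility = NULL, forwardMean = 8,
                           forwardSd = 2, yawGain = 0.7,
                           sampleRate = 60, seed = 1L) {
  mode <- match.arg(mode)
  jumpTimes <- jumpPeriodS * seq_len(floor(duration / jumpPeriodS + 1e-9))
  if (length(jumpTimes)) {
    mags <- rep_len(jumpSequence, length(jumpTimes))
  } else {
    mags <- numeric(0)
  }
  structure(list(duration = duration, jumpTimes = jumpTimes,
                 jumpMagnitudes = mags, goalSchedule = goalSchedule,
                 mode = mode, S = S, reversionRate = reversionRate,
                 headingNoiseSd = headingNoiseSd,
                 immobility = immobility, forwardMean = forwardMean,
                 forwardSd = forwardSd, yawGain = yawGain,
                 sampleRate = sampleRate, seed = as.integer(seed)),
            class = "synthTrialSpec")
}

.inIntervals <- function(time, intervals) {
  out <- rep(FALSE, length(time))
  if (is.null(intervals) || nrow(intervals) == 0L) return(out)
  for (i in seq_len(nrow(intervals))) {
    out[time >= intervals$start_s[i] & time < intervals$end_s[i]] <- TRUE
  }
  out
}

.goalAt <- function(time, schedule) {
  idx <- findInterval(time, schedule$start_s)
  idx[idx < 1L] <- 1L
  schedule$theta_g[idx]
}

#' Generate synthetic closed-loop behaviour
#'
#' @param spec A [synthTrialSpec()].
#' @param params Model parameters for mode "model" (the spec's \code{S}
#'   and \code{seed} override the corresponding fields).
#' @return A list: \code{kinematics} (\linkS4class{KinematicsTrace}),
#'   \code{trial} (descriptor mirroring the trial JSON: jump schedule,
#'   arena, seed registry), \code{groundTruth} (goal schedule, per-jump
#'   will-correct labels, immobility intervals, generator settings),
#'   and \code{yaw_deg} / \code{cue_deg} series (cumulative ball yaw and
#'   cue azimuth implied by the yaw gain).
#' @export
synthBehavior <- function(spec, params = NULL) {
  stopifnot(inherits(spec, "synthTrialSpec"))
  fs <- spec$sampleRate
  dt <- 1 / fs
  n <- round(spec$duration * fs) + 1L
  time <- (0:(n - 1L)) * dt
  frozen <- .inIntervals(time, spec$immobility)
  thetaG <- .goalAt(time, spec$goalSchedule)
  jumpIdx <- round(spec$jumpTimes * fs) + 1L

  if (spec$mode == "model") {
    if (is.null(params)) params <- modelParams()
    params@S <- spec$S
    params@seed <- spec$seed
    params@dt <- dt
    params@duration <- spec$duration
    sim <- simulateClosedLoop(
      params, thetaInit = spec$goalSchedule$theta_g[1L],
      thetaGoal = spec$goalSchedule$theta_g[1L],
      jumpTimes = spec$jumpTimes, jumpMagnitudes = spec$jumpMagnitudes,
      freeze = if (is.null(spec$immobility)) NULL else
        as.matrix(spec$immobility), recordBump = FALSE)
    theta <- sim@theta
  } else {
    set.seed(spec$seed)
    theta <- numeric(n)
    theta[1L] <- thetaG[1L]
    z <- rnorm(n - 1L)
    jumpAt <- integer(n)
    jumpAt[jumpIdx[jumpIdx <= n]] <- seq_along(jumpIdx[jumpIdx <= n])
    for (i in seq_len(n - 1L)) {
      th <- theta[i]
      if (jumpAt[i] > 0L) {
        th <- wrapDeg(th + spec$jumpMagnitudes[jumpAt[i]])
        theta[i] <- th
      }
      dth <- if (frozen[i]) 0 else
        -spec$reversionRate * circDistDeg(th, thetaG[i]) * dt +
        spec$headingNoiseSd * sqrt(dt) * z[i]
      theta[i + 1L] <- wrapDeg(th + dth)
    }
    if (any(jumpAt[n] > 0L)) {
      theta[n] <- wrapDeg(theta[n] + spec$jumpMagnitudes[jumpAt[n]])
    }
  }

  ## rotational velocity excludes the cue-jump discontinuities (the ball
  ## did not move during a jump)
  dtheta <- c(0, circDistDeg(theta[-1L], theta[-n]))
  isJump <- rep(FALSE, n)
  isJump[jumpIdx[jumpIdx <= n]] <- TRUE
  dthetaBall <- ifelse(isJump, 0, dtheta)
  rot <- dthetaBall / dt                      # deg/s
  yawDeg <- cumsum(dthetaBall) / spec$yawGain # cumulative ball yaw
  cueDeg <- -theta                            # cue azimuth

  set.seed(spec$seed + 1L)
  ar1 <- function(nn, mean, sdv, phi = 0.98) {
    x <- numeric(nn)
    x[1L] <- mean
    e <- rnorm(nn, sd = sdv * sqrt(1 - phi^2))
    for (i in 2:nn) x[i] <- mean + phi * (x[i - 1L] - mean) + e[i]
    x
  }
  fwd <- pmax(0, ar1(n, spec$forwardMean, spec$forwardSd))
  side <- ar1(n, 0, spec$forwardSd / 2)
  fwd[frozen] <- 0
  side[frozen] <- 0
  rot[frozen] <- 0
  cum <- (abs(fwd) + abs(side)) / BALL_RADIUS_MM + abs(rot) * DEG2RAD

  kin <- new("KinematicsTrace", time = time, forward = fwd,
             sideways = side, rotational = rot, cumulativeSpeed = cum,
             heading = theta, mobile = cum > MOBILE_SPEED_RAD_S,
             sampleRate = fs)

  willCorrect <- vapply(seq_along(spec$jumpTimes), function(i) {
    jt <- spec$jumpTimes[i]
    still <- .inIntervals(jt + c(-5, 0, 5), spec$immobility)
    steered <- if (spec$mode == "model") spec$S >= 0.5 else
      spec$reversionRate >= 0.5
    steered && !any(still)
  }, logical(1))

  list(
    kinematics = kin,
    yaw_deg = yawDeg,
    cue_deg = cueDeg,
    trial = list(
      trial_id = sprintf("synth-%s-seed%d", spec$mode, spec$seed),
      duration_s = spec$duration,
      sample_rate_hz = fs,
      jump_times_s = spec$jumpTimes,
      jump_magnitudes_deg = spec$jumpMagnitudes,
      arena = list(yaw_gain = spec$yawGain),
      seed_registry = list(behavior = spec$seed)
    ),
    groundTruth = list(
      mode = spec$mode,
      goal_schedule = spec$goalSchedule,
      S = if (spec$mode == "model") spec$S else NULL,
      reversion_rate = if (spec$mode == "scripted")
        spec$reversionRate else NULL,
      immobility = spec$immobility,
      will_correct = willCorrect,
      seed = spec$seed
    )
  )
}
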