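## Inferred goal direction, consistency of head direction, and path
## segmentation by walking straightness.

#' Sliding-window goal direction and consistency
#'
#' For every sample, computes the circular mean of heading (the inferred
#' goal direction) and the mean resultant length rho over a centred
#' window, using only qualifying samples: the fly's cumulative speed must
#' exceed the mobility threshold, and samples within
#' \code{postJumpExclS} seconds after a cue jump are excluded (they are a
#' forced deviation from the maintained direction). Windows with no
#' qualifying samples yield \code{NA}.
#'
#' @param heading Heading series, degrees.
#' @param cumulativeSpeed Cumulative ball speed, rad/s (same length).
#' @param sampleRate Hz.
#' @param jumpTimes Cue-jump times, seconds (relative to sample 1 at
#'   t = 0 unless \code{time} is given).
#' @param time Optional time axis for the samples.
#' @param windowS Window length, seconds (default 30, centred).
#' @param speedThresh Mobility threshold, rad/s (default 0.67).
#' @param postJumpExclS Seconds excluded after each jump (default 5).
#' @return data.frame with \code{theta_g}, \code{rho}, \code{n} per
#'   sample.
#' @export
slidingGoalConsistency <- function(heading, cumulativeSpeed, sampleRate,
                                   jumpTimes = numeric(), time = NULL,
                                   windowS = 30, speedThresh = 0.67,
                                   postJumpExclS = 5) {
  n <- length(heading)
  if (length(cumulativeSpeed) != n) {
    stop("heading and cumulativeSpeed must share a length")
  }
  if (windowS * sampleRate >= n) {
    stop("window must be shorter than the trace")
  }
  if (is.null(time)) time <- (seq_len(n) - 1) / sampleRate
  qual <- !is.na(heading) & cumulativeSpeed > speedThresh
  for (jt in jumpTimes) {
    qual[time >= jt & time < jt + postJumpExclS] <- FALSE
  }
  rad <- ifelse(qual, heading, 0) * DEG2RAD
  s <- ifelse(qual, sin(rad), 0)
  c_ <- ifelse(qual, cos(rad), 0)
  half <- round(windowS * sampleRate / 2)
  csS <- cumsum(s); csC <- cumsum(c_); csN <- cumsum(qual)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  winSum <- function(cs) {
    prev <- numeric(n)
    has <- lo > 1L
    prev[has] <- cs[lo[has] - 1L]
    cs[hi] - prev
  }
  sw <- winSum(csS); cw <- winSum(csC); nw <- winSum(csN)
  thetaG <- ifelse(nw > 0, wrapDeg(atan2(sw, cw) * RAD2DEG), NA_real_)
  rho <- ifelse(nw > 0, sqrt(sw^2 + cw^2) / nw, NA_real_)
  data.frame(theta_g = thetaG, rho = rho, n = nw)
}

#' Segment a path by walking straightness
#'
#' Breaks the trial into segments at downward crossings of a consistency
#' threshold (default rho = 0.88); dips below threshold shorter than
#' \code{minDipS} are lumped into the surrounding segment. Per segment,
#' the inferred goal direction is the circular mean of heading over
#' mobile samples and rho is the mean of the per-sample consistency.
#' Segments are discarded (flagged invalid) when rho equals 1 exactly (a
#' frozen cue) or when the fly was never mobile for at least
#' \code{minActiveS} continuous seconds.
#'
#' @param rho Per-sample consistency (from [slidingGoalConsistency()];
#'   \code{NA} samples count as below threshold).
#' @param heading Heading series, degrees.
#' @param cumulativeSpeed Cumulative speed, rad/s.
#' @param sampleRate Hz.
#' @param rhoThresh Segmentation threshold (default 0.88).
#' @param minDipS Dips shorter than this do not break a segment (0.5 s).
#' @param minActiveS Minimum continuous mobility for a valid segment (2 s).
#' @param speedThresh Mobility threshold, rad/s.
#' @return data.frame of segments: \code{start_idx}, \code{end_idx}
#'   (half-open sample range), \code{theta_g}, \code{rho},
#'   \code{n_samples}, \code{valid}, \code{reason}.
#' @export
segmentPath <- function(rho, heading, cumulativeSpeed, sampleRate,
                        rhoThresh = 0.88, minDipS = 0.5, minActiveS = 2,
                        speedThresh = 0.67) {
  n <- length(rho)
  if (length(heading) != n || length(cumulativeSpeed) != n) {
    stop("rho, heading and cumulativeSpeed must share a length")
  }
  below <- is.na(rho) | rho < rhoThresh
  ## lump brief dips: below-runs shorter than minDipS flip to above,
  ## unless they touch the trace edge (no surrounding segment to join)
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  minDip <- round(minDipS * sampleRate)
  for (i in seq_along(r$values)) {
    if (r$values[i] && r$lengths[i] < minDip &&
        starts[i] > 1L && ends[i] < n) {
      below[starts[i]:ends[i]] <- FALSE
    }
  }
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- which(!r$values)
  if (!length(segs)) {
    return(data.frame(start_idx = integer(), end_idx = integer(),
                      theta_g = numeric(), rho = numeric(),
                      n_samples = integer(), valid = logical(),
                      reason = character()))
  }
  minActive <- round(minActiveS * sampleRate)
  out <- lapply(segs, function(i) {
    idx <- starts[i]:ends[i]
    mob <- cumulativeSpeed[idx] > speedThresh
    segRho <- mean(rho[idx], na.rm = TRUE)
    mobRun <- if (any(mob)) max(rle(mob)$lengths[rle(mob)$values]) else 0L
    reason <- "ok"
    ## rho pinned at 1 throughout means the cue never moved (a frozen
    ## panel); 1e-9 absorbs rolling-sum rounding
    if (all(rho[idx] >= 1 - 1e-9, na.rm = TRUE) && any(!is.na(rho[idx]))) {
      reason <- "rho_equal_1"
    } else if (mobRun < minActive) {
      reason <- "inactive"
    } else if (!any(mob & !is.na(heading[idx]))) {
      reason <- "no_heading"
    }
    thetaG <- if (reason %in% c("ok", "rho_equal_1")) {
      s <- circSummary(heading[idx][mob & !is.na(heading[idx])], na.rm = TRUE)
      if (s$undefined) NA_real_ else s$meanDirection
    } else NA_real_
    data.frame(start_idx = starts[i], end_idx = ends[i] + 1L,
               theta_g = thetaG, rho = segRho,
               n_samples = length(idx), valid = reason == "ok",
               reason = reason)
  })
  do.call(rbind, out)
}
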