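## Cue-jump classification: corrected/uncorrected x high-rho/low-rho.

#' Classify cue jumps as corrected/uncorrected and high/low consistency
#'
#' A jump is \emph{excluded} when the fly was essentially immobile before
#' it (cumulative speed never above threshold for >= 1 continuous second
#' in the 15 s pre-window) or when too little data flanks it. Otherwise
#' it is \emph{corrected} when heading returns to within tolerance of its
#' pre-jump circular mean (30 deg for +/-90 jumps, 60 deg for 180 jumps)
#' within 10 s; the \code{"fast"} criterion instead requires a return to
#' within 40/75 deg within 4 s (used to select rapid behavioural
#' responses for lag analyses). A jump is \emph{high rho} when the mean
#' per-sample consistency over mobile pre-jump samples is >= 0.88.
#'
#' @param heading Heading series, degrees.
#' @param rho Per-sample consistency (aligned with heading).
#' @param cumulativeSpeed Cumulative speed, rad/s.
#' @param sampleRate Hz.
#' @param jumps data.frame with \code{time} (s) and \code{magnitude}
#'   (degrees; +90, -90 or 180).
#' @param time Optional time axis (default: sample 1 at t = 0).
#' @param preS Pre-jump window, seconds (15).
#' @param criterion "standard" (30/60 deg within 10 s) or "fast"
#'   (40/75 deg within 4 s).
#' @param rhoThresh High-rho threshold (0.88).
#' @param speedThresh Mobility threshold, rad/s (0.67).
#' @param minMobileS Minimum continuous pre-jump mobility, seconds (1).
#' @return The jump table with added columns \code{pre_theta_mean},
#'   \code{pre_rho}, \code{corrected}, \code{high_rho}, \code{excluded},
#'   \code{reason}. For excluded jumps the classification columns are
#'   \code{NA}.
#' @export
classifyJump <- function(heading, rho, cumulativeSpeed, sampleRate, jumps,
                         time = NULL, preS = 15,
                         criterion = c("standard", "fast"),
                         rhoThresh = 0.88, speedThresh = 0.67,
                         minMobileS = 1) {
  criterion <- match.arg(criterion)
  returnS <- if (criterion == "standard") 10 else 4
  tol <- if (criterion == "standard") c(`90` = 30, `180` = 60)
         else c(`90` = 40, `180` = 75)
  n <- length(heading)
  if (is.null(time)) time <- (seq_len(n) - 1) / sampleRate
  if (!all(abs(jumps$magnitude) %in% c(90, 180))) {
    stop("jump magnitudes must be +90, -90 or 180 degrees")
  }
  rows <- lapply(seq_len(nrow(jumps)), function(i) {
    jt <- jumps$time[i]
    mag <- jumps$magnitude[i]
    out <- data.frame(time = jt, magnitude = mag,
                      pre_theta_mean = NA_real_, pre_rho = NA_real_,
                      corrected = NA, high_rho = NA,
                      excluded = TRUE, reason = "ok")
    pre <- which(time >= jt - preS & time < jt)
    post <- which(time > jt & time <= jt + returnS)
    if (length(pre) < preS * sampleRate * 0.99 ||
        length(post) < returnS * sampleRate * 0.99) {
      out$reason <- "insufficient_data"
      return(out)
    }
    mob <- cumulativeSpeed[pre] > speedThresh
    mobRun <- if (any(mob)) max(rle(mob)$lengths[rle(mob)$values]) else 0L
    if (mobRun < round(minMobileS * sampleRate)) {
      out$reason <- "immobile_pre"
      return(out)
    }
    hPre <- heading[pre][mob]
    hPre <- hPre[!is.na(hPre)]
    if (!length(hPre)) {
      out$reason <- "no_heading"
      return(out)
    }
    sm <- circSummary(hPre)
    out$pre_theta_mean <- sm$meanDirection
    out$pre_rho <- mean(rho[pre][mob], na.rm = TRUE)
    tolI <- tol[[as.character(abs(mag))]]
    dev <- abs(circDistDeg(heading[post], out$pre_theta_mean))
    out$corrected <- any(dev <= tolI, na.rm = TRUE)
    out$high_rho <- !is.na(out$pre_rho) && out$pre_rho >= rhoThresh
    out$excluded <- FALSE
    out
  })
  do.call(rbind, rows)
}
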