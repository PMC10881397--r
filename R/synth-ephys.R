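## Synthetic membrane potential: cosine head-direction tuning, spikes,
## and heading-modulated IPSP trains with recorded event times.

#' Generate a synthetic membrane-potential trace
#'
#' \code{vm = rest + (tuningAmp/2) cos(theta - theta_p) + goal bias +
#' IPSPs + spikes + noise}, at 1 kHz. IPSPs are exponential-recovery
#' events (instantaneous drop, tau 15 ms, amplitude 0.5-2 mV) from an
#' inhomogeneous Poisson process whose rate follows \code{ipspRateLaw}:
#' "cosine" makes the rate highest when heading equals theta_p (this
#' package's fixed convention for the heading-tuned inhibitory input),
#' "constant" is heading-independent, "none" disables events. Spikes are
#' Poisson with a rate that grows with the depolarization above rest,
#' pasted as brief templates.
#'
#' @param heading Heading at 1 kHz (or a scalar for a fixed heading).
#' @param durationS Trace length, seconds (required when heading is a
#'   scalar).
#' @param thetaP Preferred head direction, degrees.
#' @param rest Resting potential, mV (-55).
#' @param tuningAmp Peak-to-peak cosine tuning amplitude, mV.
#' @param goalBias Additive constant (mV) standing in for the
#'   goal-dependent input that scales tuning across cells.
#' @param ipspRateLaw "cosine", "constant" or "none".
#' @param ipspRate0 Baseline IPSP rate, Hz.
#' @param ipspTauMs IPSP recovery time constant, ms (15).
#' @param ipspAmpRange IPSP amplitude range, mV (0.5-2).
#' @param spikeRateMax Peak spike rate, Hz (0 disables spikes).
#' @param noiseSd Gaussian noise SD, mV (lightly smoothed).
#' @param sampleRate Hz (1000).
#' @param seed Integer seed.
#' @return A list: \code{vm} (a \linkS4class{VmTrace}),
#'   \code{groundTruth} (ipsp_times, spike_times, theta_p, rate law).
#' @export
synthVm <- function(heading, durationS = NULL, thetaP = 0, rest = -55,
                    tuningAmp = 10, goalBias = 0,
                    ipspRateLaw = c("cosine", "constant", "none"),
                    ipspRate0 = 8, ipspTauMs = 15,
                    ipspAmpRange = c(0.5, 2), spikeRateMax = 0,
                    noiseSd = 0.2, sampleRate = 1000, seed = 1L) {
  ipspRateLaw <- match.arg(ipspRateLaw)
  if (length(heading) == 1L) {
    if (is.null(durationS)) stop("durationS required for scalar heading")
    heading <- rep(heading, round(durationS * sampleRate) + 1L)
  }
  n <- length(heading)
  dt <- 1 / sampleRate
  time <- (0:(n - 1L)) * dt
  set.seed(seed)
  tune <- (tuningAmp / 2) * cos((heading - thetaP) * DEG2RAD)
  vm <- rest + tune + goalBias

  ipspTimes <- numeric(0)
  if (ipspRateLaw != "none" && ipspRate0 > 0) {
    rate <- switch(ipspRateLaw,
      cosine = ipspRate0 * (1 + cos((heading - thetaP) * DEG2RAD)),
      constant = rep(ipspRate0, n))
    hit <- which(runif(n) < rate * dt)
    if (length(hit)) {
      ## enforce the 20 ms minimum separation the detector assumes
      keep <- c(TRUE, diff(hit) >= 0.02 * sampleRate)
      while (!all(keep)) {
        hit <- hit[keep]
        keep <- c(TRUE, diff(hit) >= 0.02 * sampleRate)
      }
      amp <- runif(length(hit), ipspAmpRange[1L], ipspAmpRange[2L])
      kLen <- round(8 * ipspTauMs / 1000 * sampleRate)
      kern <- exp(-(0:(kLen - 1L)) / (ipspTauMs / 1000 * sampleRate))
      for (j in seq_along(hit)) {
        span <- hit[j]:min(n, hit[j] + kLen - 1L)
        vm[span] <- vm[span] - amp[j] * kern[seq_along(span)]
      }
      ipspTimes <- time[hit]
    }
  }

  spikeTimes <- numeric(0)
  if (spikeRateMax > 0) {
    drive <- pmax(0, tune + goalBias) / max(tuningAmp / 2 + goalBias, 1e-9)
    sRate <- spikeRateMax * drive
    sHit <- which(runif(n) < sRate * dt)
    if (length(sHit) > 1L) {
      keep <- c(TRUE, diff(sHit) >= 0.003 * sampleRate)
      sHit <- sHit[keep]
    }
    if (length(sHit)) {
      tpl <- c(10, 30, 12, -4, -2) # 5 ms spike + after-hyperpolarization
      for (j in sHit) {
        span <- j:min(n, j + length(tpl) - 1L)
        vm[span] <- vm[span] + tpl[seq_along(span)]
      }
      spikeTimes <- time[sHit]
    }
  }

  if (noiseSd > 0) {
    nz <- rnorm(n, sd = noiseSd)
    if (n > 7) nz <- signal::sgolayfilt(nz, p = 2, n = 7)
    vm <- vm + nz * (noiseSd / max(stats::sd(nz), 1e-12))
  }

  trace <- new("VmTrace", time = time, vm = vm,
               samplingRate = sampleRate, cellType = "PFL2",
               baseline = numeric(0), spikeTimes = numeric(0))
  list(vm = trace,
       groundTruth = list(ipsp_times = ipspTimes,
                          spike_times = spikeTimes, theta_p = thetaP,
                          rate_law = ipspRateLaw, rate0 = ipspRate0,
                          tuning_amp = tuningAmp, rest = rest,
                          seed = seed))
}
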