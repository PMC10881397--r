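## Membrane-potential processing: baseline extraction and spike
## detection.

.oddWin <- function(ms, sampleRate, minN = 3L) {
  n <- round(ms / 1000 * sampleRate)
  max(minN, n + (1L - n %% 2L))
}

## Local maxima of x at least minHeight high and minDist samples apart
## (greedy, highest first). Handles flat-topped peaks, which regex-based
## peak finders silently drop.
.findPeaksIdx <- function(x, minHeight, minDist) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  up <- c(TRUE, d >= 0)
  dn <- c(d < 0, TRUE)
  cand <- which(up & dn & x >= minHeight)
  if (!length(cand)) return(integer(0))
  ord <- cand[order(x[cand], decreasing = TRUE)]
  sel <- integer(0)
  for (i in ord) {
    if (!length(sel) || all(abs(sel - i) >= minDist)) sel <- c(sel, i)
  }
  sort(sel)
}

#' Read a membrane-potential CSV
#'
#' Expects columns \code{time_s} and \code{vm_mV} at 1 kHz. The liquid
#' junction potential correction (-13 mV) is applied at load time unless
#' the file was already corrected.
#'
#' @param path CSV path.
#' @param cellType "PFL2", "PFL3R" or "PFL3L".
#' @param junctionCorrection mV added to the recorded trace (default -13).
#' @param corrected Set TRUE if the file already contains corrected
#'   values.
#' @return A \linkS4class{VmTrace}.
#' @export
readVmCsv <- function(path, cellType = "PFL2", junctionCorrection = -13,
                      corrected = FALSE) {
  d <- read.csv(path)
  if (!all(c("time_s", "vm_mV") %in% names(d))) {
    stop("vm CSV must contain time_s and vm_mV")
  }
  vm <- d$vm_mV + if (corrected) 0 else junctionCorrection
  sr <- 1 / median(diff(d$time_s))
  new("VmTrace", time = d$time_s, vm = vm, samplingRate = round(sr),
      cellType = cellType, baseline = numeric(0), spikeTimes = numeric(0))
}

#' Estimate the spike-free baseline membrane potential
#'
#' Median filter over a 50 ms window (removing spikes), then light local
#' quadratic smoothing over 20 ms.
#'
#' @param vm Membrane potential, mV.
#' @param sampleRate Hz (1000 for these recordings).
#' @param medianMs Median-filter window, ms.
#' @param smoothMs Smoothing window, ms.
#' @return Baseline series, same length as \code{vm}.
#' @export
baselineVm <- function(vm, sampleRate = 1000, medianMs = 50,
                       smoothMs = 20) {
  k <- .oddWin(medianMs, sampleRate)
  if (length(vm) <= k) {
    stop("trace shorter than the median-filter window")
  }
  b <- stats::runmed(vm, k, endrule = "median")
  n <- .oddWin(smoothMs, sampleRate)
  if (n < length(b)) b <- signal::sgolayfilt(b, p = 2, n = n)
  as.numeric(b)
}

#' Detect spikes and compute a smoothed firing rate
#'
#' Threshold crossing on the high-pass residual (vm - baseline): peaks
#' above \code{thresholdMads} x MAD of the residual, with a refractory
#' minimum separation. The rate is spike counts in a sliding boxcar.
#'
#' @param vm Membrane potential, mV.
#' @param sampleRate Hz.
#' @param baseline Optional precomputed baseline (from [baselineVm()]).
#' @param thresholdMads Threshold in residual MADs (default 4).
#' @param minThresholdMv Absolute floor on the threshold, mV (default 1:
#'   spikes are mV-scale events, and a MAD-only threshold degenerates on
#'   near-noiseless traces).
#' @param refractoryMs Minimum spike separation, ms (default 2).
#' @param rateWindowMs Boxcar window for the rate, ms (default 100).
#' @return A list: \code{spikeTimes} (s, relative to sample 1 at t = 0),
#'   \code{rate} (spikes/s per sample), \code{threshold} (mV).
#' @export
detectSpikes <- function(vm, sampleRate = 1000,
                         baseline = baselineVm(vm, sampleRate),
                         thresholdMads = 4, minThresholdMv = 1,
                         refractoryMs = 2, rateWindowMs = 100) {
  resid <- vm - baseline
  thr <- max(thresholdMads * stats::mad(resid), minThresholdMv)
  minDist <- max(1L, round(refractoryMs / 1000 * sampleRate))
  idx <- .findPeaksIdx(resid, thr, minDist)
  ind <- numeric(length(vm))
  ind[idx] <- 1
  win <- max(1L, round(rateWindowMs / 1000 * sampleRate))
  rate <- as.numeric(stats::filter(ind, rep(1, win), sides = 2))
  rate[is.na(rate)] <- 0
  list(spikeTimes = (idx - 1) / sampleRate,
       rate = rate / (win / sampleRate),
       threshold = thr)
}

#' Fill the baseline and spike slots of a VmTrace
#'
#' @param x A \linkS4class{VmTrace}.
#' @param ... Passed to [detectSpikes()].
#' @return The trace with \code{baseline} and \code{spikeTimes} filled.
#' @export
processVmTrace <- function(x, ...) {
  stopifnot(is(x, "VmTrace"))
  b <- baselineVm(x@vm, x@samplingRate)
  sp <- detectSpikes(x@vm, x@samplingRate, baseline = b, ...)
  x@baseline <- b
  x@spikeTimes <- x@time[1L] + sp$spikeTimes
  x
}
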