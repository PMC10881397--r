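## IPSP detection and jump-evoked IPSP-frequency analysis.
##
## These cells receive strong head-direction-tuned inhibitory input;
## during quiescence the membrane potential is bombarded by IPSPs whose
## rate depends on the distance between head direction and the cell's
## preferred direction. Detection follows a dual-criterion scheme: a
## rapid downward deflection (negative peak in the derivative of the
## despiked trace) must occur within a short coincidence window before a
## negative peak in the slow-detrended trace.

#' Detect IPSPs in a membrane-potential trace
#'
#' Pipeline: despike (25 ms median filter) and lightly smooth (20 ms
#' local quadratic); find negative peaks of the derivative (minimum
#' separation 20 ms, per-cell threshold in MADs of the derivative during
#' quiescence); independently find negative peaks of the detrended trace
#' (trace minus its 500 ms median filter); accept an event when a
#' derivative peak falls within 30 ms before a detrended peak. Analysis
#' is restricted to quiescent samples.
#'
#' @param vm Membrane potential, mV.
#' @param sampleRate Hz (1000).
#' @param quiescentMask Logical per sample; events outside quiescence are
#'   dropped and thresholds are estimated on quiescent data only.
#' @param medianMs Despiking median window (25).
#' @param smoothMs Light smoothing window (20).
#' @param detrendMs Detrending median window (500).
#' @param minSepMs Minimum peak separation (20).
#' @param coincMs Coincidence window: derivative peak within this many ms
#'   before the detrended peak (30).
#' @param derivThreshMads Derivative-peak threshold in noise MADs
#'   (default 2; kept permissive because precision is protected by the
#'   coincidence requirement with the detrended-peak criterion).
#' @param ampThreshMads Detrended-peak threshold in noise MADs (3).
#' @param twoPass Iterate detection: mask detected events, re-estimate
#'   the noise MADs on the cleaned trace and detect again until the
#'   event count stabilizes (default TRUE, up to \code{maxPasses}).
#'   Event-laden traces inflate a single-pass MAD and depress recall at
#'   high event rates.
#' @param maxPasses Maximum detection passes (6).
#' @return data.frame of events: \code{time} (s), \code{derivative_peak}
#'   (mV/ms, negative), \code{detrended_peak} (mV, negative).
#' @export
detectIpsps <- function(vm, sampleRate = 1000, quiescentMask = NULL,
                        medianMs = 25, smoothMs = 20, detrendMs = 500,
                        minSepMs = 20, coincMs = 30,
                        derivThreshMads = 2, ampThreshMads = 3,
                        twoPass = TRUE, maxPasses = 6L) {
  n <- length(vm)
  if (is.null(quiescentMask)) quiescentMask <- rep(TRUE, n)
  if (!any(quiescentMask)) {
    stop("no quiescent samples available for IPSP analysis")
  }
  b <- as.numeric(stats::runmed(vm, .oddWin(medianMs, sampleRate),
                                endrule = "median"))
  sw <- .oddWin(smoothMs, sampleRate)
  if (sw < n) b <- as.numeric(signal::sgolayfilt(b, p = 2, n = sw))
  dtMs <- 1000 / sampleRate
  deriv <- .centralGradient(b, dtMs)                       # mV/ms
  detr <- b - as.numeric(stats::runmed(b, .oddWin(detrendMs, sampleRate),
                                       endrule = "median"))
  minDist <- max(1L, round(minSepMs / 1000 * sampleRate))
  coinc <- round(coincMs / 1000 * sampleRate)
  detectPass <- function(noiseMask) {
    ## absolute floors keep near-noiseless traces from a zero threshold
    thrD <- max(derivThreshMads * stats::mad(deriv[noiseMask]), 1e-4)
    thrA <- max(ampThreshMads * stats::mad(detr[noiseMask]), 1e-3)
    iD <- .findPeaksIdx(-deriv, thrD, minDist)
    iA <- .findPeaksIdx(-detr, thrA, minDist)
    if (!length(iD) || !length(iA)) return(list(iA = integer(0)))
    keep <- vapply(iA, function(i) any(iD >= i - coinc & iD <= i),
                   logical(1))
    list(iA = iA[keep], iD = iD)
  }
  res <- detectPass(quiescentMask)
  if (twoPass) {
    pre <- round(0.03 * sampleRate)
    post <- round(0.05 * sampleRate)
    prev <- -1L
    for (it in seq_len(maxPasses)) {
      if (length(res$iA) == prev) break
      prev <- length(res$iA)
      clean <- quiescentMask
      for (i in res$iA) clean[max(1L, i - pre):min(n, i + post)] <- FALSE
      if (sum(clean) <= sampleRate) break
      res <- detectPass(clean)
    }
  }
  iA <- res$iA[quiescentMask[res$iA]]
  if (!length(iA)) {
    return(data.frame(time = numeric(), derivative_peak = numeric(),
                      detrended_peak = numeric()))
  }
  dPk <- vapply(iA, function(i) {
    cand <- res$iD[res$iD >= i - coinc & res$iD <= i]
    min(deriv[cand])
  }, numeric(1))
  data.frame(time = (iA - 1) / sampleRate,
             derivative_peak = dPk,
             detrended_peak = detr[iA])
}

#' Jump-evoked change in IPSP frequency versus change in |theta - theta_p|
#'
#' For cue jumps around which the fly was immobile for the whole +/-5 s
#' window, compares the change in detected IPSP frequency (after minus
#' before) with the change in the absolute angular distance between head
#' direction and the cell's preferred direction produced by the jump
#' (negative = the jump brought heading closer to theta_p).
#'
#' @param eventTimes IPSP event times, s.
#' @param jumps data.frame with \code{time} (s) and \code{magnitude}.
#' @param heading Heading series, degrees.
#' @param sampleRate Hz of the heading series.
#' @param thetaP Preferred head direction of the cell, degrees.
#' @param quiescentMask Logical per heading sample.
#' @param windowS Half-window, seconds (5).
#' @param fly Optional fly/cell identity per jump, enabling the
#'   unbalanced two-factor ANOVA (type-III sums of squares) of frequency
#'   change against the heading term and identity.
#' @return A list: \code{table} (per-jump data.frame with
#'   \code{d_abs_offset} and \code{d_freq}), \code{r}, \code{p},
#'   \code{slope}, \code{intercept}, and \code{anova} when \code{fly} is
#'   given.
#' @export
ipspJumpResponse <- function(eventTimes, jumps, heading, sampleRate,
                             thetaP, quiescentMask = NULL, windowS = 5,
                             fly = NULL) {
  n <- length(heading)
  time <- (seq_len(n) - 1) / sampleRate
  if (is.null(quiescentMask)) quiescentMask <- rep(TRUE, n)
  rows <- lapply(seq_len(nrow(jumps)), function(i) {
    jt <- jumps$time[i]
    win <- time >= jt - windowS & time <= jt + windowS
    if (!any(win) || jt - windowS < time[1L] || jt + windowS > time[n]) {
      return(NULL)
    }
    if (!all(quiescentMask[win])) return(NULL)  # fly moved: skip
    pre <- time >= jt - windowS & time < jt
    post <- time > jt & time <= jt + windowS
    hPre <- circMeanDeg(heading[pre], na.rm = TRUE)
    hPost <- circMeanDeg(heading[post], na.rm = TRUE)
    fPre <- sum(eventTimes >= jt - windowS & eventTimes < jt) / windowS
    fPost <- sum(eventTimes > jt & eventTimes <= jt + windowS) / windowS
    data.frame(
      jump = i, time = jt,
      d_abs_offset = abs(circDistDeg(hPost, thetaP)) -
        abs(circDistDeg(hPre, thetaP)),
      d_freq = fPost - fPre)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) < 3L) {
    stop("fewer than 3 qualifying (fully immobile) jumps")
  }
  ct <- suppressWarnings(cor.test(tab$d_abs_offset, tab$d_freq))
  fit <- lm(d_freq ~ d_abs_offset, data = tab)
  out <- list(table = tab, r = unname(ct$estimate), p = ct$p.value,
              slope = unname(coef(fit)[2L]),
              intercept = unname(coef(fit)[1L]))
  if (!is.null(fly)) {
    dd <- cbind(tab, fly = factor(fly[tab$jump]))
    m <- lm(d_freq ~ d_abs_offset + fly, data = dd,
            contrasts = list(fly = "contr.sum"))
    out$anova <- car::Anova(m, type = 3)
  }
  out
}
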