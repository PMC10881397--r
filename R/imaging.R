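## Calcium-imaging analyses: dF/F z-scoring, phase-heading coupling, LAL
## readouts, neural goal inference and error-binned brain-space profiles.

#' Compute dF/F and the MAD-based z-score per ROI
#'
#' Per ROI: dF/F = (F - F0)/F0 with F0 the mean of the bottom decile of
#' the trial's fluorescence values; the z-scored layer is the
#' median/MAD-normalized dF/F, y = (x - median(x)) / median(|x -
#' median(x)|) (raw MAD, no consistency constant), so each ROI's z layer
#' has median 0 and MAD 1 by construction. ROIs with MAD 0 (constant
#' fluorescence) are flagged with a warning and filled with NA.
#'
#' @param x An \linkS4class{RoiTimeSeries} with a \code{raw} assay.
#' @param bottomFrac Fraction of lowest values defining F0 (default 0.1).
#' @return The object with \code{dff} and \code{zscored} assays added.
#' @export
zscoreDff <- function(x, bottomFrac = 0.1) {
  stopifnot(is(x, "RoiTimeSeries"))
  raw <- roiValues(x, "raw")
  if (ncol(raw) == 0L) stop("empty trial")
  dff <- raw
  zs <- raw
  for (i in seq_len(nrow(raw))) {
    v <- raw[i, ]
    f0 <- mean(sort(v)[seq_len(max(1L, floor(bottomFrac * length(v))))])
    if (f0 <= 0) {
      stop("non-positive baseline fluorescence in ROI ", i)
    }
    d <- (v - f0) / f0
    dff[i, ] <- d
    md <- median(d)
    madRaw <- median(abs(d - md))
    if (madRaw == 0) {
      warning("ROI ", i, " has zero MAD (constant fluorescence); ",
              "z-scores set to NA")
      zs[i, ] <- NA_real_
    } else {
      zs[i, ] <- (d - md) / madRaw
    }
  }
  SummarizedExperiment::assay(x, "dff") <- dff
  SummarizedExperiment::assay(x, "zscored") <- zs
  x
}

#' Coupling between bump-phase changes and heading changes
#'
#' Splits the recording into fixed-length bins and compares the
#' start-to-end change in bump phase (shortest-arc difference, positive =
#' clockwise in brain space) with the change in head direction over the
#' same bin, with the phase series lagged behind heading by
#' \code{lagMs}. Bins containing invalid fits or immobile samples are
#' excluded.
#'
#' @param phase Bump-phase series, degrees (from [fitBumpSeries()]).
#' @param heading Heading series aligned with \code{phase}, degrees.
#' @param valid Logical: per-sample fit validity (adjusted r^2 >= 0.1).
#' @param mobile Logical: per-sample mobility.
#' @param sampleRate Hz of the aligned series.
#' @param binS Bin length, seconds (default 1.5).
#' @param lagMs Phase lag behind heading, milliseconds (default 200).
#' @return A list: \code{pairs} (data.frame \code{d_heading},
#'   \code{d_phase}), \code{r} and \code{p} (Pearson), \code{slope} and
#'   \code{intercept} of the least-squares line.
#' @export
phaseHeadingCoupling <- function(phase, heading, valid, mobile,
                                 sampleRate, binS = 1.5, lagMs = 200) {
  n <- length(phase)
  if (!all(lengths(list(heading, valid, mobile)) == n)) {
    stop("phase, heading, valid and mobile must share a length")
  }
  lagN <- round(lagMs / 1000 * sampleRate)
  ## phase lags heading: compare heading[t] with phase[t + lag]
  idxP <- seq_len(n - lagN) + lagN
  idxH <- seq_len(n - lagN)
  ph <- phase[idxP]; hd <- heading[idxH]
  ok <- valid[idxP] & mobile[idxH] & !is.na(ph) & !is.na(hd)
  binN <- round(binS * sampleRate)
  nBins <- floor(length(ph) / binN)
  dP <- dH <- rep(NA_real_, nBins)
  for (b in seq_len(nBins)) {
    i0 <- (b - 1L) * binN + 1L
    i1 <- b * binN
    if (all(ok[i0:i1])) {
      dP[b] <- circDistDeg(ph[i1], ph[i0])
      dH[b] <- circDistDeg(hd[i1], hd[i0])
    }
  }
  keep <- !is.na(dP)
  if (sum(keep) < 3L) {
    stop("fewer than 3 usable bins")
  }
  dP <- dP[keep]; dH <- dH[keep]
  ct <- cor.test(dH, dP)
  fit <- lm(dP ~ dH)
  list(pairs = data.frame(d_heading = dH, d_phase = dP),
       r = unname(ct$estimate), p = ct$p.value,
       slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]))
}

#' Right/left LAL sum and difference, binned by behaviour
#'
#' For the two-ROI lateral-accessory-lobe readout, computes the
#' right+left sum and right-left difference of the z-scored signals and
#' bins each against a behavioural conditioning series per segment,
#' delegating to [binSignalByBehavior()].
#'
#' @param x An \linkS4class{RoiTimeSeries} with region "LAL" and a
#'   \code{zscored} assay.
#' @param conditioning Conditioning series aligned with frames.
#' @param kind Passed to [binSignalByBehavior()].
#' @return A list of data.frames \code{sum} and \code{diff}.
#' @export
lalSumAndDiff <- function(x, conditioning,
                          kind = c("error", "rotational", "forward")) {
  stopifnot(is(x, "RoiTimeSeries"))
  kind <- match.arg(kind)
  if (imagingRegion(x) != "LAL") {
    stop("lalSumAndDiff requires region LAL")
  }
  z <- roiValues(x, "zscored")
  side <- SummarizedExperiment::rowData(x)$side
  r <- z[which(side == "R"), ]
  l <- z[which(side == "L"), ]
  list(sum = binSignalByBehavior(r + l, conditioning, kind),
       diff = binSignalByBehavior(r - l, conditioning, kind))
}

#' Infer the goal direction from bump amplitude
#'
#' Groups bump amplitudes by head direction in fixed-width bins, finds
#' the pair of opposing bins (180 deg apart) with the largest amplitude
#' difference, and returns the head direction of the smaller-amplitude
#' bin as the neurally inferred goal (the model predicts the bump is
#' smallest at the goal and largest at the anti-goal). Also returns the
#' max - min of the binned amplitudes (the "bump amplitude range").
#'
#' @param amplitude Bump-amplitude series.
#' @param heading Aligned heading, degrees.
#' @param binDeg Head-direction bin width, degrees (default 5).
#' @return A list: \code{theta_g} (degrees; bin centre), \code{amp_range},
#'   \code{pair_diff} (the winning opposing-pair difference),
#'   \code{reliable} (\code{FALSE} when the amplitude is essentially
#'   flat), \code{binned} (data.frame of bin centres, mean amplitude, n).
#' @export
inferGoalFromAmplitude <- function(amplitude, heading, binDeg = 5) {
  ok <- !is.na(amplitude) & !is.na(heading)
  amplitude <- amplitude[ok]; heading <- wrapDeg(heading[ok])
  nBins <- round(360 / binDeg)
  edges <- seq(-180, 180, length.out = nBins + 1L)
  idx <- findInterval(heading, edges, left.open = TRUE,
                      rightmost.closed = TRUE)
  centers <- edges[-1L] - binDeg / 2
  m <- vapply(seq_len(nBins), function(b) {
    v <- amplitude[idx == b]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  half <- nBins %/% 2L
  pairDiff <- abs(m[seq_len(half)] - m[seq_len(half) + half])
  if (all(is.na(pairDiff))) {
    stop("no opposing head-direction bin pairs are covered")
  }
  best <- argmaxFirst(pairDiff)
  lowBin <- if (!is.na(m[best]) && !is.na(m[best + half]) &&
                m[best] <= m[best + half]) best else best + half
  ampRange <- diff(range(m, na.rm = TRUE))
  list(theta_g = centers[lowBin],
       amp_range = ampRange,
       pair_diff = max(pairDiff, na.rm = TRUE),
       reliable = ampRange > sqrt(.Machine$double.eps),
       binned = data.frame(bin_center = centers, mean = m,
                           n = tabulate(idx, nBins)))
}

#' Error-binned brain-space activity profiles
#'
#' Bins each ROI's z-scored activity into 90-degree bins of directional
#' error (theta - theta_g, bins centred on 0, +/-90 and 180) and returns
#' the per-ROI mean within each bin: the spatial profile of population
#' activity as a function of how far the fly is from its goal.
#'
#' @param x An \linkS4class{RoiTimeSeries} with a \code{zscored} assay.
#' @param heading Heading per frame, degrees.
#' @param thetaG Goal direction, degrees (e.g. from
#'   [inferGoalFromAmplitude()]).
#' @param binDeg Error bin width (default 90).
#' @return A data.frame: \code{roi}, \code{angle_deg}, one column per
#'   error bin (named \code{err_<centre>}); empty bins give NA columns.
#' @export
errorBinnedProfiles <- function(x, heading, thetaG, binDeg = 90) {
  stopifnot(is(x, "RoiTimeSeries"))
  z <- roiValues(x, "zscored")
  if (length(heading) != ncol(z)) {
    stop("heading length must match frame count")
  }
  err <- circDistDeg(heading, thetaG)
  ## bin b covers err in (centers[b] - binDeg/2, centers[b] + binDeg/2];
  ## centers[1] = -180 is the anti-goal bin (wrapping across +/-180)
  centers <- seq(-180, 180 - binDeg, by = binDeg)
  ## bins centred on the centres: shift by half a width before cutting
  idx <- findInterval(wrapDeg(err + binDeg / 2),
                      seq(-180, 180, by = binDeg),
                      left.open = TRUE, rightmost.closed = TRUE)
  out <- data.frame(roi = seq_len(nrow(z)), angle_deg = roiAngles(x))
  for (b in seq_along(centers)) {
    sel <- which(idx == b & !is.na(err))
    out[[paste0("err_", centers[b])]] <-
      if (length(sel)) rowMeans(z[, sel, drop = FALSE]) else NA_real_
  }
  out
}
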