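## Head-direction tuning curves and their dependence on the goal offset.

#' Head-direction tuning curve, preferred direction and amplitude
#'
#' Bins a signal (baseline Vm or firing rate) by head direction. The
#' preferred direction theta_p is the centre of the bin with the maximum
#' binned mean (ties broken toward the smallest bin), and the tuning
#' amplitude is max - min of the binned means.
#'
#' @param values Signal per sample (mV or spikes/s).
#' @param heading Aligned heading, degrees.
#' @param binDeg Bin width, degrees (default 20).
#' @param minCoverage Warn when fewer than this fraction of bins have
#'   data (default 0.5).
#' @return A list: \code{curve} (data.frame \code{bin_center},
#'   \code{mean}, \code{n}), \code{theta_p}, \code{amplitude}.
#' @export
preferredDirectionTuning <- function(values, heading, binDeg = 20,
                                     minCoverage = 0.5) {
  ok <- !is.na(values) & !is.na(heading)
  values <- values[ok]; heading <- wrapDeg(heading[ok])
  nBins <- round(360 / binDeg)
  edges <- seq(-180, 180, length.out = nBins + 1L)
  idx <- findInterval(heading, edges, left.open = TRUE,
                      rightmost.closed = TRUE)
  centers <- edges[-1L] - binDeg / 2
  m <- vapply(seq_len(nBins), function(b) {
    v <- values[idx == b]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  nPer <- tabulate(idx, nBins)
  if (mean(!is.na(m)) < minCoverage) {
    warning("sparse head-direction coverage: ", sum(!is.na(m)), "/",
            nBins, " bins occupied")
  }
  best <- argmaxFirst(m)
  list(curve = data.frame(bin_center = centers, mean = m, n = nPer),
       theta_p = centers[best],
       amplitude = diff(range(m, na.rm = TRUE)))
}

#' Tuning curves grouped by the goal-to-preferred-direction offset
#'
#' Pools per-segment head-direction tuning curves across cells after
#' assigning each segment to a 72-degree bin of theta_g - theta_p (only
#' segments with rho >= 0.7 are used, to ensure enough samples per bin).
#' Curves are computed over theta - theta_p so cells align, optionally
#' min-subtracted, and averaged within each offset bin. For PFL3L cells
#' the offset sign is reversed before pooling (mirror-symmetric
#' population), so left and right cells contribute consistently.
#'
#' @param cells A list; each element describes one cell:
#'   \code{theta_p} (degrees), \code{cell_type} ("PFL2", "PFL3R",
#'   "PFL3L"), and \code{segments}: a list of segments each with
#'   \code{heading}, \code{value} (aligned numeric series), \code{theta_g}
#'   and \code{rho}.
#' @param offsetBinDeg Width of the theta_g - theta_p bins (72).
#' @param tuningBinDeg Width of the tuning-curve bins (20).
#' @param minSubtract Subtract each curve's minimum before averaging
#'   (TRUE; set FALSE for the raw-curve variant).
#' @param rhoMin Minimum segment rho (0.7).
#' @return data.frame: \code{offset_center}, \code{bin_center} (theta -
#'   theta_p), \code{mean}, \code{sem}, \code{n_curves}.
#' @export
tuningByGoalOffset <- function(cells, offsetBinDeg = 72,
                               tuningBinDeg = 20, minSubtract = TRUE,
                               rhoMin = 0.7) {
  nOff <- round(360 / offsetBinDeg)
  offEdges <- seq(-180, 180, length.out = nOff + 1L)
  offCenters <- offEdges[-1L] - offsetBinDeg / 2
  nBins <- round(360 / tuningBinDeg)
  tEdges <- seq(-180, 180, length.out = nBins + 1L)
  tCenters <- tEdges[-1L] - tuningBinDeg / 2
  curves <- list()
  for (cell in cells) {
    for (seg in cell$segments) {
      if (is.na(seg$rho) || seg$rho < rhoMin) next
      off <- circDistDeg(seg$theta_g, cell$theta_p)
      if (identical(cell$cell_type, "PFL3L")) off <- -off
      offBin <- findInterval(off, offEdges, left.open = TRUE,
                             rightmost.closed = TRUE)
      rel <- wrapDeg(seg$heading - cell$theta_p)
      idx <- findInterval(rel, tEdges, left.open = TRUE,
                          rightmost.closed = TRUE)
      cv <- vapply(seq_len(nBins), function(b) {
        v <- seg$value[idx == b]
        if (length(v)) mean(v) else NA_real_
      }, numeric(1))
      if (all(is.na(cv))) next
      if (minSubtract) cv <- cv - min(cv, na.rm = TRUE)
      curves[[length(curves) + 1L]] <- list(offBin = offBin, curve = cv)
    }
  }
  if (!length(curves)) stop("no usable segments (rho >= rhoMin)")
  rows <- list()
  for (b in seq_len(nOff)) {
    sel <- Filter(function(cu) cu$offBin == b, curves)
    if (!length(sel)) next
    m <- do.call(rbind, lapply(sel, `[[`, "curve"))
    rows[[length(rows) + 1L]] <- data.frame(
      offset_center = offCenters[b],
      bin_center = tCenters,
      mean = colMeans(m, na.rm = TRUE),
      sem = apply(m, 2L, function(v) {
        v <- v[!is.na(v)]
        if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
      }),
      n_curves = nrow(m))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
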