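## Behaviour-conditioned binning and event-triggered averaging.

#' Bin a signal by a behavioural conditioning variable
#'
#' Averages \code{signal} within bins of the conditioning series: 10
#' deg/s bins for rotational velocity, 1 mm/s for forward velocity, 10
#' deg for directional error (head direction relative to the inferred
#' goal). Bins are centred on multiples of the bin width (error bins
#' tile \code{(-180, 180]}). The caller removes immobile samples and
#' references error to the segment goal first, as the analyses require.
#'
#' @param signal Numeric series.
#' @param conditioning Aligned conditioning series (deg/s, mm/s or deg).
#' @param kind "rotational", "forward" or "error" (sets the default bin
#'   width: 10, 1, 10).
#' @param binWidth Override the bin width.
#' @return data.frame with \code{bin_center}, \code{mean}, \code{n};
#'   empty bins are dropped for velocity kinds and returned as \code{NA}
#'   means for error bins (which tile a fixed range).
#' @export
binSignalByBehavior <- function(signal, conditioning,
                                kind = c("rotational", "forward", "error"),
                                binWidth = NULL) {
  kind <- match.arg(kind)
  if (length(signal) != length(conditioning)) {
    stop("signal and conditioning must share a length")
  }
  if (is.null(binWidth)) {
    binWidth <- switch(kind, rotational = 10, forward = 1, error = 10)
  }
  ok <- !is.na(signal) & !is.na(conditioning)
  signal <- signal[ok]; conditioning <- conditioning[ok]
  if (kind == "error") {
    conditioning <- wrapDeg(conditioning)
    edges <- seq(-180, 180, by = binWidth)
    idx <- findInterval(conditioning, edges, left.open = TRUE,
                        rightmost.closed = TRUE)
    idx[conditioning == -180] <- 1L  # guard: wrapDeg excludes -180 anyway
    centers <- edges[-length(edges)] + binWidth / 2
    mean_ <- vapply(seq_along(centers), function(b) {
      v <- signal[idx == b]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    n_ <- vapply(seq_along(centers), function(b) sum(idx == b), integer(1))
    return(data.frame(bin_center = centers, mean = mean_, n = n_))
  }
  ctr <- round(conditioning / binWidth) * binWidth
  agg <- aggregate(signal, list(bin_center = ctr),
                   function(v) c(mean(v), length(v)))
  data.frame(bin_center = agg$bin_center, mean = agg$x[, 1L],
             n = as.integer(agg$x[, 2L]))
}

#' Event-triggered average across flies
#'
#' Hierarchical averaging around events (for example iontophoresis
#' pulses): windows of \code{+/- windowS} seconds around each event are
#' first averaged within each fly (per condition group, requiring at
#' least \code{minReps} usable repetitions), then the grand mean and
#' s.e.m. are computed across the per-fly averages.
#'
#' @param traces Named list (one element per fly) of data.frames with
#'   columns \code{time} and \code{value}.
#' @param events data.frame with columns \code{fly} (matching
#'   \code{names(traces)}), \code{time} (s) and \code{group} (condition
#'   label, e.g. pulse duration).
#' @param windowS Half-window, seconds (default 10).
#' @param sampleRate Lag-grid rate, Hz.
#' @param minReps Minimum usable repetitions per fly and group (4).
#' @return data.frame with \code{group}, \code{lag_s}, \code{mean},
#'   \code{sem}, \code{n_flies}.
#' @export
eventTriggeredAverage <- function(traces, events, windowS = 10,
                                  sampleRate = 60, minReps = 4) {
  lag <- seq(-windowS, windowS, by = 1 / sampleRate)
  groups <- unique(events$group)
  out <- list()
  for (g in groups) {
    flyMeans <- list()
    for (fly in unique(events$fly[events$group == g])) {
      tr <- traces[[fly]]
      if (is.null(tr)) stop("no trace for fly ", fly)
      ev <- events$time[events$group == g & events$fly == fly]
      wins <- list()
      for (tt in ev) {
        if (tt - windowS < min(tr$time) || tt + windowS > max(tr$time)) {
          warning("event at ", tt, " s (fly ", fly,
                  ") exceeds trace bounds; skipped")
          next
        }
        wins[[length(wins) + 1L]] <- approx(tr$time, tr$value,
                                            xout = tt + lag)$y
      }
      if (length(wins) >= minReps) {
        flyMeans[[fly]] <- colMeans(do.call(rbind, wins))
      }
    }
    if (!length(flyMeans)) next
    m <- do.call(rbind, flyMeans)
    out[[g]] <- data.frame(
      group = g, lag_s = lag, mean = colMeans(m),
      sem = apply(m, 2L, function(v) {
        if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
      }),
      n_flies = nrow(m))
  }
  if (!length(out)) {
    stop("no fly reached the minimum repetition count")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
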