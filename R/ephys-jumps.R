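## Jump-evoked membrane-potential statistics and the Vm-behaviour lag
## correlation.

#' Two-sample Brown-Forsythe test
#'
#' Tests equality of variances between groups via a one-way F test on
#' the absolute deviations from each group's median (the median-centred
#' Levene variant).
#'
#' @param x Numeric values.
#' @param g Group labels (two or more groups, each with >= 2 values).
#' @return A list: \code{statistic} (F), \code{df1}, \code{df2},
#'   \code{p.value}.
#' @export
brownForsythe <- function(x, g) {
  g <- factor(g)
  if (nlevels(g) < 2L) stop("need at least two groups")
  if (any(tapply(x, g, length) < 2L)) {
    stop("each group needs at least 2 values")
  }
  med <- tapply(x, g, median)
  z <- abs(x - med[as.integer(g)])
  ft <- oneway.test(z ~ g, var.equal = TRUE)
  list(statistic = unname(ft$statistic),
       df1 = unname(ft$parameter[1L]), df2 = unname(ft$parameter[2L]),
       p.value = ft$p.value)
}

#' Jump-evoked change in membrane potential, by jump class
#'
#' For each classified, non-excluded jump: the difference between mean
#' Vm over the 1 s after and the 1 s before the jump. The distributions
#' are compared between 'corrected, high rho' and 'uncorrected, low rho'
#' jumps with the Brown-Forsythe variance test (the model predicts
#' goal-directed flies show larger jump-evoked Vm transients, i.e. a
#' wider d-Vm distribution, not a mean shift).
#'
#' @param vm Membrane potential, mV.
#' @param sampleRate Hz.
#' @param jumpTable Output of [classifyJump()].
#' @param prePostS Window on each side of the jump, seconds (1).
#' @return A list: \code{table} (per-jump \code{d_vm} and \code{group}),
#'   \code{statistic}, \code{p.value}, \code{df1}, \code{df2}.
#' @export
jumpDvmStats <- function(vm, sampleRate, jumpTable, prePostS = 1) {
  n <- length(vm)
  time <- (seq_len(n) - 1) / sampleRate
  keep <- !jumpTable$excluded
  jt <- jumpTable[keep, , drop = FALSE]
  rows <- lapply(seq_len(nrow(jt)), function(i) {
    t0 <- jt$time[i]
    pre <- vm[time >= t0 - prePostS & time < t0]
    post <- vm[time > t0 & time <= t0 + prePostS]
    if (!length(pre) || !length(post)) return(NULL)
    grp <- if (jt$corrected[i] && jt$high_rho[i]) {
      "corrected_high_rho"
    } else if (!jt$corrected[i] && !jt$high_rho[i]) {
      "uncorrected_low_rho"
    } else {
      NA_character_
    }
    data.frame(time = t0, d_vm = mean(post) - mean(pre), group = grp)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[!is.na(tab$group), , drop = FALSE]
  if (any(table(tab$group) < 2L) || length(unique(tab$group)) < 2L) {
    stop("need >= 2 jumps in each class for the variance comparison")
  }
  bf <- brownForsythe(tab$d_vm, tab$group)
  c(list(table = tab), bf)
}

#' Lagged correlation between jump-evoked |dVm| and rotational speed
#'
#' For each fast-corrected jump, computes the absolute deviation of Vm
#' (relative to its 4 s pre-jump mean) over the 4 s after the jump, and
#' correlates it with lagged copies of rotational speed over the same
#' window. Positive lags mean Vm leads behaviour. The mean and s.e.m.
#' of the correlation across jumps is returned per lag.
#'
#' @param vm Membrane potential, mV.
#' @param speed Rotational speed, deg/s, aligned with \code{vm}.
#' @param sampleRate Hz of both series.
#' @param jumpTable Output of \code{classifyJump(..., criterion =
#'   "fast")}; only corrected, non-excluded jumps are used.
#' @param windowS Analysis window after the jump, seconds (4).
#' @param lagMaxS Maximum |lag|, seconds (1).
#' @param lagStepS Lag step, seconds (0.01).
#' @return data.frame: \code{lag_s}, \code{mean_r}, \code{sem_r},
#'   \code{n_jumps}.
#' @export
dvmSpeedLagCorrelation <- function(vm, speed, sampleRate, jumpTable,
                                   windowS = 4, lagMaxS = 1,
                                   lagStepS = 0.01) {
  if (length(vm) != length(speed)) {
    stop("vm and speed must share a length")
  }
  n <- length(vm)
  time <- (seq_len(n) - 1) / sampleRate
  lags <- seq(-lagMaxS, lagMaxS, by = lagStepS)
  use <- which(!jumpTable$excluded & jumpTable$corrected)
  if (!length(use)) stop("no qualifying fast-corrected jumps")
  rs <- matrix(NA_real_, nrow = length(use), ncol = length(lags))
  for (j in seq_along(use)) {
    t0 <- jumpTable$time[use[j]]
    i0 <- which.min(abs(time - t0))
    wPost <- (i0 + 1L):(i0 + round(windowS * sampleRate))
    wPre <- (i0 - round(windowS * sampleRate)):(i0 - 1L)
    if (wPre[1L] < 1L ||
        max(wPost) + round(lagMaxS * sampleRate) > n ||
        wPost[1L] - round(lagMaxS * sampleRate) < 1L) {
      next
    }
    dvm <- abs(vm[wPost] - mean(vm[wPre]))
    for (k in seq_along(lags)) {
      sh <- round(lags[k] * sampleRate)
      sp <- speed[wPost + sh]
      if (stats::sd(sp) > 0 && stats::sd(dvm) > 0) {
        rs[j, k] <- cor(dvm, sp)
      }
    }
  }
  ok <- rowSums(!is.na(rs)) > 0
  if (!any(ok)) stop("no jump had enough flanking data")
  rs <- rs[ok, , drop = FALSE]
  data.frame(
    lag_s = lags,
    mean_r = colMeans(rs, na.rm = TRUE),
    sem_r = apply(rs, 2L, function(v) {
      v <- v[!is.na(v)]
      if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
    }),
    n_jumps = nrow(rs))
}
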