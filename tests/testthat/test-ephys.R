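## Baseline extraction, spike and IPSP detection, tuning, jump-evoked
## statistics.

test_that("baseline tracks a spike-free trace and removes brief spikes", {
  set.seed(20)
  n <- 5000
  vm <- -50 + 2 * sin(2 * pi * (1:n) / 2000)
  b <- baselineVm(vm)
  expect_lt(max(abs(b - vm)), 0.05)
  ## inject 2 ms x 30 mV spikes on a flat -50 mV trace
  vmS <- rep(-50, n)
  for (i in seq(500, 4500, by = 400)) vmS[i:(i + 1)] <- -20
  bS <- baselineVm(vmS)
  expect_lt(max(abs(bS + 50)), 0.5)
  ## a step transitions cleanly; local-quadratic smoothing may ring by
  ## a few percent of the step height but no more
  vmStep <- c(rep(-60, 2500), rep(-45, 2500))
  bStep <- baselineVm(vmStep)
  expect_gte(min(bStep), -60 - 1.5)
  expect_lte(max(bStep), -45 + 1.5)
  expect_error(baselineVm(rep(-50, 20)), "shorter")
})

test_that("spike detection finds templates and respects the refractory
          period", {
  syn <- synthVm(0, durationS = 20, thetaP = 0, tuningAmp = 4,
                 spikeRateMax = 20, ipspRateLaw = "none", noiseSd = 0.1,
                 seed = 21L)
  det <- detectSpikes(syn$vm@vm)
  tr <- syn$groundTruth$spike_times
  ## every true spike matched within 3 ms, few spurious detections
  matched <- vapply(tr, function(s) any(abs(det$spikeTimes - s) < 3e-3),
                    logical(1))
  expect_gte(mean(matched), 0.95)
  expect_lte(length(det$spikeTimes), length(tr) * 1.1)
  ## noise-only trace: false positives below 1 Hz
  syn0 <- synthVm(0, durationS = 20, tuningAmp = 0, spikeRateMax = 0,
                  ipspRateLaw = "none", noiseSd = 0.2, seed = 22L)
  det0 <- detectSpikes(syn0$vm@vm)
  expect_lt(length(det0$spikeTimes) / 20, 1)
  ## doublet 1 ms apart -> one detection under the 2 ms refractory
  vm <- rep(-50, 3000)
  vm[1000] <- -20; vm[1001] <- -22
  d <- detectSpikes(vm)
  expect_identical(length(d$spikeTimes), 1L)
})

test_that("noiseless injected IPSPs are all detected; distant
          derivative peaks are not events", {
  n <- 20000
  vm <- rep(-50, n)
  tau <- 15
  kern <- -1.5 * exp(-(0:120) / tau)
  at <- seq(1000, 19000, by = 950)
  for (i in at) vm[i:(i + 120)] <- vm[i:(i + 120)] + kern
  ev <- detectIpsps(vm)
  expect_identical(nrow(ev), length(at))
  expect_true(all(vapply((at - 1) / 1000, function(s)
    any(abs(ev$time - s) < 0.02), logical(1))))
  expect_true(all(diff(ev$time) >= 0.02))
  expect_true(all(ev$derivative_peak < 0))
})

test_that("IPSP detection keeps precision and recall above 0.9 at the
          stated noise", {
  syn <- synthVm(0, durationS = 60, tuningAmp = 0,
                 ipspRateLaw = "constant", ipspRate0 = 8,
                 ipspAmpRange = c(1, 1), noiseSd = 0.2, seed = 23L)
  ev <- detectIpsps(syn$vm@vm)
  tr <- syn$groundTruth$ipsp_times
  tolS <- 0.02
  recall <- mean(vapply(tr, function(s)
    any(abs(ev$time - s) < tolS), logical(1)))
  precision <- mean(vapply(ev$time, function(s)
    any(abs(tr - s) < tolS), logical(1)))
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
})

test_that("IPSP rate estimates track the true Poisson rate", {
  ## within 10% through the physiological 2-8 Hz range; at very high
  ## rates the 500 ms median detrending starts tracking the events
  ## themselves, shallowing individual deflections, and the estimate
  ## becomes a bounded systematic undercount
  for (r0 in c(2, 5, 8)) {
    syn <- synthVm(0, durationS = 60, tuningAmp = 0,
                   ipspRateLaw = "constant", ipspRate0 = r0,
                   ipspAmpRange = c(1, 1), noiseSd = 0.2,
                   seed = 24L + r0)
    ev <- detectIpsps(syn$vm@vm)
    trueRate <- length(syn$groundTruth$ipsp_times) / 60
    expect_lt(abs(nrow(ev) / 60 - trueRate) / trueRate, 0.1)
  }
  for (r0 in c(14, 20)) {
    syn <- synthVm(0, durationS = 60, tuningAmp = 0,
                   ipspRateLaw = "constant", ipspRate0 = r0,
                   ipspAmpRange = c(1, 1), noiseSd = 0.2,
                   seed = 24L + r0)
    ev <- detectIpsps(syn$vm@vm)
    tr <- syn$groundTruth$ipsp_times
    rel <- (nrow(ev) / 60 - length(tr) / 60) / (length(tr) / 60)
    expect_lt(rel, 0)  # strictly an undercount, never spurious events
    prec <- mean(vapply(ev$time, function(s)
      any(abs(tr - s) < 0.02), logical(1)))
    expect_gte(prec, 0.95)
  }
})

test_that("quiescence is required and respected", {
  vm <- rep(-50, 5000)
  expect_error(detectIpsps(vm, quiescentMask = rep(FALSE, 5000)),
               "quiescent")
})

test_that("cosine-tuned Vm yields theta_p in the right bin and the
          right amplitude", {
  set.seed(25)
  heading <- runif(20000, -180, 180)
  vm <- -50 + 5 * cos((heading - 40) * pi / 180)
  tn <- preferredDirectionTuning(vm, heading)
  expect_lt(abs(circDistDeg(tn$theta_p, 40)), 10 + 1e-9)
  expect_equal(tn$amplitude, 10, tolerance = 0.05)
  ## flat input: tiny amplitude, deterministic smallest-bin tie-break
  tf <- preferredDirectionTuning(rep(-50, 1000),
                                 runif(1000, -180, 180))
  expect_lt(tf$amplitude, 1e-9)
  expect_identical(tf$theta_p, -170)
  expect_warning(preferredDirectionTuning(1:5, rep(0, 5)), "coverage")
})

test_that("theta_p recovery within one bin holds for >= 95% of noisy
          cells at SNR 2", {
  set.seed(26)
  hit <- 0L
  for (i in 1:60) {
    thetaP <- runif(1, -180, 180)
    heading <- runif(4000, -180, 180)
    vm <- -50 + 2.5 * cos((heading - thetaP) * pi / 180) +
      rnorm(4000, sd = 1.25)
    tn <- preferredDirectionTuning(vm, heading)
    if (abs(circDistDeg(tn$theta_p, thetaP)) <= 20) hit <- hit + 1L
  }
  expect_gte(hit / 60, 0.95)
})

test_that("IPSP frequency drops when a jump moves heading away from
          theta_p", {
  ## heading steps between two values across jumps; rate follows
  ## r0 (1 + cos(theta - theta_p))
  fs <- 1000
  jumps <- data.frame(time = c(20, 40, 60), magnitude = c(90, 90, -90))
  heading <- rep(0, 80 * fs)
  time <- (seq_along(heading) - 1) / fs
  heading[time >= 20 & time < 40] <- 90
  heading[time >= 40 & time < 60] <- 180
  heading[time >= 60] <- 90
  syn <- synthVm(heading, thetaP = 0, tuningAmp = 4,
                 ipspRateLaw = "cosine", ipspRate0 = 10, noiseSd = 0.15,
                 seed = 27L)
  ev <- detectIpsps(syn$vm@vm)
  res <- ipspJumpResponse(ev$time, jumps, heading, fs, thetaP = 0)
  ## moving away from theta_p (positive d_abs_offset) lowers the rate
  expect_lt(res$slope, 0)
  expect_lt(res$r, -0.5)
  away <- res$table$d_abs_offset > 0
  expect_true(all(res$table$d_freq[away] < 0))
})

test_that("heading-independent IPSP rates give near-zero correlation", {
  fs <- 1000
  jumps <- data.frame(time = seq(15, 105, by = 15),
                      magnitude = rep(c(90, -90), 4)[1:7])
  heading <- rep(0, 120 * fs)
  time <- (seq_along(heading) - 1) / fs
  for (i in seq_len(nrow(jumps))) {
    heading[time >= jumps$time[i]] <-
      wrapDeg(heading[time >= jumps$time[i]][1] + jumps$magnitude[i])
  }
  syn <- synthVm(heading, thetaP = 0, tuningAmp = 0,
                 ipspRateLaw = "constant", ipspRate0 = 10,
                 noiseSd = 0.15, seed = 28L)
  ev <- detectIpsps(syn$vm@vm)
  res <- ipspJumpResponse(ev$time, jumps, heading, fs, thetaP = 0)
  expect_gt(res$p, 0.01)
})

test_that("goal-offset binning orders tuning amplitude as the model
          predicts and min-subtraction is exact arithmetic", {
  set.seed(29)
  mkSeg <- function(thetaG, thetaP, amp) {
    heading <- runif(3000, -180, 180)
    list(heading = heading,
         value = -50 + amp / 2 * cos((heading - thetaP) * pi / 180) +
           rnorm(3000, sd = 0.2),
         theta_g = thetaG, rho = 0.9)
  }
  ## amplitude largest when theta_p sits at the anti-goal
  cells <- lapply(seq(-150, 150, by = 60), function(tp) {
    ## tuning amplitude maximal for cells whose theta_p sits at the
    ## anti-goal (theta_g + 180; here theta_g = 0)
    amp <- 2 + 8 * (1 + cos((tp - 180) * pi / 180)) / 2
    list(theta_p = tp, cell_type = "PFL2",
         segments = list(mkSeg(0, tp, amp)))
  })
  tb <- tuningByGoalOffset(cells)
  ampPerOffset <- tapply(tb$mean, tb$offset_center, function(v)
    diff(range(v, na.rm = TRUE)))
  ## the winning offset bin is one of the two anti-goal bins (+/-144)
  expect_equal(abs(as.numeric(names(which.max(ampPerOffset)))), 144)
  ## flag arithmetic: raw curves differ from min-subtracted by each
  ## curve's minimum
  one <- list(list(theta_p = 0, cell_type = "PFL2",
                   segments = list(mkSeg(30, 0, 6))))
  on <- tuningByGoalOffset(one, minSubtract = TRUE)
  off <- tuningByGoalOffset(one, minSubtract = FALSE)
  expect_equal(on$mean, off$mean - min(off$mean, na.rm = TRUE),
               tolerance = 1e-9)
  ## low-rho segments are refused
  lowRho <- list(list(theta_p = 0, cell_type = "PFL2",
                      segments = list(modifyList(mkSeg(0, 0, 5),
                                                 list(rho = 0.5)))))
  expect_error(tuningByGoalOffset(lowRho), "usable")
})

test_that("PFL3L offsets are mirrored before pooling", {
  set.seed(30)
  heading <- runif(2000, -180, 180)
  seg <- list(heading = heading, value = cos((heading - 10) * pi / 180),
              theta_g = 60, rho = 0.95)
  right <- list(theta_p = 10, cell_type = "PFL3R", segments = list(seg))
  left <- list(theta_p = 10, cell_type = "PFL3L", segments = list(seg))
  tR <- tuningByGoalOffset(list(right))
  tL <- tuningByGoalOffset(list(left))
  expect_identical(unique(tR$offset_center), 72)   # offset +50 -> bin 72
  expect_identical(unique(tL$offset_center), -72)  # mirrored
})

test_that("Brown-Forsythe matches its closed form on a hand-computable
          example", {
  ## two groups; absolute deviations from group medians are easy to
  ## enumerate: x = (0,2,4,10), y = (1,1,1,1,7)
  x <- c(0, 2, 4, 10)
  y <- c(1, 1, 1, 1, 7)
  z <- c(abs(x - 3), abs(y - 1))
  g <- factor(rep(c("x", "y"), c(4, 5)))
  m <- tapply(z, g, mean)
  grand <- mean(z)
  ssb <- sum(tapply(z, g, length) * (m - grand)^2)
  ssw <- sum((z - m[g])^2)
  Fref <- (ssb / 1) / (ssw / 7)
  bf <- brownForsythe(c(x, y), g)
  expect_equal(bf$statistic, Fref, tolerance = 1e-12)
  expect_equal(bf$df1, 1)
  expect_equal(bf$df2, 7)
  ## cross-check against the independent car implementation
  lt <- car::leveneTest(c(x, y), g, center = median)
  expect_equal(bf$statistic, lt[1, "F value"], tolerance = 1e-12)
  expect_equal(bf$p.value, lt[1, "Pr(>F)"], tolerance = 1e-12)
  ## identical groups: statistic ~ 0
  same <- rep(c(1, 2, 3), 4)
  expect_lt(brownForsythe(c(same, same),
                          rep(c("a", "b"), each = 12))$statistic, 1e-20)
})

test_that("Brown-Forsythe type-I error is nominal and it detects a 4:1
          variance ratio", {
  set.seed(31)
  nRep <- 1000
  rej <- 0L
  for (i in seq_len(nRep)) {
    p <- brownForsythe(c(rnorm(15), rnorm(15)),
                       rep(c("a", "b"), each = 15))$p.value
    if (p < 0.05) rej <- rej + 1L
  }
  ## binomial 99% CI around 0.05 at 1000 reps
  expect_gt(rej / nRep, 0.05 - 2.58 * sqrt(0.05 * 0.95 / nRep))
  expect_lt(rej / nRep, 0.05 + 2.58 * sqrt(0.05 * 0.95 / nRep))
  pow <- mean(replicate(300, brownForsythe(
    c(rnorm(30, sd = 2), rnorm(30, sd = 1)),
    rep(c("a", "b"), each = 30))$p.value < 0.05))
  expect_gt(pow, 0.5)
})

test_that("jump-evoked dVm statistics split by class and compare
          variances", {
  fs <- 1000
  n <- 200 * fs
  set.seed(32)
  vm <- rnorm(n, -50, 0.05)
  jumps <- data.frame(time = seq(10, 190, by = 10))
  jumps$magnitude <- 90
  ## corrected/high-rho jumps get a real Vm transient, the others none
  cls <- rep(c(TRUE, FALSE), length.out = nrow(jumps))
  time <- (seq_len(n) - 1) / fs
  sgn <- 1
  for (i in which(cls)) {
    t0 <- jumps$time[i]
    sgn <- -sgn   # balanced signs: a variance effect, not a mean shift
    vm[time > t0 & time <= t0 + 1] <- vm[time > t0 & time <= t0 + 1] +
      sgn * 3
  }
  jumpTable <- data.frame(time = jumps$time, magnitude = 90,
                          pre_theta_mean = 0, pre_rho = 0.9,
                          corrected = cls, high_rho = cls,
                          excluded = FALSE, reason = "ok")
  res <- jumpDvmStats(vm, fs, jumpTable)
  v <- tapply(res$table$d_vm, res$table$group, var)
  expect_gt(v[["corrected_high_rho"]], v[["uncorrected_low_rho"]])
  expect_lt(res$p.value, 0.01)
  expect_error(jumpDvmStats(vm, fs, jumpTable[1:2, ]), ">= 2")
})

test_that("Vm leading speed by 300 ms peaks the lag correlation at a
          positive lag", {
  fs <- 100
  n <- 400 * fs
  set.seed(33)
  drive <- stats::filter(rnorm(n), rep(1, 50), sides = 2, circular = TRUE)
  drive <- as.numeric(drive) / sd(drive, na.rm = TRUE)
  lead <- round(0.3 * fs)
  ## Vm deflects first; rotational speed follows 300 ms later
  vm <- -50 + drive
  speed <- 20 + 5 * abs(c(rep(drive[1], lead), drive[1:(n - lead)]))
  jumps <- data.frame(time = seq(20, 380, by = 20), magnitude = 90)
  jumpTable <- data.frame(time = jumps$time, magnitude = 90,
                          pre_theta_mean = 0, pre_rho = 0.9,
                          corrected = TRUE, high_rho = TRUE,
                          excluded = FALSE, reason = "ok")
  lc <- dvmSpeedLagCorrelation(vm, speed, fs, jumpTable)
  expect_identical(nrow(lc), 201L)
  expect_identical(range(lc$lag_s), c(-1, 1))
  pk <- lc$lag_s[which.max(lc$mean_r)]
  expect_gt(pk, 0.1)
  expect_lt(abs(pk - 0.3), 0.15)
  ## independent Vm and speed: flat, near-zero profile
  lc0 <- dvmSpeedLagCorrelation(rnorm(n, -50, 0.5), speed, fs, jumpTable)
  expect_lt(max(abs(lc0$mean_r)), 0.2)
})
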