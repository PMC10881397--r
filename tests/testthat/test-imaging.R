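## z-scoring, phase-heading coupling, neural goal inference, LAL
## readouts and error-binned profiles.

test_that("z-scored dF/F has median 0 and MAD 1 per ROI", {
  set.seed(4)
  vals <- matrix(rexp(10 * 400, rate = 0.02) + 20, nrow = 10)
  roi <- roiTimeSeries(vals, "PB", frameRate = 7)
  roi <- zscoreDff(roi)
  z <- roiValues(roi, "zscored")
  for (i in 1:10) {
    expect_equal(median(z[i, ]), 0, tolerance = 1e-12)
    expect_equal(median(abs(z[i, ])), 1, tolerance = 1e-12)
  }
  ## dF/F uses the bottom-decile mean as F0
  d <- roiValues(roi, "dff")
  v <- vals[1, ]
  f0 <- mean(sort(v)[1:40])
  expect_equal(d[1, ], (v - f0) / f0, tolerance = 1e-12)
})

test_that("the worked z-score example holds: trace 1,2,3,4,100", {
  x <- c(1, 2, 3, 4, 100)
  md <- median(x)
  madRaw <- median(abs(x - md))
  expect_equal(madRaw, 1)
  expect_equal((x[5] - md) / madRaw, 97)
})

test_that("adding a constant to raw F changes dF/F but not the z MAD", {
  set.seed(5)
  vals <- matrix(rexp(9 * 300, 0.05) + 30, nrow = 9)
  a <- zscoreDff(roiTimeSeries(vals, "FB", 7))
  b <- zscoreDff(roiTimeSeries(vals + 50, "FB", 7))
  expect_false(isTRUE(all.equal(roiValues(a, "dff"), roiValues(b, "dff"))))
  for (i in 1:9) {
    expect_equal(median(abs(roiValues(b, "zscored")[i, ])), 1,
                 tolerance = 1e-12)
  }
})

test_that("constant-fluorescence ROIs are flagged, bad baselines error", {
  vals <- matrix(rexp(10 * 100, 0.05) + 30, nrow = 10)
  vals[3, ] <- 42
  expect_warning(out <- zscoreDff(roiTimeSeries(vals, "PB", 7)), "ROI 3")
  expect_true(all(is.na(roiValues(out, "zscored")[3, ])))
  neg <- matrix(-1, nrow = 10, ncol = 50)
  expect_error(zscoreDff(roiTimeSeries(neg, "PB", 7)), "baseline")
})

test_that("bump phase moving exactly opposite heading gives r = -1,
          slope = -1", {
  fs <- 10
  n <- 600
  set.seed(6)
  heading <- cumsum(rnorm(n, sd = 2))      # slow drift, no wrap issues
  phase <- wrapDeg(40 - heading)
  ok <- rep(TRUE, n)
  cp <- phaseHeadingCoupling(phase, wrapDeg(heading), ok, ok, fs,
                             lagMs = 0)
  expect_equal(cp$r, -1, tolerance = 1e-9)
  expect_equal(cp$slope, -1, tolerance = 1e-9)
  ## phase independent of heading: negligible correlation
  cp0 <- phaseHeadingCoupling(wrapDeg(cumsum(rnorm(n, sd = 2))),
                              wrapDeg(heading), ok, ok, fs, lagMs = 0)
  expect_lt(abs(cp0$r), 0.3)
  expect_gt(cp0$p, 0.001)
})

test_that("a built-in 200 ms bump-phase delay is recovered by the lag
          sweep", {
  fs <- 20
  n <- 2400
  set.seed(7)
  heading <- cumsum(rnorm(n, sd = 3))
  lagN <- round(0.2 * fs)
  phase <- wrapDeg(-c(rep(heading[1], lagN), heading[1:(n - lagN)]))
  ok <- rep(TRUE, n)
  rs <- vapply(c(0, 100, 200, 300, 400), function(lag) {
    phaseHeadingCoupling(phase, wrapDeg(heading), ok, ok, fs,
                         lagMs = lag)$r
  }, numeric(1))
  expect_identical(which.min(rs), 3L)  # |r| max (r most negative) at 200
})

test_that("goal inference finds the amplitude minimum", {
  set.seed(8)
  heading <- runif(4000, -180, 180)
  amp <- 1 - cos((heading - 30) * pi / 180)
  g <- inferGoalFromAmplitude(amp, heading)
  expect_lt(abs(circDistDeg(g$theta_g, 30)), 5.01)
  expect_equal(g$amp_range, 2, tolerance = 0.05)
  expect_true(g$reliable)
  ## constant amplitude: unreliable, range ~ 0
  gc <- inferGoalFromAmplitude(rep(1, 4000), heading)
  expect_false(gc$reliable)
  expect_lt(gc$amp_range, 1e-9)
  ## single-direction coverage: no opposing pairs
  expect_error(inferGoalFromAmplitude(rep(1, 50), rep(10, 50)),
               "opposing")
})

test_that("synthetic PFL2 trials recover the goal end-to-end", {
  spec <- synthTrialSpec(duration = 600, mode = "scripted",
                         reversionRate = 0.4, headingNoiseSd = 60,
                         goalSchedule = data.frame(start_s = 0,
                                                   theta_g = -120),
                         seed = 12L)
  beh <- synthBehavior(spec)
  syn <- synthCalcium(beh$kinematics@heading, 60, thetaG = -120,
                      amplitudeLaw = "pfl2", noiseSd = 0.15, seed = 13L)
  fits <- fitBumpSeries(roiValues(syn$roi, "zscored"))
  hF <- syn$groundTruth$heading
  g <- inferGoalFromAmplitude(fits$amplitude, hF)
  expect_lt(abs(circDistDeg(g$theta_g, -120)), 10)
  expect_lt(abs(g$amp_range - syn$groundTruth$amp_range) /
              syn$groundTruth$amp_range, 0.15)
})

test_that("error-binned profiles have the largest amplitude at the
          anti-goal and are flat for heading-independent signals", {
  spec <- synthTrialSpec(duration = 240, mode = "scripted",
                         reversionRate = 0.3, headingNoiseSd = 70,
                         seed = 14L)
  beh <- synthBehavior(spec)
  syn <- synthCalcium(beh$kinematics@heading, 60, thetaG = 0,
                      amplitudeLaw = "pfl2", noiseSd = 0.1, seed = 15L)
  prof <- errorBinnedProfiles(syn$roi, syn$groundTruth$heading, 0)
  ampOf <- function(col) fitBump(prof[[col]])$amplitude
  amps <- vapply(c("err_-180", "err_-90", "err_0", "err_90"), ampOf,
                 numeric(1))
  expect_identical(unname(which.max(amps)), 1L)  # anti-goal bin
  ## heading-independent signal: four near-identical profiles
  syn2 <- synthCalcium(beh$kinematics@heading, 60, thetaG = 0,
                       amplitudeLaw = "constant", phaseOffset = 55,
                       noiseSd = 0, seed = 16L)
  z <- roiValues(syn2$roi, "zscored")
  z[] <- rep(rowMeans(z), ncol(z))  # freeze the profile in time
  SummarizedExperiment::assay(syn2$roi, "zscored") <- z
  prof2 <- errorBinnedProfiles(syn2$roi, syn2$groundTruth$heading, 0)
  cols <- grep("^err_", names(prof2))
  rng <- apply(prof2[cols], 1, function(v) diff(range(v)))
  expect_lt(max(rng), 1e-9)
  ## single-bin occupancy: one profile, three missing
  syn3 <- synthCalcium(rep(5, 600), 60, thetaG = 0, noiseSd = 0,
                       seed = 17L)
  prof3 <- errorBinnedProfiles(syn3$roi, rep(5, length(frameTimes(syn3$roi))), 0)
  isNA <- vapply(prof3[grep("^err_", names(prof3))],
                 function(v) all(is.na(v)), logical(1))
  expect_identical(sum(!isNA), 1L)
})

test_that("LAL sum/difference readouts follow the model curves", {
  p <- modelParams(duration = 1, noiseSd = 0)
  set.seed(18)
  heading <- runif(3000, -180, 180)
  lal <- synthLalFromModel(p, heading, 60, thetaG = 0, what = "pfl3")
  err <- circDistDeg(lal$groundTruth$heading, 0)
  out <- lalSumAndDiff(lal$roi, err, kind = "error")
  d <- out$diff
  ## difference (R - L) crosses zero at the goal and anti-goal
  at <- function(b, c0) b$mean[b$bin_center == c0]
  expect_lt(abs(at(d, 5)) + abs(at(d, -175)),
            0.25 * max(abs(d$mean), na.rm = TRUE))
  ## and is antisymmetric-ish: opposite signs at +/-90
  expect_lt(at(d, -95) * at(d, 95), 0)
  ## PFL2-style sum peaks near the anti-goal
  lal2 <- synthLalFromModel(p, heading, 60, thetaG = 0, what = "pfl2")
  s2 <- lalSumAndDiff(lal2$roi, err, kind = "error")$sum
  pk <- s2$bin_center[which.max(s2$mean)]
  expect_gt(abs(pk), 160)
  ## region guard
  expect_error(lalSumAndDiff(synthCalcium(heading, 60, 0)$roi, err),
               "LAL")
})
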