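## Kinematics preprocessing, sliding goal/consistency, segmentation and
## jump classification.

makeRaw <- function(n, rate, fwd = 0, yawRadS = 0) {
  t <- (0:(n - 1)) / rate
  data.frame(time_s = t,
             forward_rad = (fwd * t) %% (2 * pi),
             sideways_rad = rep(0, n),
             yaw_rad = (yawRadS * t) %% (2 * pi))
}

test_that("constant ball position gives zero velocities", {
  k <- preprocessKinematics(makeRaw(600, 300), sampleRate = 300)
  expect_lt(max(abs(k@forward)), 1e-9)
  expect_lt(max(abs(k@rotational)), 1e-9)
  expect_true(all(!k@mobile))
})

test_that("a 1 rad/s yaw ramp converts to 57.296 deg/s", {
  ## a wide-open filter isolates the unit conversion from edge effects
  k <- preprocessKinematics(makeRaw(1200, 300, yawRadS = 1),
                            sampleRate = 300, butterCorner = 0.9)
  mid <- seq(100, length(k@rotational) - 100)
  expect_equal(median(k@rotational[mid]), 180 / pi, tolerance = 1e-3)
  ## translation conversion via the 4.5 mm ball radius
  k2 <- preprocessKinematics(makeRaw(1200, 300, fwd = 1),
                             sampleRate = 300, butterCorner = 0.9)
  expect_equal(median(k2@forward[mid]), 4.5, tolerance = 1e-2)
})

test_that("artefactual velocity spikes are clipped at 20 rad/s", {
  raw <- makeRaw(1200, 300, yawRadS = 0.5)
  ## inject a single-sample position glitch worth ~100 rad/s
  raw$yaw_rad[600] <- raw$yaw_rad[600] + 100 / 300
  k <- preprocessKinematics(raw, sampleRate = 300)
  ## after clipping (pre-smoothing) no resampled value can exceed the cap
  expect_lte(max(abs(k@rotational)) * pi / 180, 20 + 1e-6)
})

test_that("preprocessing rejects malformed input", {
  raw <- makeRaw(100, 300)
  raw$time_s[5] <- raw$time_s[7]
  expect_error(preprocessKinematics(raw, 300), "increasing")
  expect_error(preprocessKinematics(makeRaw(10, 300), 300), "too short")
  expect_error(preprocessKinematics(makeRaw(100, 300)[, 1:3], 300),
               "must contain")
})

test_that("cue azimuth converts to heading with the stated convention", {
  expect_equal(cueToHeading(rep(0, 10), smoothN = 1), rep(0, 10))
  ## fly 90 deg clockwise of the cue: cue sits 90 deg to its left
  expect_equal(cueToHeading(rep(-90, 10), smoothN = 1), rep(90, 10))
  ## clamping, not wrapping, at +/-180 by default
  expect_equal(cueToHeading(rep(-200, 10), smoothN = 1), rep(180, 10))
  expect_equal(cueToHeading(rep(-200, 10), smoothN = 1, wrap = TRUE),
               rep(-160, 10))
  ## closed-loop gain: 100 deg of ball yaw moves the cue 70 deg
  expect_equal(closedLoopCue(100), 70)
  expect_error(closedLoopCue(100, yawGain = 0), "> 0")
})

test_that("sliding goal/consistency matches the limiting cases", {
  fs <- 60
  n <- 90 * fs
  mobileSpeed <- rep(2, n)
  gw <- slidingGoalConsistency(rep(25, n), mobileSpeed, fs)
  expect_true(all(abs(gw$rho - 1) < 1e-9))
  expect_true(all(abs(gw$theta_g - 25) < 1e-6))
  ## immobile trial: everything missing
  gw0 <- slidingGoalConsistency(rep(25, n), rep(0, n), fs)
  expect_true(all(is.na(gw0$rho)))
  ## uniform sweep: rho ~ 0 in the interior of full windows
  sweep <- wrapDeg(seq(0, by = 360 / (30 * fs), length.out = n))
  gws <- slidingGoalConsistency(sweep, mobileSpeed, fs)
  inner <- seq(16 * fs, n - 16 * fs)
  expect_lt(max(gws$rho[inner]), 0.01)
})

test_that("samples within 5 s after a jump are excluded from windows", {
  fs <- 60
  n <- 60 * fs
  heading <- rep(0, n)
  time <- (seq_len(n) - 1) / fs
  ## a wild post-jump excursion that would wreck rho if included
  heading[time >= 30 & time < 35] <- 180
  gw <- slidingGoalConsistency(heading, rep(2, n), fs, jumpTimes = 30)
  expect_true(all(gw$rho > 0.999))
})

test_that("segmentation recovers a clean two-goal trajectory", {
  fs <- 60
  spec <- synthTrialSpec(
    duration = 240, jumpPeriodS = 1e6,
    goalSchedule = data.frame(start_s = c(0, 120), theta_g = c(-30, 90)),
    mode = "scripted", reversionRate = 2, headingNoiseSd = 12,
    seed = 8L)
  beh <- synthBehavior(spec)
  k <- beh$kinematics
  gw <- slidingGoalConsistency(k@heading, k@cumulativeSpeed, fs)
  segs <- segmentPath(gw$rho, k@heading, k@cumulativeSpeed, fs)
  segs <- segs[segs$valid & segs$n_samples > 30 * fs, ]
  expect_identical(nrow(segs), 2L)
  expect_lt(abs(circDistDeg(segs$theta_g[1], -30)), 5)
  expect_lt(abs(circDistDeg(segs$theta_g[2], 90)), 5)

  ## threshold robustness: recovered goals move < 5 deg across the
  ## whole plausible rho-threshold range
  for (th in c(0.70, 0.80, 0.95, 0.98)) {
    s2 <- segmentPath(gw$rho, k@heading, k@cumulativeSpeed, fs,
                      rhoThresh = th)
    s2 <- s2[s2$valid & s2$n_samples > 30 * fs, ]
    expect_identical(nrow(s2), 2L)
    expect_lt(max(abs(circDistDeg(s2$theta_g, segs$theta_g))), 5)
  }

  ## global rotation shifts goals and changes nothing else
  rot <- wrapDeg(k@heading + 77)
  gwr <- slidingGoalConsistency(rot, k@cumulativeSpeed, fs)
  sr <- segmentPath(gwr$rho, rot, k@cumulativeSpeed, fs)
  sr <- sr[sr$valid & sr$n_samples > 30 * fs, ]
  expect_identical(sr$start_idx, segs$start_idx)
  expect_lt(max(abs(circDistDeg(sr$theta_g, segs$theta_g + 77))), 1e-6)
})

test_that("segments with rho exactly 1 are discarded as frozen-cue", {
  fs <- 60
  n <- 100 * fs
  segs <- segmentPath(rep(1, n), rep(12, n), rep(2, n), fs)
  expect_identical(sum(segs$valid), 0L)
  expect_true(all(segs$reason == "rho_equal_1"))
})

test_that("brief rho dips are lumped, long dips split", {
  fs <- 60
  n <- 120 * fs
  rho <- rep(0.95, n)
  heading <- rep(0, n)
  speed <- rep(2, n)
  rho[seq(60 * fs, 60 * fs + 0.3 * fs)] <- 0.5   # 0.3 s dip
  expect_identical(sum(segmentPath(rho, heading, speed, fs)$valid), 1L)
  rho[seq(60 * fs, 60 * fs + 2 * fs)] <- 0.5     # 2 s dip
  expect_identical(sum(segmentPath(rho, heading, speed, fs)$valid), 2L)
})

test_that("jump classification follows the return-tolerance rules", {
  fs <- 60
  n <- 60 * fs
  time <- (seq_len(n) - 1) / fs
  speed <- rep(2, n)
  rho <- rep(0.95, n)
  ## scripted 90-deg jump at t = 30 returning to within 10 deg at +6 s
  h <- rep(0, n)
  h[time >= 30 & time < 36] <- 90
  h[time >= 36] <- 8
  jt <- classifyJump(h, rho, speed, fs,
                     data.frame(time = 30, magnitude = 90))
  expect_false(jt$excluded)
  expect_true(jt$corrected)
  expect_true(jt$high_rho)
  expect_lt(abs(jt$pre_theta_mean), 1e-9)
  ## 180-deg jump that never returns
  h2 <- ifelse(time >= 30, 180, 0)
  jt2 <- classifyJump(h2, rho, speed, fs,
                      data.frame(time = 30, magnitude = 180))
  expect_false(jt2$corrected)
  ## heading settling 50 deg away counts for 180 jumps (tol 60), not
  ## for 90 jumps (tol 30)
  h3 <- rep(0, n); h3[time >= 30] <- 50
  expect_true(classifyJump(h3, rho, speed, fs,
                           data.frame(time = 30, magnitude = 180))$corrected)
  expect_false(classifyJump(h3, rho, speed, fs,
                            data.frame(time = 30, magnitude = 90))$corrected)
  ## immobile fly: excluded
  jt4 <- classifyJump(h, rho, rep(0.1, n), fs,
                      data.frame(time = 30, magnitude = 90))
  expect_true(jt4$excluded)
  expect_identical(jt4$reason, "immobile_pre")
  expect_true(is.na(jt4$corrected))
  ## too close to the trace edge: excluded with reason
  jt5 <- classifyJump(h, rho, speed, fs,
                      data.frame(time = 5, magnitude = 90))
  expect_identical(jt5$reason, "insufficient_data")
  ## fast criterion: return at +6 s no longer counts
  jt6 <- classifyJump(h, rho, speed, fs,
                      data.frame(time = 30, magnitude = 90),
                      criterion = "fast")
  expect_false(jt6$corrected)
})

test_that("model-driven flies correct jumps when steering is on", {
  spec <- synthTrialSpec(duration = 300, mode = "model", S = 0.8,
                         seed = 3L)
  beh <- synthBehavior(spec)
  k <- beh$kinematics
  gw <- slidingGoalConsistency(k@heading, k@cumulativeSpeed,
                               k@sampleRate,
                               jumpTimes = spec$jumpTimes)
  jt <- classifyJump(k@heading, gw$rho, k@cumulativeSpeed, k@sampleRate,
                     data.frame(time = spec$jumpTimes,
                                magnitude = spec$jumpMagnitudes))
  ok <- !jt$excluded
  expect_gte(mean(jt$corrected[ok]), 0.8)

  spec0 <- synthTrialSpec(duration = 300, mode = "model", S = 0,
                          seed = 3L)
  beh0 <- synthBehavior(spec0)
  k0 <- beh0$kinematics
  gw0 <- slidingGoalConsistency(k0@heading, k0@cumulativeSpeed,
                                k0@sampleRate,
                                jumpTimes = spec0$jumpTimes)
  jt0 <- classifyJump(k0@heading, gw0$rho, k0@cumulativeSpeed,
                      k0@sampleRate,
                      data.frame(time = spec0$jumpTimes,
                                 magnitude = spec0$jumpMagnitudes))
  ok0 <- !jt0$excluded
  expect_lte(mean(jt0$corrected[ok0]), 0.2)
})
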