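mkTraj <- function(t, x, y) data.frame(t_s = t, x_mm = x, y_mm = y)

test_that("trajectory low-pass passes DC and low frequencies, kills 28 Hz", {
  fs <- 60
  t <- seq(0, 10, by = 1 / fs)
  # constant position unchanged
  traj <- lowpassTrajectory(mkTraj(t, rep(3, length(t)), rep(7, length(t))))
  expect_lt(max(abs(traj$x_mm - 3)), 1e-9)
  expect_lt(max(abs(traj$y_mm - 7)), 1e-9)
  # 2 Hz attenuation < 1%
  i <- 150:450
  traj2 <- lowpassTrajectory(mkTraj(t, sin(2 * pi * 2 * t), rep(0, length(t))))
  expect_gt((max(traj2$x_mm[i]) - min(traj2$x_mm[i])) / 2, 0.99)
  # 28 Hz attenuation > 75% (cutoff ratio 1.4, squared by the two passes)
  traj3 <- lowpassTrajectory(mkTraj(t, sin(2 * pi * 28 * t), rep(0, length(t))))
  expect_lt(max(abs(traj3$x_mm[i])), 0.25)
})

test_that("finite-difference velocity matches linear and bell profiles", {
  fs <- 60
  t <- seq(0, 1, by = 1 / fs)
  expect_equal(computeVelocity(mkTraj(t, t * 0, 100 * t)),
               rep(100, length(t)), tolerance = 1e-9)
  expect_equal(computeVelocity(mkTraj(t, t * 0, rep(5, length(t)))),
               rep(0, length(t)))
  expect_error(computeVelocity(mkTraj(0, 0, 0)), "2 samples")
  # minimum-jerk peak velocity: closed form 1.875 D / T
  D <- 100; Tm <- 0.4
  tau <- pmin(pmax((t - 0.2) / Tm, 0), 1)
  y <- D * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  v <- computeVelocity(mkTraj(t, t * 0, y))
  expect_equal(max(v), 1.875 * D / Tm, tolerance = 0.02)
})

test_that("RT and MT follow the 20 mm/s threshold rule", {
  fs <- 60
  t <- seq(0, 2, by = 1 / fs)
  # constructed crossing exactly 0.3 s after go
  v <- ifelse(t > 0.8, 100, 0)
  expect_lt(abs(reactionTime(v, t, tGo = 0.5) - 0.3), 1 / 60 + 1e-9)
  expect_true(is.na(reactionTime(rep(0, length(t)), t, tGo = 0.5)))
  expect_error(reactionTime(v, t, tGo = 5), "outside")
  # rectangular pulse of 0.5 s
  v2 <- ifelse(t >= 0.5 & t < 1.0, 100, 0)
  expect_lt(abs(movementTime(v2, t) - 0.5), 1 / 60 + 1e-9)
  expect_true(is.na(movementTime(rep(0, length(t)), t)))
  # random min-jerk trials: equals an exhaustive scan oracle
  set.seed(61)
  for (i in 1:120) {
    tGo <- runif(1, 0.2, 0.6)
    rt0 <- runif(1, 0.15, 0.5)
    Tm <- runif(1, 0.25, 0.5)
    tau <- pmin(pmax((t - tGo - rt0) / Tm, 0), 1)
    y <- 100 * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
    v <- computeVelocity(mkTraj(t, t * 0, y))
    # oracle: scan every sample
    idx <- which(t >= tGo & v > 20)
    expRT <- if (length(idx)) t[idx[1]] - tGo else NA_real_
    expect_identical(reactionTime(v, t, tGo), expRT)
    pk <- which.max(v)
    runs <- rle(v > 20)
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
    hit <- which(runs$values & starts <= pk & ends >= pk)
    expMT <- (ends[hit] - starts[hit] + 1L) / fs
    expect_equal(movementTime(v, t), expMT, tolerance = 1e-12)
  }
})

test_that("hand angle at peak y-velocity recovers the reach direction", {
  fs <- 60
  t <- seq(0, 1.5, by = 1 / fs)
  mj <- function(dirDeg, tOn = 0.4, Tm = 0.3, D = 100) {
    tau <- pmin(pmax((t - tOn) / Tm, 0), 1)
    s <- D * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
    a <- dirDeg * pi / 180
    mkTraj(t, -sin(a) * s, cos(a) * s)
  }
  # straight reach along the target direction
  expect_lt(abs(computeHandAngle(mj(5), targetAngle = 5)), 1e-9)
  # deviation of +5 deg (counterclockwise) is -5 in the compensatory sign
  expect_equal(computeHandAngle(mj(10), targetAngle = 5), -5,
               tolerance = 0.1)
  # random trials: the straight-line reach direction is the oracle
  set.seed(71)
  for (i in 1:50) {
    tgt <- runif(1, -10, 10); dev <- runif(1, -20, 20)
    traj <- lowpassTrajectory(mj(tgt - dev))
    expect_equal(computeHandAngle(traj, tgt), dev, tolerance = 0.2)
  }
  # invariance under a global rotation of target and trajectory
  tr0 <- mj(3); h0 <- computeHandAngle(tr0, 8)
  rot <- 25 * pi / 180
  trR <- mkTraj(t, cos(rot) * tr0$x_mm - sin(rot) * tr0$y_mm,
                sin(rot) * tr0$x_mm + cos(rot) * tr0$y_mm)
  # rotating by +25 deg CCW shifts the direction angle by +25
  expect_equal(computeHandAngle(trR, 8 + 25), h0, tolerance = 1e-6)
  expect_error(computeHandAngle(mkTraj(t, t * 0, t * 0), 0), "undefined")
})

test_that("RT and MT are invariant under translating the trajectory", {
  fs <- 60
  t <- seq(0, 1.5, by = 1 / fs)
  tau <- pmin(pmax((t - 0.5) / 0.3, 0), 1)
  y <- 100 * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  v1 <- computeVelocity(mkTraj(t, t * 0, y))
  v2 <- computeVelocity(mkTraj(t, t * 0 + 55, y + 31))
  expect_equal(reactionTime(v1, t, 0.4), reactionTime(v2, t, 0.4))
  expect_equal(movementTime(v1, t), movementTime(v2, t))
})

test_that("outlier rule flags a gross spike and nothing in clean noise", {
  expect_equal(flagOutliers(numeric(0)), logical(0))
  expect_true(!any(flagOutliers(rep(2, 50))))
  set.seed(81)
  x <- rnorm(120)
  x[60] <- 50
  fl <- flagOutliers(x)
  expect_equal(which(fl), 60L)
  # direct recomputation of the windowed statistics
  s <- sd(x)
  dev <- vapply(seq_along(x), function(t) {
    w <- x[max(1, t - 2):min(length(x), t + 2)]
    abs(x[t] - mean(w))
  }, 0)
  expect_equal(fl, dev > 3 * s)
  # flags computed once: removing the flagged trial does not re-flag others
  expect_true(!any(flagOutliers(x[-60])))
})

test_that("full-dataset kinematics excludes exactly the injected outliers", {
  d <- makeDesign(8, seed = 1)
  beh <- simulateBehavior(d, seed = 1)
  kin <- computeKinematics(beh$trials, beh$trajectories)
  expect_equal(nrow(kin), 2880)
  expect_equal(sum(kin$excluded), 2)
  expect_equal(sum(kin$exclude_reason == "outlier"), 2)
  inj <- beh$trials[beh$trials$outlier_injected, ]
  flg <- kin[kin$excluded, ]
  expect_setequal(paste(flg$subject, flg$task, flg$trial),
                  paste(inj$subject, inj$task, inj$trial))
  # estimated hand angles track the generative ones closely
  ord <- order(beh$trials$subject, beh$trials$task, beh$trials$trial)
  expect_lt(max(abs(kin$hand_angle_deg -
                    beh$trials$hand_angle_true_deg[ord]), na.rm = TRUE),
            0.01)
})
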