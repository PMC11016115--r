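test_that("rotation schedule ramps at 0.2 deg/trial to the 20 deg ceiling", {
  sched <- buildRotationSchedule()
  expect_equal(nrow(sched), 180)
  expect_true(all(sched$rotation_deg[sched$phase != "adaptation"] == 0))
  ad <- sched$rotation_deg[sched$phase == "adaptation"]
  expect_equal(length(ad), 120)
  expect_true(all(diff(ad) >= 0))
  expect_equal(which(ad == 20)[1], 101)
  expect_equal(sum(ad[102:120] == 20), 19)
  expect_equal(ad[1], 0)
  expect_true(all(buildRotationSchedule(increment = 0)$rotation_deg == 0))
  expect_error(buildRotationSchedule(nAdapt = -1), "non-negative")
})

test_that("forward simulation follows the state-space recursion exactly", {
  # full one-trial correction
  expect_equal(simulateStateSpace(c(10, 10, 10), A = 1, B = 1), c(0, 10, 10))
  # no learning
  expect_equal(simulateStateSpace(rep(5, 10), A = 1, B = 0, x1 = 2),
               rep(2, 10))
  # fixed point under constant rotation: B r / (1 - A + B)
  x <- simulateStateSpace(rep(20, 600), A = 0.9, B = 0.3)
  expect_equal(tail(x, 1), 0.3 * 20 / (1 - 0.9 + 0.3), tolerance = 1e-10)
  # noiseless residuals are zero at machine precision for random params
  set.seed(11)
  for (i in 1:20) {
    A <- runif(1); B <- runif(1); x1 <- runif(1, -5, 5)
    r <- runif(60, -20, 20)
    x <- simulateStateSpace(r, A, B, x1)
    resid <- x[-1] - (A * x[-60] + B * (r[-60] - x[-60]))
    expect_lt(max(abs(resid)), 1e-12)
  }
  # boundedness: 0 <= A, B <= 1, constant rotation
  for (i in 1:20) {
    A <- runif(1); B <- runif(1); r0 <- runif(1, -30, 30)
    x1 <- runif(1, -30, 30)
    x <- simulateStateSpace(rep(r0, 200), A, B, x1)
    expect_lte(max(abs(x)), max(abs(x1), abs(r0)) + 1e-9)
  }
  # seeded noise is reproducible
  expect_identical(simulateStateSpace(rep(5, 50), 0.9, 0.2, noiseSd = 1,
                                      seed = 4),
                   simulateStateSpace(rep(5, 50), 0.9, 0.2, noiseSd = 1,
                                      seed = 4))
})

test_that("regression estimation recovers the generating parameters", {
  r <- pmin(0.2 * (0:119), 20)
  x <- simulateStateSpace(r, A = 0.9, B = 0.3)
  fit <- estimateStateSpace(x, r)
  expect_lt(abs(fit@A - 0.9), 1e-8)
  expect_lt(abs(fit@B - 0.3), 1e-8)
  expect_equal(fit@R2, 1, tolerance = 1e-10)
  expect_equal(fit@nPairs, 119L)
  # estimate o simulate is the identity on (A, B) for noiseless inputs
  set.seed(21)
  for (i in 1:10) {
    A <- runif(1, 0.5, 0.99); B <- runif(1, 0.05, 0.5)
    xi <- simulateStateSpace(r, A, B, x1 = runif(1, -2, 2))
    f <- estimateStateSpace(xi, r)
    expect_lt(abs(f@A - A), 1e-7)
    expect_lt(abs(f@B - B), 1e-7)
  }
})

test_that("estimated coefficients equal the normal-equation solution", {
  set.seed(31)
  r <- pmin(0.2 * (0:119), 20)
  for (i in 1:10) {
    x <- simulateStateSpace(r, 0.9, 0.3, noiseSd = 1.5, seed = 100 + i)
    fit <- estimateStateSpace(x, r)
    ne <- normalEquationAB(x, r)
    expect_equal(fit@A, unname(ne["A"]), tolerance = 1e-10)
    expect_equal(fit@B, unname(ne["B"]), tolerance = 1e-10)
  }
})

test_that("estimation is equivariant under angle rescaling", {
  r <- pmin(0.2 * (0:119), 20)
  x <- simulateStateSpace(r, 0.85, 0.25, noiseSd = 1, seed = 9)
  f1 <- estimateStateSpace(x, r)
  f2 <- estimateStateSpace(3.7 * x, 3.7 * r)
  expect_equal(f1@A, f2@A, tolerance = 1e-10)
  expect_equal(f1@B, f2@B, tolerance = 1e-10)
})

test_that("excluded trials are dropped pairwise without biasing the fit", {
  r <- pmin(0.2 * (0:119), 20)
  x <- simulateStateSpace(r, 0.9, 0.3)
  excl <- rep(FALSE, 120); excl[c(40, 85)] <- TRUE
  fit <- estimateStateSpace(x, r, excluded = excl)
  # both pairs touching an excluded trial are dropped
  expect_equal(fit@nPairs, 119L - 4L)
  expect_lt(abs(fit@A - 0.9), 1e-8)
  expect_lt(abs(fit@B - 0.3), 1e-8)
})

test_that("degenerate series are reported as unidentifiable", {
  r <- rep(0, 50)
  expect_error(estimateStateSpace(rep(0, 50), r), "unidentifiable")
  expect_error(estimateStateSpace(c(1, 2), c(0, 0)), "at least 3")
})

test_that("parameter recovery is unbiased under motor noise (small MC)", {
  r <- pmin(0.2 * (0:119), 20)
  fits <- t(vapply(1:60, function(i) {
    x <- simulateStateSpace(r, 0.9, 0.3, noiseSd = 1, seed = 2000 + i)
    f <- estimateStateSpace(x, r)
    c(f@A, f@B)
  }, numeric(2)))
  expect_lt(abs(mean(fits[, 1]) - 0.9), 0.05)
  expect_lt(abs(mean(fits[, 2]) - 0.3), 0.05)
})

test_that("block metrics summarize only usable trials", {
  sched <- buildRotationSchedule()
  base <- data.frame(trial = sched$trial,
                     block = (sched$trial - 1) %/% 30 + 1,
                     phase = sched$phase, rt_s = 0.3, mt_s = 0.3,
                     excluded = FALSE)
  # perfect adaptation: x_t = r_t -> zero absolute error everywhere
  kin <- cbind(base, hand_angle_deg = sched$rotation_deg)
  met <- adaptationMetrics(kin, sched)
  expect_equal(met$blocks$mean_abs_error_deg,
               rep(0, 6), tolerance = 1e-12)
  # immobile learner: zero aftereffect and zero block means
  kin0 <- cbind(base, hand_angle_deg = 0)
  met0 <- adaptationMetrics(kin0, sched)
  expect_equal(met0$aftereffect_deg, 0)
  expect_equal(met0$blocks$mean_hand_angle_deg, rep(0, 6))
  # block means equal an independent group-by aggregation
  set.seed(41)
  kinr <- cbind(base, hand_angle_deg = rnorm(180, 5, 3))
  kinr$excluded[c(10, 100)] <- TRUE
  metr <- adaptationMetrics(kinr, sched)
  use <- kinr[!kinr$excluded, ]
  expect_equal(metr$blocks$mean_hand_angle_deg,
               as.numeric(tapply(use$hand_angle_deg, use$block, mean)))
  expect_equal(metr$baseline_sd_deg,
               sd(use$hand_angle_deg[use$phase == "baseline"]))
  expect_equal(metr$aftereffect_deg,
               mean(use$hand_angle_deg[use$phase == "washout"]))
})
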