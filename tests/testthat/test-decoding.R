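test_that("feature assembly yields one sample per subject x task", {
  set.seed(131)
  times <- seq(0, 1, by = 0.05)
  vals <- array(rnorm(8 * 2 * 3 * length(times)),
                c(8, 2, 3, length(times)))
  bt <- makeBandTable(vals, c("P3", "Pz", "P4"), times)
  ds <- assembleFeatures(bt, "delta", c("P3", "Pz", "P4"), "feedback",
                         c(0, 1))
  expect_equal(dim(ds$X), c(16L, 3L, 21L))   # 16 samples, 21 bins
  expect_equal(sum(ds$y == 1), 8)
  # features land in the right cells
  expect_equal(ds$X[1, 2, 5], vals[1, 1, 2, 5])
  expect_equal(ds$X[2, 3, 21], vals[1, 2, 3, 21])
  dsFz <- assembleFeatures(makeBandTable(vals[, , 1, , drop = FALSE],
                                         "Fz", times),
                           "delta", "Fz", "feedback", c(0, 1))
  expect_equal(dim(dsFz$X)[2], 1L)
  expect_error(assembleFeatures(bt, "delta", "P3", "feedback", c(5, 6)),
               "not covered")
  expect_error(assembleFeatures(bt[bt$subject != 3 | bt$task != "memory", ],
                                "delta", "P3", "feedback", c(0, 1)),
               "missing subject")
})

test_that("LOSO accuracy is 1 for separable features, chance for noise", {
  X <- array(rep(rep(c(1, -1), 8), 3 * 5), c(16, 3, 5))
  ds <- makeDecodingDataset(X)
  expect_equal(losoAccuracy(ds), rep(1, 5))
  # accuracies are pooled over 8 folds x 2 predictions -> multiples of 1/16
  set.seed(141)
  accs <- replicate(60, {
    a <- losoAccuracy(makeDecodingDataset(array(rnorm(16 * 3 * 3),
                                                c(16, 3, 3))))
    expect_true(all(abs(a * 16 - round(a * 16)) < 1e-9))
    mean(a)
  })
  expect_lt(abs(mean(accs) - 0.5), 0.06)
})

test_that("accuracy is invariant to a feature-axis permutation", {
  set.seed(151)
  X <- array(rnorm(16 * 3 * 7), c(16, 3, 7))
  a1 <- losoAccuracy(makeDecodingDataset(X))
  a2 <- losoAccuracy(makeDecodingDataset(X[, c(3, 1, 2), ]))
  expect_equal(a1, a2)
})

test_that("own SVM solves the same dual as libsvm (e1071 cross-check)", {
  library(e1071)
  set.seed(161)
  for (i in 1:20) {
    n <- 14; d <- sample(1:4, 1)
    X <- matrix(rnorm(n * d), n, d)
    y <- rep(c(1, -1), each = n / 2)
    own <- rotadapt:::cpp_svm_train(X, y, 1)
    ref <- svm(X, factor(y), kernel = "linear", cost = 1, scale = FALSE)
    w <- drop(t(ref$coefs) %*% ref$SV)
    b <- -ref$rho
    if (ref$labels[1] == -1) { w <- -w; b <- -b }
    expect_lt(max(abs(own$w - w)), 0.02)
    expect_lt(abs(own$b - b), 0.02)
    # and identical predictions on fresh points
    Z <- matrix(rnorm(40 * d), 40, d)
    predOwn <- ifelse(Z %*% own$w + own$b >= 0, 1, -1)
    predRef <- as.numeric(as.character(predict(ref, Z)))
    expect_gte(mean(predOwn == predRef), 0.975)
  }
})

test_that("permutation null calibrates chance and significance", {
  # separable features: true accuracy 1 clears the threshold
  X <- array(rep(rep(c(1, -1), 8), 3 * 5), c(16, 3, 5))
  res <- decodeTaskType(makeDecodingDataset(X), nPerm = 200, seed = 3)
  expect_true(all(accuracySeries(res) == 1))
  expect_true(all(res@significant))
  expect_lt(res@threshold, 1)
  # fixed seed reproduces the null exactly
  res2 <- decodeTaskType(makeDecodingDataset(X), nPerm = 200, seed = 3)
  expect_identical(res@null, res2@null)
  expect_identical(res@threshold, res2@threshold)
  # per-bin chance approaches 1/2 for a balanced dataset at large nPerm
  set.seed(171)
  Xn <- array(rnorm(16 * 3 * 3), c(16, 3, 3))
  resPb <- permutationNull(makeDecodingDataset(Xn), nPerm = 2000,
                           seed = 5, mode = "perbin")
  expect_lt(max(abs(resPb@chance - 0.5)), 0.07)
  # null accuracies are symmetric about 1/2 in expectation
  expect_lt(abs(mean(resPb@null) - 0.5), 0.02)
  # the tidy table mirrors the object
  tab <- decodingTable(res)
  expect_equal(tab$accuracy, accuracySeries(res))
  expect_true(all(tab$significant))
})
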