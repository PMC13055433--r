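test_that("soft-thresholding matches its closed form", {
  expect_equal(softThreshold(2, 0), 2)
  expect_equal(softThreshold(0.5, 1), 0)
  expect_equal(softThreshold(-2, 0.5), -1.5)
  expect_equal(softThreshold(c(-3, 0, 3), 1), c(-2, 0, 2))
})

test_that("the unpenalized fit solves the delta-scaled linear system", {
  set.seed(31)
  ds <- smallDataset(30, 4)
  # delta > 1 makes the system strictly positive definite
  sys <- buildScoreSystem(ds, 0, 0, delta = 1.5)
  fit <- cdFit(sys, 0, 0, eps = 1e-10, tmax = 50000)
  direct <- solve(as.matrix(gammaDelta(sys)), sys@g)
  expect_equal(fit@theta, direct, tolerance = 1e-6)
  # at delta = 1 the symmetric representative still satisfies the normal
  # equations of the (rank-deficient) system
  sys1 <- buildScoreSystem(ds, 0, 0, delta = 1)
  fit1 <- cdFit(sys1, 0, 0, eps = 1e-10, tmax = 50000)
  expect_lt(max(abs(as.vector(sys1@Gamma %*% fit1@theta) - sys1@g)), 1e-5)
  K1 <- fit1@theta[scoreDA:::thetaLayout(4, TRUE)$kIdx]
  expect_equal(matrix(K1, 4, 4), t(matrix(K1, 4, 4)), tolerance = 1e-10)
})

test_that("KKT conditions hold at penalized solutions", {
  set.seed(32)
  ds <- smallDataset(25, 5)
  sys <- buildScoreSystem(ds, 0, 0)
  lay <- scoreDA:::thetaLayout(5, TRUE)
  for (lam in c(0.01, 0.1, 0.5)) {
    fit <- cdFit(sys, lam, 0.01, eps = 1e-8, tmax = 50000)
    expect_lt(fit@kktResidual, 1e-4)
    # recompute the subgradient bound independently
    grad <- as.vector(as.matrix(gammaDelta(sys)) %*% fit@theta) - sys@g
    lamVec <- scoreDA:::penaltyVector(sys, lam, 0.01)
    zero <- fit@theta == 0
    expect_true(all(abs(grad[zero]) <= lamVec[zero] + 1e-4))
    expect_true(all(abs(grad[!zero] + sign(fit@theta[!zero]) *
      lamVec[!zero]) <= 1e-4))
  }
})

test_that("a large enough penalty removes every off-diagonal K entry and the
           remaining coordinates solve their reduced system", {
  set.seed(33)
  ds <- smallDataset(20, 4)
  sys <- buildScoreSystem(ds, 0, 0)
  lamBig <- max(abs(sys@g)) * 10 + 10
  fit <- cdFit(sys, lamBig, 0, eps = 1e-10, tmax = 50000)
  expect_true(all(fit@K[upper.tri(fit@K)] == 0))
  lay <- scoreDA:::thetaLayout(4, TRUE)
  free <- c(lay$kDiag, lay$eta0Idx, lay$eta1Idx)
  Gd <- as.matrix(gammaDelta(sys))
  sol <- solve(Gd[free, free], sys@g[free])
  expect_equal(fit@theta[free], sol, tolerance = 1e-6)
  expect_equal(max(abs(fit@theta[-free])), 0)
})

test_that("the objective is non-increasing across sweeps", {
  set.seed(34)
  ds <- smallDataset(20, 5)
  sys <- buildScoreSystem(ds, 0.5, 0.5)
  fit <- cdFit(sys, 0.05, 0, eps = 1e-10, tmax = 300, traceObjective = TRUE)
  tr <- attr(fit, "objTrace")
  expect_gt(length(tr), 1)
  expect_true(all(diff(tr) <= 1e-12))
})

test_that("solutions are invariant to the coordinate update order", {
  set.seed(35)
  ds <- smallDataset(25, 4)
  sys <- buildScoreSystem(ds, 0, 0)
  nFused <- length(scoreDA:::fusedLayout(4, TRUE)$primary)
  f1 <- cdFit(sys, 0.05, eps = 1e-10, tmax = 50000)
  f2 <- cdFit(sys, 0.05, eps = 1e-10, tmax = 50000, order = sample(nFused))
  expect_equal(f1@theta, f2@theta, tolerance = 1e-6)
})

test_that("paths are warm-started, sorted and degenerate to a single fit", {
  set.seed(36)
  ds <- smallDataset(20, 5)
  sys <- buildScoreSystem(ds, 0, 0)
  path <- fitPath(sys, c(0.01, 1, 0.1), eps = 1e-8, tmax = 50000)
  expect_equal(path@lambdas, c(1, 0.1, 0.01))
  expect_equal(path@supportSizes,
    vapply(path@fits, function(f) sum(f@K[upper.tri(f@K)] != 0), integer(1)))
  # densest fit at the smallest lambda
  expect_gte(path@supportSizes[3], path@supportSizes[1])
  single <- fitPath(sys, 0.1, eps = 1e-8, tmax = 50000)
  expect_equal(single@fits[[1]]@theta, path@fits[[2]]@theta, tolerance = 1e-5)
  # default grid
  expect_equal(length(defaultLambdaPath()), 100)
  expect_equal(range(defaultLambdaPath()), c(1e-6, 1))
})

test_that("objective slot matches the penalized quadratic value", {
  set.seed(37)
  ds <- smallDataset(15, 4)
  sys <- buildScoreSystem(ds, 0, 0)
  fit <- cdFit(sys, 0.07, 0.02, eps = 1e-8)
  K <- matrix(fit@theta[scoreDA:::thetaLayout(4, TRUE)$kIdx], 4, 4)
  off <- K; diag(off) <- 0
  lay <- scoreDA:::thetaLayout(4, TRUE)
  obj <- quadLoss(sys, fit@theta, useDelta = TRUE) +
    0.07 * sum(abs(off)) +
    0.02 * sum(abs(fit@theta[c(lay$eta0Idx, lay$eta1Idx)]))
  expect_equal(fit@objective, obj, tolerance = 1e-8)
})

test_that("lambda-max scaling yields a path from empty to full support", {
  set.seed(38)
  ds <- smallDataset(40, 4)
  sys <- buildScoreSystem(ds, 0, 0)
  path <- fitPath(sys, defaultLambdaPath(20), eps = 1e-6,
    scaleToLambdaMax = TRUE)
  expect_equal(path@supportSizes[1], 0L)
  expect_equal(path@supportSizes[length(path@supportSizes)], 6L)
})
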