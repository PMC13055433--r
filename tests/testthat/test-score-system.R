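test_that("weight function is the truncated squared minimum", {
  expect_equal(weightFunction(c(0.5, 0, 0.5), 1), 0.25)
  expect_equal(weightFunction(c(0, 0.1, 0.9), 1), 0)
  expect_equal(weightFunction(c(0.9, 0.05, 0.05), 1), 0.0025)
  expect_equal(weightFunction(c(0.3, 0.3, 0.4), 1, weightSpec(c = 1, Cj = 0.2)),
    0.2)
})

test_that("analytic partials match finite differences of the profiled density", {
  set.seed(21)
  for (cfg in list(c(0, 0), c(1, 1), c(0.6, 0.3), c(0, 0.5))) {
    p <- 3
    pars <- randomParams(p, cfg[1], cfg[2])
    x <- as.vector(rDirichletMatrix(1, rep(2, p)))
    y <- rnorm(1)
    d <- logDensityPartials(x, y, pars)
    h <- 1e-6
    for (j in 1:(p - 1)) {
      xp <- x; xp[j] <- x[j] + h; xp[p] <- x[p] - h
      xm <- x; xm[j] <- x[j] - h; xm[p] <- x[p] + h
      fd1 <- (unnormLogDensity(xp, y, pars) - unnormLogDensity(xm, y, pars)) /
        (2 * h)
      fd2 <- (unnormLogDensity(xp, y, pars) - 2 * unnormLogDensity(x, y, pars) +
        unnormLogDensity(xm, y, pars)) / h^2
      expect_equal(d$first[j], fd1, tolerance = 1e-5)
      expect_equal(d$second[j], fd2, tolerance = 1e-3)
    }
  }
})

test_that("quadratic form reproduces the direct loss up to a theta-free constant", {
  set.seed(22)
  for (rep in 1:20) {
    p <- sample(3:6, 1)
    n <- sample(5:15, 1)
    ab <- sample(list(c(0, 0), c(1, 1), c(0.5, 0.5), c(0.7, 0.2)), 1)[[1]]
    ds <- smallDataset(n, p, withCov = TRUE, alpha = runif(p, 1, 4))
    sys <- buildScoreSystem(ds, ab[1], ab[2])
    pars <- randomParams(p, ab[1], ab[2])
    th <- thetaFromFit(pars, sys)
    scale <- max(1, abs(lossDirect(ds, pars)))
    expect_equal(lossDirect(ds, pars), quadLoss(sys, th),
      tolerance = 1e-8 * scale)
  }
})

test_that("duplicating every sample leaves the loss unchanged", {
  set.seed(23)
  ds <- smallDataset(8, 4)
  ds2 <- CompositionData(rbind(compositions(ds), compositions(ds)),
    y = c(covariate(ds), covariate(ds)), normalize = FALSE)
  pars <- randomParams(4, 0.5, 0.5)
  expect_equal(lossDirect(ds, pars), lossDirect(ds2, pars), tolerance = 1e-12)
})

test_that("Gamma is symmetric PSD and per-sample components average to the aggregate", {
  set.seed(24)
  ds <- smallDataset(10, 4)
  sys <- buildScoreSystem(ds, 0, 0)
  G <- as.matrix(sys@Gamma)
  expect_lt(max(abs(G - t(G))), 1e-8)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * max(abs(G)))
  agg <- Reduce(`+`, lapply(1:10, function(i) {
    scoreDA:::perSampleComponents(sys, i)$Gamma
  })) / 10
  expect_equal(agg, G, tolerance = 1e-10)
  gAgg <- Reduce(`+`, lapply(1:10, function(i) {
    scoreDA:::perSampleComponents(sys, i)$g
  })) / 10
  expect_equal(gAgg, sys@g, tolerance = 1e-10)
})

test_that("covariate blocks obey the y-weighted identities for real-valued y", {
  set.seed(25)
  p <- 4; n <- 9
  ds <- smallDataset(n, p, withCov = TRUE)
  y <- covariate(ds)
  sys <- buildScoreSystem(ds, 0.5, 0.5)
  lay <- scoreDA:::thetaLayout(p, TRUE)
  comps <- lapply(seq_len(n), function(i) scoreDA:::perSampleComponents(sys, i))
  G <- as.matrix(sys@Gamma)
  wmean <- function(f, w) Reduce(`+`, Map(function(c, wi) wi * f(c), comps, w)) / n
  expect_equal(G[lay$kIdx, lay$eta1Idx],
    wmean(function(c) c$Gamma[lay$kIdx, lay$eta0Idx], y), tolerance = 1e-10)
  expect_equal(G[lay$eta0Idx, lay$eta1Idx],
    wmean(function(c) c$Gamma[lay$eta0Idx, lay$eta0Idx], y), tolerance = 1e-10)
  expect_equal(G[lay$eta1Idx, lay$eta1Idx],
    wmean(function(c) c$Gamma[lay$eta0Idx, lay$eta0Idx], y^2), tolerance = 1e-10)
  expect_equal(sys@g[lay$eta1Idx],
    wmean(function(c) c$g[lay$eta0Idx], y), tolerance = 1e-10)
})

test_that("degenerate covariates zero or copy the eta1 blocks", {
  set.seed(26)
  X <- rDirichletMatrix(8, rep(2, 4))
  lay <- scoreDA:::thetaLayout(4, TRUE)
  sys0 <- buildScoreSystem(CompositionData(X, y = rep(0, 8), normalize = FALSE),
    0, 0)
  expect_equal(sys0@g[lay$eta1Idx], rep(0, 4))
  expect_equal(max(abs(sys0@Gamma[, lay$eta1Idx])), 0)
  sys1 <- buildScoreSystem(CompositionData(X, y = rep(1, 8), normalize = FALSE),
    0, 0)
  G <- as.matrix(sys1@Gamma)
  expect_equal(G[lay$eta1Idx, lay$eta1Idx], G[lay$eta0Idx, lay$eta0Idx])
  expect_equal(sys1@g[lay$eta1Idx], sys1@g[lay$eta0Idx])
})

test_that("sample order does not change the system and GammaDelta only rescales the vec(K) diagonal", {
  set.seed(27)
  ds <- smallDataset(10, 4)
  sys <- buildScoreSystem(ds, 0, 0)
  perm <- sample(10)
  dsP <- CompositionData(compositions(ds)[perm, ], y = covariate(ds)[perm],
    normalize = FALSE)
  sysP <- buildScoreSystem(dsP, 0, 0)
  expect_equal(as.matrix(sysP@Gamma), as.matrix(sys@Gamma), tolerance = 1e-12)
  expect_equal(sysP@g, sys@g, tolerance = 1e-12)

  Dd <- as.matrix(gammaDelta(sys)) - as.matrix(sys@Gamma)
  lay <- scoreDA:::thetaLayout(4, TRUE)
  offDiagMask <- Dd; diag(offDiagMask) <- 0
  expect_equal(max(abs(offDiagMask)), 0)
  expect_equal(which(diag(Dd) != 0), lay$kIdx)
})

test_that("zeros are rejected for log models and tolerated for positive powers", {
  X <- rDirichletMatrix(6, rep(2, 4))
  X[1, 2] <- 0
  X <- X / rowSums(X)
  ds <- CompositionData(X, normalize = FALSE)
  expect_error(buildScoreSystem(ds, 0, 0), "pseudocount")
  sys <- buildScoreSystem(ds, 0.5, 0.5)
  expect_true(all(is.finite(sys@g)))
  expect_true(all(is.finite(sys@Gamma@x)))
})

test_that("the memory guard names the limit", {
  ds <- smallDataset(4, 5)
  expect_error(buildScoreSystem(ds, 0, 0, memoryGuard = 4L), "memory guard")
})
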