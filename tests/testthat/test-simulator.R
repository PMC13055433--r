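test_that("banded interaction matrices match the printed construction", {
  K <- bandedInteractionMatrix(4, 1)
  expect_equal(K[1, 2], 1 / 2 - 1)
  expect_equal(diag(K), c(0.5, 1, 1, 0.5))
  expect_equal(K, t(K))
  for (cfg in list(c(10, 3), c(100, 2), c(100, 7), c(50, 5))) {
    K <- bandedInteractionMatrix(cfg[1], cfg[2])
    expect_equal(as.vector(K %*% rep(1, cfg[1])), rep(0, cfg[1]),
      tolerance = 1e-12)
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-12)
  }
  expect_error(bandedInteractionMatrix(5, 5), "s")
})

test_that("block-diagonal tiling preserves symmetry and zero row sums", {
  K <- bandedInteractionMatrix(11, 2)
  K99 <- tileBlockDiagonal(K, 9)
  expect_equal(dim(K99), c(99, 99))
  expect_equal(as.vector(K99 %*% rep(1, 99)), rep(0, 99), tolerance = 1e-12)
  expect_equal(K99, t(K99))
  expect_equal(K99[1:11, 1:11], K)
  expect_equal(max(abs(K99[1:11, 12:99])), 0)
})

test_that("samples live on the simplex and seeds fully determine them", {
  K <- bandedInteractionMatrix(5, 1)
  pars <- PowerModelParams(0, 0, K, rep(-1, 5))
  X1 <- samplePowerInteraction(50, pars, seed = 99)
  X2 <- samplePowerInteraction(50, pars, seed = 99)
  expect_identical(X1, X2)
  expect_equal(rowSums(X1), rep(1, 50), tolerance = 1e-10)
  expect_true(all(X1 > 0))
  X3 <- samplePowerInteraction(50, pars, seed = 100)
  expect_false(identical(X1, X3))
  # Gibbs route is deterministic under seed too
  parsG <- PowerModelParams(1, 1, K, rep(0.5, 5))
  G1 <- samplePowerInteraction(20, parsG, seed = 5, burnIn = 50)
  G2 <- samplePowerInteraction(20, parsG, seed = 5, burnIn = 50)
  expect_identical(G1, G2)
  expect_equal(rowSums(G1), rep(1, 20), tolerance = 1e-10)
})

test_that("the Gibbs sampler recovers Dirichlet moments", {
  set.seed(71)
  alpha <- c(2, 3, 4)
  pars <- PowerModelParams(0, 0, matrix(0, 3, 3), alpha - 1)
  n <- 5000
  X <- samplePowerInteraction(n, pars, method = "gibbs", burnIn = 300,
    gridSize = 512)
  m <- alpha / sum(alpha)
  v <- m * (1 - m) / (sum(alpha) + 1)
  mcse <- sqrt(v / n)
  expect_true(all(abs(colMeans(X) - m) < 3 * mcse))
  # marginal variances within 10% relative
  expect_true(all(abs(apply(X, 2, var) - v) / v < 0.1))
})

test_that("a long chain matches quadrature of the target density (a = b = 1)", {
  set.seed(72)
  p <- 3
  K <- bandedInteractionMatrix(3, 1) * 2
  pars <- PowerModelParams(1, 1, K, c(1, 2, 1.5))
  n <- 4000
  X <- samplePowerInteraction(n, pars, method = "gibbs", burnIn = 250,
    gridSize = 256)
  # quadrature on the (x1, x2) triangle
  G <- 200
  xs <- (seq_len(G) - 0.5) / G
  grid <- expand.grid(x1 = xs, x2 = xs)
  grid <- grid[grid$x1 + grid$x2 < 1, ]
  lp <- apply(grid, 1, function(r) {
    unnormLogDensity(c(r[1], r[2], 1 - r[1] - r[2]), 0, pars)
  })
  w <- exp(lp - max(lp)); w <- w / sum(w)
  # 6x6 histogram comparison
  bins <- 6
  cellOf <- function(x1, x2) {
    pmin(floor(x1 * bins), bins - 1) * bins + pmin(floor(x2 * bins), bins - 1)
  }
  pTheo <- tapply(w, cellOf(grid$x1, grid$x2), sum)
  pEmp <- table(factor(cellOf(X[, 1], X[, 2]), levels = names(pTheo))) / n
  tv <- 0.5 * sum(abs(as.vector(pEmp) - as.vector(pTheo)))
  expect_lt(tv, 0.05)
})

test_that("two-group scenarios carry the designed effect with the right sign", {
  set.seed(73)
  scen <- makeDAScenario(2000, 1, 4, burnIn = 300)
  X <- compositions(scen$dataset)
  y <- covariate(scen$dataset)
  expect_equal(sum(scen$truth), 1)
  expect_true(scen$truth[4])
  expect_equal(scen$params@eta1, 1 * replace(rep(0, 11), 4, 1) *
    scen$params@eta0)
  # eta1_4 = eta0_4 < 0: the case group should carry less of feature 4
  d <- mean(X[y == 1, 4]) - mean(X[y == 0, 4])
  expect_lt(d, 0)
  expect_error(makeDAScenario(101, 1, 4), "even")
  # tau = 0 gives an all-null truth vector
  expect_equal(sum(makeDAScenario(20, 0, 4, burnIn = 10)$truth), 0)
})

test_that("the recovery benchmark reproduces its design and is seed-stable", {
  b1 <- makeRecoveryBenchmark(p = 20, n = 15, s = 2, R = 2, seed = 3)
  b2 <- makeRecoveryBenchmark(p = 20, n = 15, s = 2, R = 2, seed = 3)
  expect_identical(
    compositions(b1$datasets[[1]]),
    compositions(b2$datasets[[1]])
  )
  expect_equal(b1$Ktrue, bandedInteractionMatrix(20, 2))
  expect_equal(b1$params@eta0, rep(-1, 20))
  expect_equal(nSamples(b1$datasets[[2]]), 15)
  # the generating parameters satisfy the propriety grid check
  set.seed(1)
  expect_true(validateParams(b1$params)$is_valid)
})
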