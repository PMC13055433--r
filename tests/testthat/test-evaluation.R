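test_that("support-recovery ROC hits the trivial anchors", {
  Ktrue <- bandedInteractionMatrix(5, 1)
  exact <- Ktrue
  roc <- supportRecoveryROC(list(exact), Ktrue)
  expect_equal(roc$auc, 1)
  diagOnly <- diag(5)
  roc0 <- supportRecoveryROC(list(diagOnly), Ktrue)
  # single (0, 0) point plus anchors: chance-level chord
  expect_equal(roc0$auc, 0.5)
  expect_error(supportRecoveryROC(list(diag(5)), diag(5)), "nonempty")
  expect_error(supportRecoveryROC(list(diag(5)), matrix(1, 5, 5)), "non-full")
})

test_that("path AUC equals the rank-based AUC for nested threshold supports", {
  set.seed(81)
  p <- 5
  score <- matrix(0, p, p)
  score[upper.tri(score)] <- runif(choose(p, 2))
  score <- score + t(score)
  Ktrue <- bandedInteractionMatrix(p, 2)
  thr <- sort(unique(score[upper.tri(score)]), decreasing = TRUE)
  supports <- lapply(c(thr, 0), function(t) {
    M <- score * (abs(score) > t + 1e-15)
    diag(M) <- 1
    M
  })
  roc <- supportRecoveryROC(supports, Ktrue)
  # Mann-Whitney / rank oracle over all thresholds of the same score
  truth <- scoreDA:::offSupport(Ktrue)
  s <- score[upper.tri(score)]
  aucRank <- mean(outer(s[truth], s[!truth], ">") +
    0.5 * outer(s[truth], s[!truth], "=="))
  expect_equal(roc$auc, aucRank, tolerance = 1e-12)
  # refining the grid with duplicate supports does not change the AUC
  roc2 <- supportRecoveryROC(c(supports, supports), Ktrue)
  expect_equal(roc2$auc, roc$auc, tolerance = 1e-12)
})

test_that("DA metrics implement the stated conventions", {
  # nothing called, nothing true: 0/0 conventions
  m <- daMetrics(rep(0.5, 10), rep(FALSE, 10))
  expect_equal(c(m$fdr, m$tpr, m$mcc), c(0, 0, 0))
  # perfect calls
  truth <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  m2 <- daMetrics(c(0.01, 0.01, 0.9, 0.9, 0.9), truth)
  expect_equal(c(m2$fdr, m2$tpr, m2$mcc), c(0, 1, 1))
  # TP=1 FP=1 FN=1 TN=8
  padj <- c(0.01, 0.5, 0.01, rep(0.9, 8))
  tru <- c(TRUE, TRUE, FALSE, rep(FALSE, 8))
  m3 <- daMetrics(padj, tru)
  expect_equal(m3$fdr, 0.5)
  expect_equal(m3$tpr, 0.5)
  expect_equal(m3$mcc, (1 * 8 - 1 * 1) / sqrt(2 * 2 * 9 * 9))
  # a single false discovery with no true positive gives FDR 1
  m4 <- daMetrics(c(0.01, rep(0.9, 4)), c(FALSE, TRUE, rep(FALSE, 3)))
  expect_equal(m4$fdr, 1)
  # permutation invariance
  perm <- sample(length(padj))
  m5 <- daMetrics(padj[perm], tru[perm])
  expect_equal(m5$fdr, m3$fdr)
  expect_equal(m5$mcc, m3$mcc)
})

test_that("the mean ROC averages replicate curves vertically", {
  r1 <- structure(list(fpr = c(0, 0.5, 1), tpr = c(0, 0.5, 1), auc = 0.5),
    class = "recoveryROC")
  r2 <- structure(list(fpr = c(0, 0.5, 1), tpr = c(0, 1, 1), auc = 0.75),
    class = "recoveryROC")
  m <- meanROC(list(r1, r2), fprGrid = c(0, 0.5, 1))
  expect_equal(m$tpr, c(0, 0.75, 1))
  expect_equal(m$auc, 0.625)
})

test_that("the glasso comparator satisfies its stationarity conditions", {
  set.seed(82)
  K <- bandedInteractionMatrix(8, 2)
  pars <- PowerModelParams(0, 0, K, rep(-1, 8))
  X <- samplePowerInteraction(60, pars, validate = FALSE)
  S <- cov(clrTransform(X))
  rho <- 0.2 * max(abs(S - diag(diag(S))))
  f <- scoreDA:::glasso_fit(S, rho, NULL, NULL, 200L, 1e-8, 500L)
  W <- f$W; B <- f$B
  # each column's lasso KKT: |S12 - W11 beta| <= rho, equality on support
  for (j in 1:8) {
    resid <- S[-j, j] - W[-j, -j] %*% B[-j, j]
    act <- B[-j, j] != 0
    expect_true(all(abs(resid[!act]) <= rho + 1e-6))
    if (any(act)) {
      expect_equal(as.vector(resid[act]),
        rho * sign(B[-j, j][act]), tolerance = 1e-6)
    }
  }
  # diagonal of W fixed at S + rho
  expect_equal(diag(W), diag(S) + rho, tolerance = 1e-10)
})

test_that("the naive log t-test baseline returns adjusted p-values per feature", {
  set.seed(83)
  scen <- makeDAScenario(60, 1, 4, burnIn = 100)
  tab <- logTTestDA(scen$dataset)
  expect_equal(nrow(tab), 10)
  expect_true(all(tab$p_adj >= tab$p_raw))
  expect_error(logTTestDA(CompositionData(compositions(scen$dataset),
    normalize = FALSE)), "covariate")
})
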