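# Benchmark metrics and harnesses: support-recovery ROC/AUC along a lambda
# path, differential abundance FDR/TPR/MCC, and the replicate-level
# benchmark drivers.

offSupport <- function(M, tol = 1e-10) {
  A <- pmax(abs(M), abs(t(M)))
  A[upper.tri(A)] > tol
}

rocFromSupports <- function(supports, truthOff) {
  pos <- sum(truthOff)
  neg <- sum(!truthOff)
  if (pos == 0L || neg == 0L) {
    stop("true off-diagonal support must be nonempty and non-full")
  }
  tpr <- vapply(supports, function(s) sum(s & truthOff) / pos, numeric(1))
  fpr <- vapply(supports, function(s) sum(s & !truthOff) / neg, numeric(1))
  fpr <- c(0, fpr, 1)
  tpr <- c(0, tpr, 1)
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(
    list(fpr = fpr, tpr = tpr, auc = auc),
    class = "recoveryROC"
  )
}

#' @rdname supportRecoveryROC
#' @export
setMethod("supportRecoveryROC", signature("ScoreFitPath", "matrix"),
  function(path, Ktrue) {
    supports <- lapply(path@fits, function(f) offSupport(f@K))
    rocFromSupports(supports, offSupport(Ktrue))
  }
)

#' @rdname supportRecoveryROC
#' @export
setMethod("supportRecoveryROC", signature("list", "matrix"),
  function(path, Ktrue) {
    supports <- lapply(path, offSupport)
    rocFromSupports(supports, offSupport(Ktrue))
  }
)

#' @export
print.recoveryROC <- function(x, ...) {
  cat(sprintf("Support-recovery ROC: %d points, AUC = %.3f\n",
    length(x$fpr), x$auc))
  invisible(x)
}

#' @export
plot.recoveryROC <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlab = "FPR", ylab = "TPR",
    xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Vertically averaged ROC over replicates
#'
#' Interpolates each replicate's TPR on a common FPR grid and averages,
#' with the standard error across replicates.
#'
#' @param rocs list of \code{recoveryROC} objects.
#' @param fprGrid common grid (default 0 to 1 by 0.01).
#' @export
meanROC <- function(rocs, fprGrid = seq(0, 1, by = 0.01)) {
  tprMat <- vapply(rocs, function(r) {
    stats::approx(r$fpr, r$tpr, xout = fprGrid, ties = max, rule = 2)$y
  }, numeric(length(fprGrid)))
  list(
    fpr = fprGrid,
    tpr = rowMeans(tprMat),
    se = apply(tprMat, 1, sd) / sqrt(length(rocs)),
    auc = mean(vapply(rocs, function(r) r$auc, numeric(1)))
  )
}

#' Differential abundance error metrics at a nominal level
#'
#' Calls are \code{p_adj < alpha}. FDR = FP / (FP + TP) with the 0/0 -> 0
#' convention (no special-casing when FP > 0: a single false discovery with
#' no true positives gives FDR = 1); TPR = TP / (TP + FN) (0/0 -> 0); MCC
#' by the closed form, 0 when any confusion margin is 0.
#'
#' @param p_adj adjusted p-values (reference feature excluded upstream).
#' @param truth logical ground-truth vector of equal length.
#' @param alpha nominal FDR level (default 0.05).
#' @return a \code{daMetrics} list: \code{fdr}, \code{tpr}, \code{mcc},
#'   \code{n_called}.
#' @export
daMetrics <- function(p_adj, truth, alpha = 0.05) {
  stopifnot(length(p_adj) == length(truth))
  if (any(is.na(p_adj))) stop("NA adjusted p-values; exclude the reference upstream")
  call <- p_adj < alpha
  TP <- sum(call & truth); FP <- sum(call & !truth)
  FN <- sum(!call & truth); TN <- sum(!call & !truth)
  fdr <- if (TP + FP == 0L) 0 else FP / (FP + TP)
  tpr <- if (TP + FN == 0L) 0 else TP / (TP + FN)
  denom <- prod(sqrt(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  mcc <- if (denom == 0) 0 else (TP * TN - FP * FN) / denom
  structure(
    list(fdr = fdr, tpr = tpr, mcc = mcc, n_called = TP + FP),
    class = "daMetrics"
  )
}

#' @export
print.daMetrics <- function(x, ...) {
  cat(sprintf("DA metrics: FDR = %.3f, TPR = %.3f, MCC = %.3f (%d called)\n",
    x$fdr, x$tpr, x$mcc, x$n_called))
  invisible(x)
}

# ---- graphical lasso comparator -----------------------------------------

#' Graphical lasso path on CLR-transformed compositions (thin comparator)
#'
#' Sparse inverse covariance estimation on centered log-ratio transformed
#' data, the SPIEC-EASI-style misspecified proxy for the interaction
#' matrix. Warm-started along a decreasing penalty grid.
#'
#' @param X strictly positive n x p composition matrix.
#' @param lambdas penalty values; with \code{scaleToLambdaMax = TRUE}
#'   (default) they are fractions of \code{max |offdiag(S)|}, the smallest
#'   fully sparsifying penalty, so the grid covers the whole sparsity range.
#' @param maxOuter,tol,maxInner solver controls.
#' @param scaleToLambdaMax scale the grid by the data-dependent lambda-max.
#' @param earlyStopFull stop refining once the support is complete and
#'   reuse it for the remaining lambdas (default TRUE).
#' @return list with \code{lambdas} and \code{supports} (list of p x p
#'   coefficient matrices whose off-diagonal support estimates the
#'   precision support).
#' @export
glassoCLRPath <- function(X, lambdas = defaultLambdaPath(),
                          maxOuter = 30L, tol = 3e-4, maxInner = 200L,
                          scaleToLambdaMax = TRUE, earlyStopFull = TRUE) {
  S <- cov(clrTransform(X))
  lambdas <- sort(unique(lambdas), decreasing = TRUE)
  if (scaleToLambdaMax) {
    off <- abs(S); diag(off) <- 0
    lambdas <- lambdas * max(off)
  }
  p <- ncol(S)
  W <- NULL; B <- NULL
  supports <- vector("list", length(lambdas))
  for (i in seq_along(lambdas)) {
    fitI <- glasso_fit(S, lambdas[i], W, B, as.integer(maxOuter), tol,
      as.integer(maxInner))
    W <- fitI$W; B <- fitI$B
    supports[[i]] <- B
    if (earlyStopFull && sum(offSupport(B)) == p * (p - 1) / 2 &&
        i < length(lambdas)) {
      for (k in (i + 1L):length(lambdas)) supports[[k]] <- B
      break
    }
  }
  list(lambdas = lambdas, supports = supports)
}

# ---- benchmark drivers ---------------------------------------------------

#' Support-recovery AUC of one dataset under one estimation route
#'
#' @param dataset a \linkS4class{CompositionData} (with covariate for the
#'   covariate-extended route).
#' @param Ktrue ground-truth interaction matrix.
#' @param lambdas penalty path (fractions of the data-dependent lambda-max
#'   when \code{scaleToLambdaMax = TRUE}, the default, so that the path
#'   covers the full sparsity range).
#' @param a,b powers; @param eps,tmax solver controls.
#' @param scaleToLambdaMax see \code{\link{fitPath}}.
#' @export
recoveryAUC <- function(dataset, Ktrue, lambdas = defaultLambdaPath(),
                        a = 0, b = 0, eps = 1e-1, tmax = 1000L,
                        scaleToLambdaMax = TRUE) {
  sys <- buildScoreSystem(dataset, a, b, keepPerSample = FALSE)
  path <- fitPath(sys, lambdas, eps = eps, tmax = tmax,
    scaleToLambdaMax = scaleToLambdaMax, earlyStopFull = TRUE)
  supportRecoveryROC(path, Ktrue)
}

#' Run the interaction-recovery benchmark over replicates
#'
#' Generates R replicate datasets from the banded-K log-based model and
#' computes support-recovery ROC/AUC for (i) the covariate-less score
#' matching fit, (ii) the covariate-extended fit with a misspecified
#' binary covariate, (iii) the graphical lasso on CLR data.
#'
#' @param R replicates; @param p,n,s design parameters.
#' @param seed RNG seed.
#' @param lambdas penalty path shared by all methods.
#' @param methods subset of c("nocov", "cov", "glasso").
#' @param eps,tmax solver controls.
#' @return list with \code{auc} (R x method matrix), \code{meanAUC},
#'   \code{rocs} (per method, list of per-replicate ROCs).
#' @export
runRecoveryBenchmark <- function(R = 5L, p = 100L, n = 80L, s = 2L,
                                 seed = 1L, lambdas = defaultLambdaPath(),
                                 methods = c("nocov", "cov", "glasso"),
                                 eps = 1e-3, tmax = 1000L) {
  bench <- makeRecoveryBenchmark(p = p, n = n, s = s, R = R, seed = seed)
  aucs <- matrix(NA_real_, R, length(methods),
    dimnames = list(NULL, methods))
  rocs <- setNames(vector("list", length(methods)), methods)
  for (m in methods) rocs[[m]] <- vector("list", R)
  for (r in seq_len(R)) {
    X <- compositions(bench$datasets[[r]])
    if ("nocov" %in% methods) {
      roc <- recoveryAUC(bench$datasets[[r]], bench$Ktrue, lambdas,
        eps = eps, tmax = tmax)
      rocs[["nocov"]][[r]] <- roc
      aucs[r, "nocov"] <- roc$auc
    }
    if ("cov" %in% methods) {
      y <- sample(c(0, 1), n, replace = TRUE) # misspecified covariate
      ds <- CompositionData(X, y = y, normalize = FALSE)
      roc <- recoveryAUC(ds, bench$Ktrue, lambdas, eps = eps, tmax = tmax)
      rocs[["cov"]][[r]] <- roc
      aucs[r, "cov"] <- roc$auc
    }
    if ("glasso" %in% methods) {
      gl <- glassoCLRPath(X, lambdas)
      roc <- supportRecoveryROC(gl$supports, bench$Ktrue)
      rocs[["glasso"]][[r]] <- roc
      aucs[r, "glasso"] <- roc$auc
    }
  }
  list(auc = aucs, meanAUC = colMeans(aucs), rocs = rocs, seed = seed)
}

#' Per-feature two-sample t-tests on log proportions (naive baseline)
#'
#' The interaction-blind baseline: an independent Welch t-test of
#' log-transformed proportions per non-reference feature, BH-adjusted.
#' Zeros are replaced by half the smallest positive entry.
#'
#' @param dataset a \linkS4class{CompositionData} with a binary covariate.
#' @return data.frame with feature, p_raw, p_adj.
#' @export
logTTestDA <- function(dataset) {
  X <- compositions(dataset)
  y <- covariate(dataset)
  if (is.null(y) || length(unique(y)) != 2L) {
    stop("binary covariate required")
  }
  if (any(X == 0)) X[X == 0] <- min(X[X > 0]) / 2
  L <- log(X)
  idx <- setdiff(seq_len(ncol(X)), referenceIndex(dataset))
  pRaw <- vapply(idx, function(j) {
    t.test(L[y == unique(y)[1], j], L[y == unique(y)[2], j])$p.value
  }, numeric(1))
  data.frame(
    feature = featureNames(dataset)[idx],
    p_raw = pRaw, p_adj = bhAdjust(pRaw),
    stringsAsFactors = FALSE
  )
}

#' Penalty grid of the differential abundance benchmark
#'
#' 20 values log-spaced in [1e-3, 2].
#' @export
daLambdaGrid <- function() exp(seq(log(2), log(1e-3), length.out = 20))

#' Run the two-group differential abundance benchmark
#'
#' For each replicate and effect size tau, generates a correlated-feature
#' scenario, runs the full score matching DA pipeline (5-fold CV with the
#' 1SE rule over the benchmark penalty grid, sandwich test, BH) and the
#' naive log t-test baseline on the same data, and records FDR/TPR/MCC at
#' the nominal level.
#'
#' @param nRep replicates per tau.
#' @param n samples per dataset (even).
#' @param taus effect sizes (default \code{\link{daTauGrid}}).
#' @param targetFeatures affected features. The default (feature 8) is the
#'   most strongly loaded feature of the synthetic base scenario
#'   (largest |eta0|, so the relative effect tau * eta0 is largest),
#'   mirroring the abundant-cell-type case where the false-positive
#'   contrast between interaction-aware and naive testing is sharpest.
#' @param seed RNG seed.
#' @param lambdas penalty grid (default \code{\link{daLambdaGrid}}).
#' @param alpha nominal FDR level.
#' @param burnIn Gibbs burn-in for the case group.
#' @return data.frame with one row per (rep, tau, method).
#' @export
daBenchmark <- function(nRep = 5L, n = 1000L, taus = daTauGrid(),
                        targetFeatures = 8L, seed = 1L,
                        lambdas = daLambdaGrid(), alpha = 0.05,
                        burnIn = 300L) {
  set.seed(seed)
  out <- list()
  for (r in seq_len(nRep)) {
    for (tau in taus) {
      scen <- makeDAScenario(n, tau, targetFeatures, burnIn = burnIn)
      ds <- scen$dataset
      ref <- referenceIndex(ds)
      truth <- scen$truth[-ref]

      sel <- crossValidate(ds, 0, 0, lambdas, k = 5L,
        seed = sample.int(1e6, 1))
      sys <- buildScoreSystem(ds, 0, 0)
      fit <- cdFit(sys, sel$lambda_selected)
      res <- daTest(fit, sandwichCovariance(sys, fit), sys)
      tab <- daTable(res)
      mCos <- daMetrics(tab$p_adj[!tab$is_reference], truth, alpha)

      base <- logTTestDA(ds)
      mBase <- daMetrics(base$p_adj, truth, alpha)

      out[[length(out) + 1L]] <- data.frame(
        rep = r, tau = tau,
        method = c("scoreDA", "logTTest"),
        fdr = c(mCos$fdr, mBase$fdr),
        tpr = c(mCos$tpr, mBase$tpr),
        mcc = c(mCos$mcc, mBase$mcc),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
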