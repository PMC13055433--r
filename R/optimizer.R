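# l1-penalized quadratic score matching solver: proximal coordinate descent
# with warm-started lambda paths. Off-diagonal vec(K) coordinates carry the
# lambda1 penalty, eta coordinates lambda2, the K diagonal is unpenalized.

#' Soft-thresholding operator
#'
#' The proximal map of the l1 norm: \code{sign(z) * max(|z| - t, 0)}.
#'
#' @param z numeric; @param t threshold >= 0.
#' @export
softThreshold <- function(z, t) {
  stopifnot(all(t >= 0))
  sign(z) * pmax(abs(z) - t, 0)
}

penaltyVector <- function(system, lambda1, lambda2) {
  lay <- thetaLayout(system@p, system@hasCovariate)
  lam <- numeric(lay$r)
  lam[lay$kOff] <- lambda1
  lam[lay$eta0Idx] <- lambda2
  if (system@hasCovariate) lam[lay$eta1Idx] <- lambda2
  lam
}

# Fused-coordinate structure: the (j,k) and (k,j) vec(K) coordinates have
# structurally identical Gamma columns and are updated as one symmetric
# coordinate. partner[s] = mirror coordinate (s itself when unfused);
# primary = the coordinates swept (upper triangle incl. diagonal + eta).
fusedLayout <- function(p, hasCovariate) {
  lay <- thetaLayout(p, hasCovariate)
  partner <- seq_len(lay$r)
  idx <- matrix(partner[lay$kIdx], p, p)
  partner[lay$kIdx] <- as.vector(t(idx))
  primary <- c(
    lay$kIdx[as.vector(upper.tri(idx, diag = TRUE))],
    lay$eta0Idx, lay$eta1Idx
  )
  list(partner = partner, primary = primary)
}

#' Fit the penalized score matching problem at one (lambda1, lambda2)
#'
#' Cyclic proximal coordinate descent on \eqn{\tfrac12\theta^\top
#' \Gamma_\delta\theta - g^\top\theta + \lambda_1\|\mathrm{vec}(K_{off})\|_1
#' + \lambda_2(\|\eta_0\|_1 + \|\eta_1\|_1)}. A sweep stops the iteration
#' when the largest coordinate change falls below \code{eps} relative to
#' \code{max(1, ||theta||_inf)}.
#'
#' @param system a \linkS4class{ScoreSystem}.
#' @param lambda1 penalty on off-diagonal vec(K) coordinates.
#' @param lambda2 penalty on eta coordinates (default 0).
#' @param thetaInit warm start (default zero; symmetrized in K).
#' @param eps convergence tolerance (default 1e-1).
#' @param tmax maximum number of sweeps (default 1000).
#' @param order optional update order: a permutation of the fused
#'   coordinate sequence (upper-triangle K pairs incl. diagonal, then
#'   eta), length p(p+1)/2 + p (+p with covariate). The mirrored vec(K)
#'   coordinates are updated jointly as one symmetric coordinate, which
#'   keeps the minimizer unique even where the penalized problem is flat
#'   along antisymmetric directions.
#' @param traceObjective record the penalized objective after every sweep
#'   (attribute \code{objTrace} on the result).
#' @return a \linkS4class{ScoreFit}.
#' @export
cdFit <- function(system, lambda1, lambda2 = 0, thetaInit = NULL,
                  eps = 1e-1, tmax = 1000L, order = NULL,
                  traceObjective = FALSE) {
  stopifnot(lambda1 >= 0, lambda2 >= 0)
  p <- system@p
  lay <- thetaLayout(p, system@hasCovariate)
  fused <- fusedLayout(p, system@hasCovariate)
  if (is.null(thetaInit)) {
    thetaInit <- numeric(lay$r)
  } else {
    # the solver iterates on the symmetric representative
    Km <- matrix(thetaInit[lay$kIdx], p, p)
    thetaInit[lay$kIdx] <- as.vector((Km + t(Km)) / 2)
  }
  if (is.null(order)) order <- seq_along(fused$primary)
  stopifnot(length(order) == length(fused$primary))
  res <- cd_quad_lasso(
    system@Gamma, system@g, penaltyVector(system, lambda1, lambda2),
    diagMultiplier(system), thetaInit,
    eps, as.integer(tmax), as.integer(fused$primary[order]) - 1L,
    as.integer(fused$partner) - 1L, traceObjective
  )
  pars <- thetaToParams(res$theta, system)
  fit <- new("ScoreFit",
    theta = res$theta, K = pars$K, eta0 = pars$eta0, eta1 = pars$eta1,
    lambda1 = lambda1, lambda2 = lambda2,
    nIter = as.integer(res$nIter), converged = res$converged,
    objective = res$objective, kktResidual = res$kkt
  )
  if (traceObjective) attr(fit, "objTrace") <- res$objTrace
  fit
}

#' Default log-linear lambda1 grid
#'
#' 100 values log-linearly spaced in [1e-6, 1], covering the path from a
#' diagonal-only to a dense interaction matrix in the benchmark designs.
#'
#' @param nLambda number of values (default 100).
#' @param range interval endpoints (default \code{c(1e-6, 1)}).
#' @export
defaultLambdaPath <- function(nLambda = 100L, range = c(1e-6, 1)) {
  exp(seq(log(range[2]), log(range[1]), length.out = nLambda))
}

#' Warm-started fits along a lambda1 path
#'
#' Lambdas are sorted to decreasing order; each fit starts from the previous
#' solution.
#'
#' @param system a \linkS4class{ScoreSystem}.
#' @param lambdas positive penalty values; with
#'   \code{scaleToLambdaMax = TRUE} they are interpreted as fractions of the
#'   smallest fully sparsifying penalty (\code{\link{lambdaMaxSparsify}}),
#'   so the default grid covers the whole sparsity range of K for any
#'   dataset dimension.
#' @param lambda2 penalty on eta coordinates (default 0).
#' @param eps,tmax solver controls (see \code{\link{cdFit}}).
#' @param scaleToLambdaMax scale the grid by the data-dependent lambda-max
#'   (default FALSE: use the grid as given).
#' @param earlyStopFull once the off-diagonal support is complete, reuse
#'   that fit for all remaining (smaller) lambdas (default FALSE).
#' @return a \linkS4class{ScoreFitPath}.
#' @export
fitPath <- function(system, lambdas = defaultLambdaPath(), lambda2 = 0,
                    eps = 1e-1, tmax = 1000L, scaleToLambdaMax = FALSE,
                    earlyStopFull = FALSE) {
  stopifnot(all(lambdas > 0))
  lambdas <- sort(unique(lambdas), decreasing = TRUE)
  if (scaleToLambdaMax) lambdas <- lambdas * lambdaMaxSparsify(system, lambda2)
  fits <- vector("list", length(lambdas))
  p <- system@p
  fullSupport <- p * (p - 1L) / 2L
  theta <- NULL
  for (i in seq_along(lambdas)) {
    fits[[i]] <- tryCatch(
      cdFit(system, lambdas[i], lambda2, thetaInit = theta,
            eps = eps, tmax = tmax),
      error = function(e) {
        stop("path fit failed at lambda1 = ", signif(lambdas[i], 4), ": ",
             conditionMessage(e))
      }
    )
    theta <- fits[[i]]@theta
    if (earlyStopFull &&
        sum(fits[[i]]@K[upper.tri(fits[[i]]@K)] != 0) == fullSupport &&
        i < length(lambdas)) {
      for (k in (i + 1L):length(lambdas)) fits[[k]] <- fits[[i]]
      break
    }
  }
  supp <- vapply(fits, function(f) {
    sum(f@K[upper.tri(f@K)] != 0)
  }, integer(1))
  new("ScoreFitPath", lambdas = lambdas, fits = fits, supportSizes = supp)
}

#' Smallest lambda1 that fully sparsifies the off-diagonal of K
#'
#' With the eta/diagonal coordinates solved at their unpenalized optimum
#' (theta restricted to the unpenalized set), the off-diagonal K subgradient
#' bound gives the smallest lambda1 for which the all-sparse solution is
#' stationary.
#'
#' @param system a \linkS4class{ScoreSystem}.
#' @param lambda2 penalty on eta (default 0); only lambda2 = 0 admits the
#'   closed-form restricted solve, otherwise a conservative bound
#'   \code{max(|g|)} is returned.
#' @export
lambdaMaxSparsify <- function(system, lambda2 = 0) {
  lay <- thetaLayout(system@p, system@hasCovariate)
  if (lambda2 > 0) return(max(abs(system@g)))
  free <- c(lay$kDiag, lay$eta0Idx, lay$eta1Idx)
  Gd <- gammaDelta(system)
  A <- as.matrix(Gd[free, free])
  b <- system@g[free]
  sol <- tryCatch(solve(A, b), error = function(e) qr.solve(A, b))
  theta <- numeric(lay$r)
  theta[free] <- sol
  grad <- as.vector(Gd %*% theta) - system@g
  max(abs(grad[lay$kOff]))
}
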