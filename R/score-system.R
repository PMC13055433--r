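# Assembly of the generalized score matching quadratic system
# (Gamma, g) for the covariate-extended power interaction model, with
# per-sample components retained for the sandwich variance estimator.
#
# The reference feature is moved to the last position internally; the score
# matching loss profiles out that coordinate (x_p = 1 - sum of the others)
# and sums weighted squared/linear terms in the first and second partial
# derivatives of the log density over coordinates j = 1..p-1. Because those
# partials are linear in theta = (vec(K), eta0, eta1), each (sample,
# coordinate) pair contributes one sparse coefficient row c (first
# derivative) and d (second derivative), and
#   Gamma = (1/n) sum h c c',   g = -(1/n) sum (h' c + h d),
# so that the empirical loss equals 1/2 theta' Gamma theta - g' theta
# exactly. Correctness is enforced by the direct-loss oracle
# (\code{\link{lossDirect}}) rather than transcribed closed forms.

#' Weight specification for generalized score matching
#'
#' The boundary weight is \eqn{\tilde h_j(x) = \min\{x_j, x_p, C_j\}^c};
#' with the defaults \eqn{C_j = 1}, \eqn{c = 2} it is
#' \eqn{\min\{x_j, x_p\}^2}, vanishing at the simplex boundary.
#'
#' @param c exponent (default 2).
#' @param Cj truncation constant (default 1).
#' @export
weightSpec <- function(c = 2, Cj = 1) {
  stopifnot(c >= 0, Cj > 0)
  structure(list(c = c, Cj = Cj), class = "weightSpec")
}

#' Evaluate the score matching weight for one coordinate
#'
#' @param x a simplex point (full length p; the profiled coordinate is the
#'   last).
#' @param j coordinate index, 1 <= j <= p - 1.
#' @param spec a \code{\link{weightSpec}}.
#' @return \eqn{\min\{x_j, x_p, C_j\}^c}.
#' @export
weightFunction <- function(x, j, spec = weightSpec()) {
  p <- length(x)
  stopifnot(j >= 1, j < p)
  min(x[j], x[p], spec$Cj)^spec$c
}

# h and its x_j-derivative for all samples at coordinate j, given columns
# xj and xp. The x_p branch carries a -1 chain factor (x_p = 1 - sum x_-p);
# ties at the kink take the x_j branch.
weightAndDeriv <- function(xj, xp, spec) {
  m <- pmin(xj, xp, spec$Cj)
  h <- m^spec$c
  dh <- numeric(length(xj))
  xjActive <- xj <= pmin(xp, spec$Cj)
  xpActive <- !xjActive & (xp <= spec$Cj)
  dh[xjActive] <- spec$c * xj[xjActive]^(spec$c - 1)
  dh[xpActive] <- -spec$c * xp[xpActive]^(spec$c - 1)
  list(h = h, dh = dh)
}

#' First and second partial derivatives of the profiled log density
#'
#' Computes \eqn{\partial_j \log p(x_{-p})} and \eqn{\partial_{jj} \log
#' p(x_{-p})} for j = 1..p-1, where the last coordinate is profiled out
#' (\eqn{x_p = 1 - \sum_{j<p} x_j}) and the covariate enters through
#' \eqn{\eta = \eta_0 + y\,\eta_1}.
#'
#' @param x simplex point (length p, reference/profiled coordinate last).
#' @param y scalar covariate.
#' @param params a \linkS4class{PowerModelParams} (in the same coordinate
#'   order as \code{x}).
#' @return list with \code{first} and \code{second}, each length p - 1.
#' @export
logDensityPartials <- function(x, y, params) {
  a <- params@a; b <- params@b
  p <- length(x)
  K <- (params@K + t(params@K)) / 2
  eta <- params@eta0 + y * params@eta1
  u <- boxcoxPower(x, a)
  t1 <- x^(a - 1)
  t2 <- (a - 1) * x^(a - 2)
  s1 <- x^(b - 1)
  s2 <- (b - 1) * x^(b - 2)
  Ku <- as.vector(K %*% u)
  j <- seq_len(p - 1L)
  first <- -Ku[j] * t1[j] + Ku[p] * t1[p] + eta[j] * s1[j] - eta[p] * s1[p]
  second <- -(diag(K)[j] * t1[j]^2 - 2 * K[j, p] * t1[j] * t1[p] +
    K[p, p] * t1[p]^2) -
    (t2[j] * Ku[j] + t2[p] * Ku[p]) +
    (eta[j] * s2[j] + eta[p] * s2[p])
  list(first = first, second = second)
}

#' Direct evaluation of the empirical score matching loss
#'
#' Brute-force oracle for the quadratic system: averages, over samples and
#' coordinates, \eqn{\tfrac12 h_j (\partial_j \log p)^2 + (\partial_j h_j)
#' (\partial_j \log p) + h_j (\partial_{jj} \log p)} using the analytic
#' partials. Equals \eqn{\tfrac12\theta^\top\Gamma\theta - g^\top\theta}
#' from \code{\link{buildScoreSystem}} for every theta.
#'
#' @param dataset a \linkS4class{CompositionData}.
#' @param params a \linkS4class{PowerModelParams} in the original feature
#'   order of \code{dataset}.
#' @param spec a \code{\link{weightSpec}}.
#' @return scalar loss value.
#' @export
lossDirect <- function(dataset, params, spec = weightSpec()) {
  X <- dataset@X
  p <- ncol(X)
  perm <- refPermutation(p, dataset@referenceIndex)
  Xp <- X[, perm, drop = FALSE]
  pp <- PowerModelParams(
    params@a, params@b, params@K[perm, perm],
    params@eta0[perm], params@eta1[perm]
  )
  y <- if (length(dataset@y)) dataset@y else rep(0, nrow(X))
  total <- 0
  for (i in seq_len(nrow(Xp))) {
    x <- Xp[i, ]
    keep <- which(x[-p] > 0 & x[p] > 0)
    if (!length(keep)) next
    d <- logDensityPartials(x, y[i], pp)
    wd <- weightAndDeriv(x[keep], rep(x[p], length(keep)), spec)
    total <- total + sum(
      0.5 * wd$h * d$first[keep]^2 + wd$dh * d$first[keep] +
        wd$h * d$second[keep]
    )
  }
  total / nrow(Xp)
}

refPermutation <- function(p, refIndex) {
  c(setdiff(seq_len(p), refIndex), refIndex)
}

#' Default diagonal multiplier
#'
#' \eqn{\delta = 2 - (1 + 4e\max\{\sqrt{6\log(p)/n},\,6\log(p)/n\})^{-1}},
#' applied to the Gamma diagonal entries of the vec(K) block to keep the
#' high-dimensional penalized problem bounded.
#'
#' The multiplier perturbs the estimating equations and therefore biases
#' the estimator at finite n (it tends to 1 as n grows). When the system
#' is comfortably overdetermined (\eqn{n(p-1) \ge 2r}) the quadratic loss
#' is already bounded and \code{\link{buildScoreSystem}}'s "auto" rule
#' uses \eqn{\delta = 1} instead; the inflation formula is reserved for
#' the high-dimensional regime it was designed for.
#'
#' @param n,p sample and feature counts.
#' @export
autoDelta <- function(n, p) {
  m <- max(sqrt(6 * log(p) / n), 6 * log(p) / n)
  2 - 1 / (1 + 4 * exp(1) * m)
}

resolveDelta <- function(delta, n, p, hasCov) {
  if (!identical(delta, "auto")) return(delta)
  if (n * (p - 1) >= 2 * nTheta(p, hasCov)) 1 else autoDelta(n, p)
}

#' Build the score matching quadratic system
#'
#' Assembles Gamma and g (and retains per-sample coefficient rows) for the
#' covariate-extended power interaction model at powers (a, b). Stacked
#' coordinate rows with zero weight (x_j = 0 or x_ref = 0) contribute
#' nothing and are zeroed out; zeros are therefore only admissible when
#' a > 0 and b > 0.
#'
#' @param dataset a \linkS4class{CompositionData}; its covariate (if any)
#'   determines whether eta1 coordinates are included.
#' @param a,b nonnegative power exponents.
#' @param spec a \code{\link{weightSpec}}.
#' @param delta diagonal multiplier (> 1) or "auto" for
#'   \code{\link{autoDelta}}.
#' @param keepPerSample retain the stacked per-sample components needed by
#'   \code{\link{sandwichCovariance}} (default TRUE; set FALSE for large p
#'   to save memory).
#' @param memoryGuard refuse p above this bound (dense path storage grows
#'   as (p^2 + 2p)^2); default 150.
#' @return a \linkS4class{ScoreSystem}.
#' @examples
#' cd <- CompositionData(rDirichletMatrix(20, rep(2, 4), seed = 1),
#'   y = rep(0:1, 10))
#' sys <- buildScoreSystem(cd, a = 0, b = 0)
#' sys
#' @export
buildScoreSystem <- function(dataset, a, b, spec = weightSpec(),
                             delta = "auto", keepPerSample = TRUE,
                             memoryGuard = 150L) {
  X <- dataset@X
  n <- nrow(X); p <- ncol(X)
  if (p > memoryGuard) {
    stop(
      "p = ", p, " exceeds the memory guard (", memoryGuard, "); ",
      "filter features before model fitting or raise memoryGuard"
    )
  }
  if ((a == 0 || b == 0) && any(X == 0)) {
    stop(
      "zero entries with a = 0 or b = 0; use positive powers or construct ",
      "the dataset with a pseudocount (e.g. pseudocount = 0.5)"
    )
  }
  hasCov <- length(dataset@y) > 0L
  y <- if (hasCov) dataset@y else numeric(0)
  perm <- refPermutation(p, dataset@referenceIndex)
  Xp <- X[, perm, drop = FALSE]
  lay <- thetaLayout(p, hasCov)
  r <- lay$r

  # assemble the stacked coefficient rows for a subset of samples
  assembleRows <- function(idx) {
    Xs <- Xp[idx, , drop = FALSE]
    ys <- if (hasCov) y[idx] else NULL
    ns <- length(idx)
    U <- boxcoxPower(pmax(Xs, 0), a) # zeros allowed only when a > 0
    T1 <- Xs^(a - 1)
    T2 <- (a - 1) * Xs^(a - 2)
    S1 <- Xs^(b - 1)
    S2 <- (b - 1) * Xs^(b - 2)
    xp <- Xs[, p]
    up <- U[, p]; tp <- T1[, p]; t2p <- T2[, p]
    sp <- S1[, p]; s2p <- S2[, p]
    kcol <- function(m, l) (l - 1L) * p + m
    nK <- 4L * (p - 2L) + 4L
    Lj <- nK + (if (hasCov) 4L else 2L)
    iList <- jList <- vCList <- vDList <- vector("list", p - 1L)
    hAll <- dhAll <- numeric(ns * (p - 1L))
    for (j in seq_len(p - 1L)) {
      oth <- setdiff(seq_len(p), c(j, p))
      xj <- Xs[, j]
      uj <- U[, j]; tj <- T1[, j]; t2j <- T2[, j]
      sj <- S1[, j]; s2j <- S2[, j]
      wd <- weightAndDeriv(xj, xp, spec)
      mask <- (xj == 0) | (xp == 0)
      wd$h[mask] <- 0; wd$dh[mask] <- 0
      cols <- c(
        kcol(j, oth), kcol(oth, j), kcol(p, oth), kcol(oth, p),
        kcol(j, j), kcol(p, p), kcol(j, p), kcol(p, j),
        p^2 + j, p^2 + p,
        if (hasCov) c(p^2 + p + j, p^2 + 2L * p)
      )
      Uoth <- U[, oth, drop = FALSE]
      crossJP <- 0.5 * (-tj * up + tp * uj)
      Vc <- cbind(
        -0.5 * tj * Uoth, -0.5 * Uoth * tj,
        0.5 * tp * Uoth, 0.5 * Uoth * tp,
        -tj * uj, tp * up, crossJP, crossJP,
        sj, -sp,
        if (hasCov) cbind(ys * sj, -ys * sp)
      )
      crossD <- -0.5 * (t2j * up + t2p * uj) + tj * tp
      Vd <- cbind(
        -0.5 * t2j * Uoth, -0.5 * Uoth * t2j,
        -0.5 * t2p * Uoth, -0.5 * Uoth * t2p,
        -(t2j * uj + tj^2), -(t2p * up + tp^2), crossD, crossD,
        s2j, s2p,
        if (hasCov) cbind(ys * s2j, ys * s2p)
      )
      if (any(mask)) {
        Vc[mask, ] <- 0
        Vd[mask, ] <- 0
      }
      if (any(!is.finite(Vc)) || any(!is.finite(Vd))) {
        bad <- which(!is.finite(Vc) | !is.finite(Vd), arr.ind = TRUE)
        stop(
          "non-finite score system entries at feature '",
          colnames(Xp)[j], "' (extreme powers/abundances); sample ",
          idx[bad[1, 1]]
        )
      }
      rows <- (j - 1L) * ns + seq_len(ns)
      iList[[j]] <- rep(rows, times = Lj)
      jList[[j]] <- rep(cols, each = ns)
      vCList[[j]] <- as.vector(Vc)
      vDList[[j]] <- as.vector(Vd)
      hAll[rows] <- wd$h
      dhAll[rows] <- wd$dh
    }
    Ns <- ns * (p - 1L)
    ii <- unlist(iList); jj <- unlist(jList)
    list(
      C = Matrix::sparseMatrix(i = ii, j = jj, x = unlist(vCList),
        dims = c(Ns, r)),
      D = Matrix::sparseMatrix(i = ii, j = jj, x = unlist(vDList),
        dims = c(Ns, r)),
      h = hAll, dh = dhAll, N = Ns
    )
  }

  if (keepPerSample) {
    blk <- assembleRows(seq_len(n))
    C <- blk$C; D <- blk$D
    hAll <- blk$h; dhAll <- blk$dh
    rowSample <- rep(seq_len(n), times = p - 1L)
    Cw <- Matrix::Diagonal(blk$N, sqrt(hAll / n)) %*% C
    Gamma <- Matrix::crossprod(Cw)
    g <- -as.vector(Matrix::crossprod(C, dhAll) +
      Matrix::crossprod(D, hAll)) / n
  } else {
    # chunked accumulation keeps memory bounded for large n * p
    chunk <- max(1L, as.integer(4e6 / ((p - 1) * (4 * p + 8))))
    Gamma <- NULL
    g <- numeric(r)
    start <- 1L
    while (start <= n) {
      idx <- start:min(start + chunk - 1L, n)
      blk <- assembleRows(idx)
      Cw <- Matrix::Diagonal(blk$N, sqrt(blk$h / n)) %*% blk$C
      Gpart <- Matrix::crossprod(Cw)
      Gamma <- if (is.null(Gamma)) Gpart else Gamma + Gpart
      g <- g - as.vector(Matrix::crossprod(blk$C, blk$dh) +
        Matrix::crossprod(blk$D, blk$h)) / n
      start <- start + chunk
    }
    C <- D <- NULL
    hAll <- dhAll <- numeric(0)
    rowSample <- integer(0)
  }
  Gamma <- as(as(Gamma, "generalMatrix"), "CsparseMatrix")

  delta <- resolveDelta(delta, n, p, hasCov)
  stopifnot(is.numeric(delta), delta >= 1)

  new("ScoreSystem",
    Gamma = Gamma, g = g, delta = as.numeric(delta),
    a = as.numeric(a), b = as.numeric(b), n = as.integer(n), p = as.integer(p),
    hasCovariate = hasCov, y = y,
    refIndex = dataset@referenceIndex, perm = as.integer(perm),
    Cmat = if (keepPerSample) C else NULL,
    Dmat = if (keepPerSample) D else NULL,
    h = if (keepPerSample) hAll else numeric(0),
    hprime = if (keepPerSample) dhAll else numeric(0),
    rowSample = if (keepPerSample) as.integer(rowSample) else integer(0),
    featureNames = colnames(X)
  )
}

#' @rdname gammaDelta
#' @export
setMethod("gammaDelta", "ScoreSystem", function(object) {
  lay <- thetaLayout(object@p, object@hasCovariate)
  G <- object@Gamma
  d <- Matrix::diag(G)
  d[lay$kIdx] <- d[lay$kIdx] * object@delta
  Matrix::diag(G) <- d
  G
})

# Multiplier on Gamma[s,s] per coordinate (delta on all p^2 vec(K) coords).
diagMultiplier <- function(system) {
  lay <- thetaLayout(system@p, system@hasCovariate)
  dm <- rep(1, lay$r)
  dm[lay$kIdx] <- system@delta
  dm
}

#' Quadratic score matching loss at a given theta
#'
#' \eqn{\tfrac12\theta^\top\Gamma\theta - g^\top\theta}; with
#' \code{useDelta = TRUE} the optimizer's diagonal-multiplied Gamma is used.
#'
#' @param system a \linkS4class{ScoreSystem}.
#' @param theta coefficient vector (internal order; see
#'   \code{\link{thetaFromFit}}).
#' @param useDelta use the delta-scaled diagonal (default FALSE: the plain
#'   divergence).
#' @export
quadLoss <- function(system, theta, useDelta = FALSE) {
  G <- if (useDelta) gammaDelta(system) else system@Gamma
  0.5 * sum(theta * as.vector(G %*% theta)) - sum(system@g * theta)
}

# Per-sample aggregated (Gamma_i, g_i) as dense matrices -- only sensible
# for small p; used by tests of the per-sample mean identity.
perSampleComponents <- function(system, i) {
  if (is.null(system@Cmat)) stop("per-sample components were not retained")
  rows <- which(system@rowSample == i)
  Ci <- system@Cmat[rows, , drop = FALSE]
  Di <- system@Dmat[rows, , drop = FALSE]
  hi <- system@h[rows]; dhi <- system@hprime[rows]
  Gi <- as.matrix(Matrix::crossprod(Ci * sqrt(hi), Ci * sqrt(hi)))
  gi <- -as.vector(Matrix::crossprod(Ci, dhi) + Matrix::crossprod(Di, hi))
  list(Gamma = Gi, g = gi)
}

#' Map a fitted theta back to (K, eta0, eta1) in the original feature order
#'
#' @param theta coefficient vector in the system's internal order.
#' @param system the \linkS4class{ScoreSystem} it was fitted on.
#' @param symmetrize symmetrize K on output (default TRUE).
#' @export
thetaToParams <- function(theta, system, symmetrize = TRUE) {
  p <- system@p
  lay <- thetaLayout(p, system@hasCovariate)
  Kint <- matrix(theta[lay$kIdx], p, p)
  if (symmetrize) Kint <- (Kint + t(Kint)) / 2
  inv <- order(system@perm)
  K <- Kint[inv, inv]
  eta0 <- theta[lay$eta0Idx][inv]
  eta1 <- if (system@hasCovariate) theta[lay$eta1Idx][inv] else numeric(0)
  dimnames(K) <- list(system@featureNames, system@featureNames)
  names(eta0) <- system@featureNames
  if (length(eta1)) names(eta1) <- system@featureNames
  list(K = K, eta0 = eta0, eta1 = eta1)
}

#' Internal-order theta from parameters in original feature order
#'
#' @param params a \linkS4class{PowerModelParams} in original order.
#' @param system the target \linkS4class{ScoreSystem}.
#' @export
thetaFromFit <- function(params, system) {
  perm <- system@perm
  th <- c(
    as.vector(params@K[perm, perm]),
    params@eta0[perm]
  )
  if (system@hasCovariate) th <- c(th, params@eta1[perm])
  th
}
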