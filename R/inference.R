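# Differential abundance inference: sandwich covariance of the score
# matching estimator, studentized statistics on eta1, t(n-3) p-values,
# Benjamini-Hochberg adjustment.

#' Sandwich covariance of the penalized score matching estimator
#'
#' Estimates \eqn{\widehat\Sigma_0 = \tfrac1n\sum_i \psi_i\psi_i^\top} with
#' per-sample scores \eqn{\psi_i = \tilde\Gamma_\delta^{(i)}\hat\theta -
#' \tilde g^{(i)}}, and returns the M-estimation variance
#' \eqn{\widehat S = \Gamma^{-1}\widehat\Sigma_0\Gamma^{-1}/n}. The outer
#' inverse uses the unscaled Gamma (delta is an optimization device); set
#' \code{useDelta = TRUE} for the delta-scaled variant. When the condition
#' number of Gamma exceeds \code{condMax} a ridge jitter of
#' \code{1e-8 * trace / r} is added to the diagonal.
#'
#' @param system a \linkS4class{ScoreSystem} built with
#'   \code{keepPerSample = TRUE}.
#' @param theta estimated coefficient vector (internal order), or a
#'   \linkS4class{ScoreFit}.
#' @param useDelta use the delta-scaled Gamma in the outer inverse.
#' @param condMax condition-number threshold triggering the jitter
#'   (default 1e12).
#' @return dense r x r covariance matrix of theta-hat.
#' @export
sandwichCovariance <- function(system, theta, useDelta = FALSE,
                               condMax = 1e12) {
  if (is(theta, "ScoreFit")) theta <- theta@theta
  if (is.null(system@Cmat)) {
    stop("per-sample components unavailable; rebuild with keepPerSample = TRUE")
  }
  n <- system@n
  lay <- thetaLayout(system@p, system@hasCovariate)
  N <- length(system@h)

  Ct <- as.vector(system@Cmat %*% theta)
  z <- system@h * Ct
  Ind <- Matrix::sparseMatrix(
    i = seq_len(N), j = system@rowSample, x = 1, dims = c(N, n)
  )
  # per-sample Gamma_i theta (un-scaled) and g_i, as r x n matrices
  GiTheta <- as.matrix(Matrix::crossprod(system@Cmat, Ind * z))
  Gi <- as.matrix(
    Matrix::crossprod(system@Cmat, Ind * system@hprime) +
      Matrix::crossprod(system@Dmat, Ind * system@h)
  )
  gMat <- -Gi
  # per-sample delta adjustment: (delta - 1) * diag_K(Gamma_i) * theta
  C2 <- system@Cmat
  C2@x <- C2@x^2
  diagK <- as.matrix(Matrix::crossprod(C2, Ind * system@h))[lay$kIdx, ,
    drop = FALSE
  ]
  Psi <- GiTheta - gMat
  Psi[lay$kIdx, ] <- Psi[lay$kIdx, ] +
    (system@delta - 1) * diagK * theta[lay$kIdx]

  Sigma0 <- tcrossprod(Psi) / n
  G <- as.matrix(if (useDelta) gammaDelta(system) else system@Gamma)

  # The mirrored vec(K) coordinates carry structurally identical Gamma
  # columns, so the full Jacobian is always singular along antisymmetric
  # directions; the estimator lives on the symmetric subspace, and the
  # sandwich is computed there (fused basis) and mapped back. Unfused
  # (eta) coordinates are unaffected by the change of basis.
  fused <- fusedLayout(system@p, system@hasCovariate)
  rF <- length(fused$primary)
  M <- Matrix::sparseMatrix(
    i = seq_along(fused$partner),
    j = match(pmax(seq_along(fused$partner), fused$partner), fused$primary),
    x = 1, dims = c(length(fused$partner), rF)
  )
  M <- as.matrix(M)
  A <- crossprod(M, G %*% M)
  SigF <- crossprod(M, Sigma0 %*% M)
  kap <- kappa(A, exact = FALSE)
  if (!is.finite(kap) || kap > condMax) {
    A <- A + diag(1e-8 * sum(diag(A)) / nrow(A), nrow(A))
    kap2 <- kappa(A, exact = FALSE)
    if (!is.finite(kap2) || kap2 > 1e3 * condMax) {
      stop(
        "Gamma numerically singular beyond jitter tolerance; ",
        "use stronger regularization or more samples"
      )
    }
  }
  Ainv <- solve(A)
  M %*% (Ainv %*% SigF %*% Ainv) %*% t(M) / n
}

#' Studentized differential abundance test on eta1
#'
#' For each non-reference feature j, \eqn{T_j = \hat\eta_{1,j} /
#' \sqrt{\widehat S_{\eta_{1,j}}}}; two-sided p-values from the
#' t-distribution with n - 3 degrees of freedom, adjusted across features
#' by Benjamini-Hochberg. The profiled-out reference feature carries no
#' test.
#'
#' @param fit a \linkS4class{ScoreFit} from a covariate system (or an
#'   internal-order theta vector).
#' @param Shat sandwich covariance from \code{\link{sandwichCovariance}}.
#' @param system the \linkS4class{ScoreSystem} used for the fit.
#' @return a \linkS4class{DAResults}.
#' @export
daTest <- function(fit, Shat, system) {
  if (!system@hasCovariate) stop("system has no covariate; nothing to test")
  n <- system@n
  if (n <= 3L) stop("need n > 3 samples for the t(n-3) reference")
  lay <- thetaLayout(system@p, system@hasCovariate)
  theta <- if (is(fit, "ScoreFit")) fit@theta else fit
  eta1Int <- theta[lay$eta1Idx]
  v <- diag(Shat)[lay$eta1Idx]
  p <- system@p
  perm <- system@perm
  eta1 <- se <- numeric(p)
  eta1[perm] <- eta1Int
  vOrig <- numeric(p)
  vOrig[perm] <- v
  ref <- system@refIndex
  testIdx <- setdiff(seq_len(p), ref)
  if (any(vOrig[testIdx] <= 0)) {
    stop(
      "nonpositive variance estimate for feature(s) ",
      paste(system@featureNames[testIdx][vOrig[testIdx] <= 0], collapse = ", "),
      "; sandwich estimator failed"
    )
  }
  se <- sqrt(pmax(vOrig, 0))
  tStat <- rep(NA_real_, p)
  tStat[testIdx] <- eta1[testIdx] / se[testIdx]
  pRaw <- rep(NA_real_, p)
  pRaw[testIdx] <- 2 * pt(-abs(tStat[testIdx]), df = n - 3)
  pAdj <- rep(NA_real_, p)
  pAdj[testIdx] <- bhAdjust(pRaw[testIdx])
  tab <- data.frame(
    feature = system@featureNames,
    eta1_hat = eta1, se = se, t = tStat,
    p_raw = pRaw, p_adj = pAdj,
    is_reference = seq_len(p) == ref,
    stringsAsFactors = FALSE
  )
  new("DAResults",
    table = tab, n = n, df = as.integer(n - 3),
    referenceFeature = system@featureNames[ref]
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values, capped at one and monotone in rank.
#'
#' @param p vector of p-values in [0, 1].
#' @export
bhAdjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must be finite and in [0, 1]")
  }
  p.adjust(p, method = "BH")
}
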