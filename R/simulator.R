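# Ground-truth parameter generators and samplers for the power interaction
# model: banded interaction matrices, exact ALR-Gaussian sampling for the
# log-based subfamily, and a pairwise Gibbs sampler for the general case;
# plus the interaction-recovery and two-group differential abundance
# scenario generators.

#' Banded ground-truth interaction matrix
#'
#' Off-diagonal entries \eqn{K_{ij} = |i-j|/(s+1) - 1} for \eqn{1 \le |i-j|
#' \le s} (negative), zero outside the band, and diagonal entries equal to
#' the negative off-diagonal row sums, so that \eqn{K 1_p = 0}. The matrix
#' is symmetric, diagonally dominant and positive semidefinite.
#'
#' @param p dimension; @param s bandwidth, 1 <= s <= p - 1.
#' @export
bandedInteractionMatrix <- function(p, s) {
  stopifnot(s >= 1, s <= p - 1)
  K <- matrix(0, p, p)
  for (d in seq_len(s)) {
    v <- d / (s + 1) - 1
    idx <- seq_len(p - d)
    K[cbind(idx, idx + d)] <- v
    K[cbind(idx + d, idx)] <- v
  }
  diag(K) <- -rowSums(K)
  K
}

#' Block-diagonal tiling of a base interaction matrix
#'
#' Repeats K along the diagonal; the row sum-to-zero constraint is
#' preserved. Used to scale the p = 11 scenario parameters up to p = 99.
#'
#' @param K base matrix; @param times number of diagonal blocks.
#' @export
tileBlockDiagonal <- function(K, times) {
  p <- nrow(K)
  out <- matrix(0, p * times, p * times)
  for (t in seq_len(times)) {
    idx <- (t - 1) * p + seq_len(p)
    out[idx, idx] <- K
  }
  out
}

#' Random Dirichlet matrix
#'
#' @param n rows; @param alpha concentration vector; @param seed optional.
#' @export
rDirichletMatrix <- function(n, alpha, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- length(alpha)
  G <- matrix(stats::rgamma(n * p, shape = rep(alpha, each = n)), n, p)
  G / rowSums(G)
}

# Exact sampler for the log-based subfamily: with a = b = 0, K 1p = 0 and
# 1p' eta = -p, the model density in ALR coordinates w_j = log(x_j / x_p)
# is exactly Gaussian, w ~ N(Ktil^-1 (eta_-p + 1), Ktil^-1) with
# Ktil = K[-p, -p] (see the methods vignette for the derivation). Returns
# NULL when the preconditions fail.
alrGaussianSample <- function(n, K, eta, tol = 1e-8) {
  p <- length(eta)
  if (max(abs(K %*% rep(1, p))) > tol) return(NULL)
  if (abs(sum(eta) + p) > tol) return(NULL)
  Ktil <- K[-p, -p, drop = FALSE]
  R <- tryCatch(chol(Ktil), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  mu <- backsolve(R, backsolve(R, eta[-p] + 1, transpose = TRUE))
  Z <- matrix(rnorm(n * (p - 1)), n, p - 1)
  W <- Z %*% t(solve(R)) + matrix(mu, n, p - 1, byrow = TRUE)
  Wfull <- cbind(W, 0)
  Wfull <- Wfull - apply(Wfull, 1, max)
  E <- exp(Wfull)
  E / rowSums(E)
}

#' Draw samples from the (covariate-extended) power interaction model
#'
#' Exact sampling is used where available: for a = b = 0 with
#' \eqn{K 1_p = 0} and \eqn{1_p^\top\eta = -p} the model is a logistic
#' normal in ALR coordinates. Otherwise a pairwise Gibbs sampler runs
#' parallel chains (one per requested draw by default): each sweep
#' redistributes mass within disjoint random coordinate pairs, drawing the
#' univariate conditional by griddy inverse-CDF on \code{gridSize}
#' midpoints with within-bin jitter. Chains are warm-started from the
#' ALR-Gaussian approximation when the interaction matrix admits it.
#'
#' @param n number of draws.
#' @param params a \linkS4class{PowerModelParams}.
#' @param y covariate values (scalar, length-n vector, or NULL for the
#'   covariate-less model).
#' @param seed optional RNG seed.
#' @param method "auto" (default), "exact" or "gibbs".
#' @param burnIn Gibbs burn-in sweeps (default 1000).
#' @param thin sweeps between harvested states when running fewer chains
#'   than draws (default 10).
#' @param chains number of parallel chains (default \code{n}: one draw per
#'   chain after burn-in).
#' @param gridSize conditional grid size (default 256).
#' @param validate check the propriety conditions before sampling
#'   (default TRUE).
#' @return n x p matrix with rows on the simplex.
#' @export
samplePowerInteraction <- function(n, params, y = NULL, seed = NULL,
                                   method = c("auto", "exact", "gibbs"),
                                   burnIn = 1000L, thin = 10L, chains = NULL,
                                   gridSize = 256L, validate = TRUE) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  p <- length(params@eta0)
  if (is.null(y)) y <- 0
  if (length(y) == 1L) y <- rep(y, n)
  stopifnot(length(y) == n)
  if (validate) {
    vr <- validateParams(params, range(y))
    if (!vr$is_valid) {
      stop(
        "improper model parameters (case ", vr$case_label, "): ",
        paste(vr$violated_conditions, collapse = "; ")
      )
    }
  }
  Eta <- matrix(params@eta0, n, p, byrow = TRUE) + y * matrix(params@eta1,
    n, p, byrow = TRUE)

  if (method != "gibbs" && params@a == 0 && params@b == 0) {
    groups <- split(seq_len(n), y)
    Xout <- matrix(NA_real_, n, p)
    ok <- TRUE
    for (g in groups) {
      Xg <- alrGaussianSample(length(g), params@K, Eta[g[1], ])
      if (is.null(Xg)) { ok <- FALSE; break }
      Xout[g, ] <- Xg
    }
    if (ok) return(Xout)
    if (method == "exact") {
      stop(
        "exact sampling requires a = b = 0, K 1p = 0, sum(eta) = -p and ",
        "a positive definite K[-p, -p]"
      )
    }
  }

  # Gibbs route
  nChains <- if (is.null(chains)) n else min(chains, n)
  X0 <- gibbsInit(nChains, params@K, Eta[seq_len(nChains), , drop = FALSE])
  X <- gibbs_simplex(X0, params@K, Eta[seq_len(nChains), , drop = FALSE],
    params@a, params@b, as.integer(burnIn), as.integer(gridSize))
  if (nChains == n) return(X)
  out <- matrix(NA_real_, n, p)
  got <- 0L
  take <- min(nChains, n)
  out[seq_len(take), ] <- X[seq_len(take), ]
  got <- take
  while (got < n) {
    X <- gibbs_simplex(X, params@K, Eta[seq_len(nChains), , drop = FALSE],
      params@a, params@b, as.integer(thin), as.integer(gridSize))
    take <- min(nChains, n - got)
    out[got + seq_len(take), ] <- X[seq_len(take), ]
    got <- got + take
  }
  out
}

# Chain initialization: ALR-Gaussian approximation (ignoring the reference
# tilt) when K[-p,-p] is positive definite, uniform Dirichlet otherwise.
gibbsInit <- function(nChains, K, Eta) {
  p <- ncol(Eta)
  Ktil <- K[-p, -p, drop = FALSE]
  R <- tryCatch(chol(Ktil), error = function(e) NULL)
  if (!is.null(R)) {
    Z <- matrix(rnorm(nChains * (p - 1)), nChains, p - 1)
    Mu <- t(backsolve(R, backsolve(R, t(Eta[, -p, drop = FALSE] + 1),
      transpose = TRUE)))
    W <- cbind(Z %*% t(solve(R)) + Mu, 0)
    W <- W - apply(W, 1, max)
    E <- exp(W)
    E / rowSums(E)
  } else {
    rDirichletMatrix(nChains, rep(1, p))
  }
}

#' Effect-size grid of the differential abundance benchmark
#' @export
daTauGrid <- function() c(-0.5, -0.3, 0.3, 0.5, 1)

#' Synthetic base parameters for the p = 11 differential abundance scenarios
#'
#' A synthetic stand-in for base parameters estimated from real cell-type
#' compositions: a banded interaction matrix (bandwidth 2) plus a
#' centered-projection ridge \eqn{0.5 (I - J/p)} that keeps the row sums at
#' zero while bounding the log-ratio variances, and a heterogeneous
#' location vector \eqn{\eta_0 = -1_p + 0.4\sin(2\pi j / p)} whose
#' perturbation sums to zero. The implied ALR moments (means within
#' about \eqn{\pm 1}, standard deviations near 1, neighbour correlations
#' 0.6-0.8) are typical of cell-type composition data; without the ridge
#' the banded matrix is nearly singular off the constant direction and the
#' compositions degenerate to extreme ratios.
#'
#' @param p number of features (default 11).
#' @export
daScenarioBase <- function(p = 11L) {
  j <- seq_len(p)
  ridge <- 0.5 * (diag(p) - matrix(1 / p, p, p))
  list(
    K = bandedInteractionMatrix(p, 2L) + ridge,
    eta0 = -1 + 0.4 * sin(2 * pi * j / p)
  )
}

#' Generate a two-group semi-synthetic differential abundance scenario
#'
#' n/2 control samples from (K, eta0) and n/2 case samples from
#' (K, eta0 + eta1) with \eqn{\eta_1 = \tau\, i \odot \eta_0}, where i
#' indicates the affected features and tau scales the relative effect.
#'
#' @param n total sample count (even).
#' @param tau relative effect size (see \code{\link{daTauGrid}}; tau = 0 is
#'   the null scenario).
#' @param targetFeatures indices of the differentially abundant features.
#' @param baseK,baseEta0 base parameters (default
#'   \code{\link{daScenarioBase}}).
#' @param seed RNG seed.
#' @param referenceIndex reference feature for downstream fitting (default
#'   last).
#' @param burnIn,gridSize Gibbs controls for the case group (default 400 /
#'   256; the control group is sampled exactly).
#' @return list with \code{dataset} (a \linkS4class{CompositionData} with a
#'   binary covariate), \code{truth} (logical per feature), \code{params},
#'   \code{tau}.
#' @export
makeDAScenario <- function(n, tau, targetFeatures, baseK = NULL,
                           baseEta0 = NULL, seed = NULL,
                           referenceIndex = NULL, burnIn = 400L,
                           gridSize = 256L) {
  if (n %% 2L != 0L) stop("n must be even for the equal two-group split")
  base <- daScenarioBase()
  if (is.null(baseK)) baseK <- base$K
  if (is.null(baseEta0)) baseEta0 <- base$eta0
  p <- length(baseEta0)
  if (is.null(referenceIndex)) referenceIndex <- p
  ind <- rep(0, p)
  ind[targetFeatures] <- 1
  eta1 <- tau * ind * baseEta0
  params <- PowerModelParams(0, 0, baseK, baseEta0, eta1)
  if (!is.null(seed)) set.seed(seed)
  y <- rep(c(0, 1), each = n / 2)
  X <- samplePowerInteraction(n, params, y = y, burnIn = burnIn,
    gridSize = gridSize)
  truth <- ind == 1 & tau != 0
  list(
    dataset = CompositionData(X, y = y, referenceIndex = referenceIndex,
      normalize = FALSE),
    truth = truth, params = params, tau = tau
  )
}

#' Generate replicate datasets for the interaction-recovery benchmark
#'
#' Compositional data from the log-based model (a = b = 0) with a banded
#' interaction matrix and \eqn{\eta_0 = -1_p}; this parameter combination is
#' exactly a logistic normal, so sampling is exact. Optionally attaches a
#' misspecified binary covariate (entries uniform on \{0, 1\}) that plays
#' no role in data generation.
#'
#' @param p features (default 100); @param n samples per replicate.
#' @param s bandwidth (2 for the low-n design, 7 for the high-n design).
#' @param R replicates (default 50).
#' @param seed RNG seed.
#' @param covariate "none" or "binary" (misspecified, fitting only).
#' @return list with \code{datasets} (list of
#'   \linkS4class{CompositionData}), \code{Ktrue}, \code{params}.
#' @export
makeRecoveryBenchmark <- function(p = 100L, n = 80L, s = 2L, R = 50L,
                                  seed = 1L,
                                  covariate = c("none", "binary")) {
  covariate <- match.arg(covariate)
  K <- bandedInteractionMatrix(p, s)
  params <- PowerModelParams(0, 0, K, rep(-1, p))
  set.seed(seed)
  datasets <- vector("list", R)
  for (r in seq_len(R)) {
    X <- samplePowerInteraction(n, params, validate = FALSE)
    y <- if (covariate == "binary") sample(c(0, 1), n, replace = TRUE) else NULL
    datasets[[r]] <- CompositionData(X, y = y, normalize = FALSE)
  }
  list(datasets = datasets, Ktrue = K, params = params, seed = seed)
}
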