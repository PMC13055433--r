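#' @useDynLib scoreDA, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats coef cov p.adjust pt qnorm rnorm runif sd setNames t.test var
#' @importFrom utils head read.csv read.delim write.table packageVersion
NULL

#' CompositionData: samples on the probability simplex with one covariate
#'
#' Container for an n x p relative-abundance matrix whose rows lie on the
#' (p-1)-dimensional probability simplex, an optional per-sample covariate
#' (binary group indicator coded 0/1, or continuous), and a designated
#' reference feature that is profiled out of the model.
#'
#' @slot X numeric matrix, n x p, nonnegative rows summing to one.
#' @slot y numeric vector of length n (covariate) or length 0 (no covariate).
#' @slot referenceIndex integer in \code{[1, p]}; the profiled-out feature.
#'
#' @details Count input should be converted to relative abundances with
#' \code{\link{CompositionData}} (\code{normalize = TRUE}), which divides each
#' row by its library size. Feature names are kept as column names of
#' \code{X}. For models with \code{a = 0} or \code{b = 0} the reference
#' column must be strictly positive.
#'
#' @seealso \code{\link{CompositionData}}, \code{\link{buildScoreSystem}}
#' @export
setClass("CompositionData",
  representation(
    X = "matrix",
    y = "numeric",
    referenceIndex = "integer"
  )
)

setValidity("CompositionData", function(object) {
  X <- object@X
  msg <- character()
  if (!is.numeric(X)) msg <- c(msg, "X must be numeric")
  if (ncol(X) < 3L) msg <- c(msg, "need at least p = 3 features")
  if (nrow(X) < 1L) msg <- c(msg, "need at least one sample")
  if (any(X < 0)) msg <- c(msg, "negative entries in X")
  rs <- rowSums(X)
  if (any(abs(rs - 1) > 1e-8)) {
    msg <- c(msg, sprintf(
      "row sums deviate from 1 by up to %.3g; construct with normalize = TRUE",
      max(abs(rs - 1))
    ))
  }
  if (length(object@y) && length(object@y) != nrow(X)) {
    msg <- c(msg, "covariate length must equal the number of samples")
  }
  ri <- object@referenceIndex
  if (length(ri) != 1L || is.na(ri) || ri < 1L || ri > ncol(X)) {
    msg <- c(msg, "referenceIndex out of range")
  }
  if (length(msg)) msg else TRUE
})

#' PowerModelParams: parameters of the covariate-extended power interaction model
#'
#' Holds the power exponents (a, b), the symmetric p x p interaction matrix K,
#' and the location vectors eta0 and eta1 of the model
#' \deqn{p(x) \propto \exp\{-\tfrac12 u_a(x)^\top K u_a(x) +
#'   (\eta_0 + y\,\eta_1)^\top u_b(x)\},}
#' where \eqn{u_c(x) = (x^c - 1)/c} elementwise (\eqn{\log x} at \eqn{c = 0}).
#'
#' @slot a,b nonnegative power exponents.
#' @slot K p x p symmetric interaction matrix.
#' @slot eta0,eta1 length-p location vectors (eta1 may be all zero for a
#'   covariate-less model).
#'
#' @details Ground-truth parameters satisfy the sum-to-zero row constraint
#' \eqn{K 1_p = 0_p}; estimates are symmetrized but not projected onto that
#' constraint. See \code{\link{validateParams}} for the propriety conditions.
#' @export
setClass("PowerModelParams",
  representation(
    a = "numeric", b = "numeric",
    K = "matrix", eta0 = "numeric", eta1 = "numeric"
  )
)

setValidity("PowerModelParams", function(object) {
  msg <- character()
  p <- length(object@eta0)
  if (length(object@a) != 1L || object@a < 0) msg <- c(msg, "a must be a scalar >= 0")
  if (length(object@b) != 1L || object@b < 0) msg <- c(msg, "b must be a scalar >= 0")
  if (!all(dim(object@K) == c(p, p))) msg <- c(msg, "K must be p x p")
  else if (max(abs(object@K - t(object@K))) > 1e-8 * max(1, max(abs(object@K)))) {
    msg <- c(msg, "K must be symmetric (within tolerance)")
  }
  if (length(object@eta1) != p) msg <- c(msg, "eta1 must have length p")
  if (length(msg)) msg else TRUE
})

#' ScoreSystem: the quadratic generalized score matching system
#'
#' The empirical score matching loss of the (covariate-extended) power
#' interaction model is the quadratic \eqn{\hat L(\theta) = \tfrac12
#' \theta^\top \Gamma \theta - g^\top \theta} in
#' \eqn{\theta = (\mathrm{vec}(K), \eta_0, \eta_1)}. This class stores the
#' aggregated \eqn{\Gamma} (sparse, r x r with \eqn{r = p^2 + 2p}, or
#' \eqn{p^2 + p} without covariate) and \eqn{g}, the diagonal multiplier
#' \eqn{\delta}, and (optionally) the stacked per-sample coefficient matrices
#' needed by the sandwich variance estimator.
#'
#' @slot Gamma sparse symmetric r x r matrix (\code{dgCMatrix}).
#' @slot g numeric length-r vector.
#' @slot delta diagonal multiplier (> 1) applied to the p^2 Gamma diagonal
#'   entries of the vec(K) block during optimization.
#' @slot a,b power exponents used to build the system.
#' @slot n,p sample and feature counts.
#' @slot hasCovariate logical; whether eta1 coordinates are present.
#' @slot y covariate vector (length n, or 0).
#' @slot refIndex reference feature index in the original column order.
#' @slot perm integer permutation mapping original columns to internal order
#'   (reference last).
#' @slot Cmat,Dmat stacked first/second-derivative coefficient rows (sparse,
#'   n(p-1) x r) or NULL when per-sample components were dropped.
#' @slot h,hprime weight function values/derivatives per stacked row.
#' @slot rowSample sample index of each stacked row.
#' @slot featureNames feature labels in original order.
#' @seealso \code{\link{buildScoreSystem}}, \code{\link{cdFit}},
#'   \code{\link{sandwichCovariance}}
#' @export
setClass("ScoreSystem",
  representation(
    Gamma = "ANY", g = "numeric", delta = "numeric",
    a = "numeric", b = "numeric", n = "integer", p = "integer",
    hasCovariate = "logical", y = "numeric",
    refIndex = "integer", perm = "integer",
    Cmat = "ANY", Dmat = "ANY",
    h = "numeric", hprime = "numeric", rowSample = "integer",
    featureNames = "character"
  )
)

setValidity("ScoreSystem", function(object) {
  r <- nTheta(object@p, object@hasCovariate)
  msg <- character()
  if (!all(dim(object@Gamma) == c(r, r))) msg <- c(msg, "Gamma has wrong dimension")
  if (length(object@g) != r) msg <- c(msg, "g has wrong length")
  if (object@delta < 1) msg <- c(msg, "delta must be >= 1")
  if (length(msg)) msg else TRUE
})

#' ScoreFit: a single penalized score matching fit
#'
#' @slot theta estimated coefficient vector (internal feature order).
#' @slot K symmetrized p x p interaction estimate (original feature order).
#' @slot eta0,eta1 location estimates (original order; eta1 zero-length when
#'   the system has no covariate).
#' @slot lambda1,lambda2 penalties on off-diagonal K and on eta.
#' @slot nIter sweeps used; @slot converged convergence flag.
#' @slot objective penalized objective at the solution.
#' @slot kktResidual maximum violation of the subgradient optimality
#'   conditions.
#' @export
setClass("ScoreFit",
  representation(
    theta = "numeric", K = "matrix", eta0 = "numeric", eta1 = "numeric",
    lambda1 = "numeric", lambda2 = "numeric",
    nIter = "integer", converged = "logical",
    objective = "numeric", kktResidual = "numeric"
  )
)

#' ScoreFitPath: warm-started fits along a decreasing lambda1 grid
#'
#' @slot lambdas strictly decreasing positive penalty values.
#' @slot fits list of \linkS4class{ScoreFit} objects.
#' @slot supportSizes number of nonzero off-diagonal K entries per fit
#'   (upper triangle, after symmetrization).
#' @export
setClass("ScoreFitPath",
  representation(
    lambdas = "numeric", fits = "list", supportSizes = "integer"
  )
)

setValidity("ScoreFitPath", function(object) {
  lam <- object@lambdas
  if (length(lam) && any(diff(lam) >= 0)) {
    "lambdas must be strictly decreasing"
  } else if (length(object@fits) != length(lam)) {
    "one fit per lambda required"
  } else TRUE
})

#' DAResults: per-feature differential abundance test results
#'
#' One row per feature: the estimated covariate effect on the location
#' vector, its sandwich standard error, the studentized statistic, the
#' two-sided p-value from the t(n-3) reference distribution, and the
#' Benjamini-Hochberg adjusted p-value. The profiled-out reference feature
#' carries no test and is flagged.
#'
#' @slot table data.frame with columns feature, eta1_hat, se, t, p_raw,
#'   p_adj, is_reference.
#' @slot n number of samples; @slot df degrees of freedom (n - 3).
#' @slot referenceFeature name of the reference feature.
#' @export
setClass("DAResults",
  representation(
    table = "data.frame", n = "integer", df = "integer",
    referenceFeature = "character"
  )
)
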