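# Regularization parameter selection: k-fold cross-validation with the
# one-standard-error rule (default) or an eBIC-type criterion.

subsetSamples <- function(dataset, idx) {
  new("CompositionData",
    X = dataset@X[idx, , drop = FALSE],
    y = if (length(dataset@y)) dataset@y[idx] else numeric(0),
    referenceIndex = dataset@referenceIndex
  )
}

#' Cross-validated selection of lambda1
#'
#' Folds are assigned uniformly at random (optionally stratified by a binary
#' covariate). Per fold the lambda path is fitted on the training samples
#' and scored by the unpenalized quadratic score matching loss
#' \eqn{\tfrac12\theta^\top\Gamma_{val}\theta - g_{val}^\top\theta} built
#' from the held-out samples (the delta multiplier is an estimation device
#' and is omitted from validation). The 1SE rule picks the largest lambda
#' whose mean CV loss is within one standard error of the minimum.
#'
#' @param dataset a \linkS4class{CompositionData}.
#' @param a,b power exponents.
#' @param lambdas candidate lambda1 values.
#' @param k number of folds (default 5).
#' @param rule "cv-1se" (default) or "cv-min".
#' @param lambda2 penalty on eta (default 0).
#' @param seed fold assignment seed.
#' @param stratify stratify folds by a binary covariate (default FALSE).
#' @param eps,tmax,spec,delta passed to \code{\link{buildScoreSystem}} /
#'   \code{\link{fitPath}}.
#' @return a \code{selectionResult} list: \code{lambda_selected},
#'   \code{rule}, \code{lambdas}, \code{cv_mean}, \code{cv_se},
#'   \code{fold_seed}.
#' @export
crossValidate <- function(dataset, a, b, lambdas = defaultLambdaPath(),
                          k = 5L, rule = c("cv-1se", "cv-min"),
                          lambda2 = 0, seed = 1L, stratify = FALSE,
                          eps = 1e-1, tmax = 1000L, spec = weightSpec(),
                          delta = "auto") {
  rule <- match.arg(rule)
  n <- nSamples(dataset)
  stopifnot(n >= k, k >= 2L)
  lambdas <- sort(unique(lambdas), decreasing = TRUE)
  set.seed(seed)
  if (stratify && length(dataset@y) && length(unique(dataset@y)) == 2L) {
    fold <- integer(n)
    for (lev in unique(dataset@y)) {
      idx <- which(dataset@y == lev)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  } else {
    fold <- sample(rep_len(seq_len(k), n))
  }
  if (min(table(fold)) < 2L) stop("a fold has fewer than 2 samples")

  lossMat <- matrix(NA_real_, k, length(lambdas))
  for (f in seq_len(k)) {
    train <- buildScoreSystem(subsetSamples(dataset, fold != f), a, b,
      spec = spec, delta = delta, keepPerSample = FALSE)
    val <- buildScoreSystem(subsetSamples(dataset, fold == f), a, b,
      spec = spec, delta = delta, keepPerSample = FALSE)
    path <- fitPath(train, lambdas, lambda2 = lambda2, eps = eps, tmax = tmax)
    lossMat[f, ] <- vapply(path@fits, function(fit) {
      quadLoss(val, fit@theta)
    }, numeric(1))
  }
  cvMean <- colMeans(lossMat)
  cvSe <- apply(lossMat, 2, sd) / sqrt(k)
  iMin <- which.min(cvMean)
  selected <- if (rule == "cv-min") {
    lambdas[iMin]
  } else {
    max(lambdas[cvMean <= cvMean[iMin] + cvSe[iMin]])
  }
  structure(
    list(
      lambda_selected = selected, rule = rule, lambdas = lambdas,
      cv_mean = cvMean, cv_se = cvSe, fold_seed = seed, k = k
    ),
    class = "selectionResult"
  )
}

#' @export
print.selectionResult <- function(x, ...) {
  cat(sprintf(
    "Lambda selection (%s, k = %d): lambda1 = %.4g\n",
    x$rule, if (is.null(x$k)) NA_integer_ else x$k, x$lambda_selected
  ))
  invisible(x)
}

#' eBIC-type criterion for a penalized score matching fit
#'
#' \eqn{S \log(n) - 2\log(\hat L + \mathrm{shift}) + 2\gamma\,
#' \|\mathrm{vec}(\hat K_{off})\|_1}, with S the off-diagonal support size
#' of K. The model has no tractable likelihood; the quadratic score
#' matching loss is plugged into the log-likelihood slot. Because that loss
#' can be nonpositive, a shift (e.g. path-wide minimum plus one) must make
#' the argument positive; \code{\link{selectLambdaEBIC}} handles this
#' automatically.
#'
#' @param fit a \linkS4class{ScoreFit}.
#' @param n sample count.
#' @param gamma eBIC weight (default 0.5).
#' @param loss loss value to plug in; default the unpenalized quadratic loss
#'   must be supplied via \code{loss}, otherwise the fit's penalized
#'   objective is used (the raw printed variant).
#' @param shift additive shift making \code{loss + shift} positive.
#' @export
ebicScore <- function(fit, n, gamma = 0.5, loss = fit@objective, shift = 0) {
  off <- fit@K[upper.tri(fit@K) | lower.tri(fit@K)]
  S <- sum(off != 0)
  l1 <- sum(abs(off))
  arg <- loss + shift
  if (arg <= 0) {
    stop("loss + shift must be positive for the log term; supply a shift")
  }
  S * log(n) - 2 * log(arg) + 2 * gamma * l1
}

#' Select lambda1 along a fitted path by the eBIC surrogate
#'
#' @param system the \linkS4class{ScoreSystem} the path was fitted on.
#' @param path a \linkS4class{ScoreFitPath}.
#' @param gamma eBIC weight (default 0.5).
#' @param useRawLoss plug the penalized delta-scaled objective into the log
#'   term exactly as printed, instead of the unpenalized quadratic loss
#'   (default FALSE).
#' @return a \code{selectionResult} list with \code{ebic_values}.
#' @export
selectLambdaEBIC <- function(system, path, gamma = 0.5, useRawLoss = FALSE) {
  losses <- vapply(path@fits, function(f) {
    if (useRawLoss) f@objective else quadLoss(system, f@theta)
  }, numeric(1))
  shift <- if (min(losses) <= 0) -min(losses) + 1 else 0
  vals <- mapply(function(f, l) ebicScore(f, system@n, gamma, loss = l,
                                          shift = shift),
                 path@fits, losses)
  i <- which.min(vals)
  structure(
    list(
      lambda_selected = path@lambdas[i], rule = "ebic",
      lambdas = path@lambdas, ebic_values = vals,
      gamma = gamma, shift = shift
    ),
    class = "selectionResult"
  )
}
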