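#' @rdname CompositionData-class
#' @param object,x a \linkS4class{CompositionData}
#' @export
setGeneric("compositions", function(object) standardGeneric("compositions"))

#' @rdname CompositionData-class
#' @export
setGeneric("covariate", function(object) standardGeneric("covariate"))

#' @rdname CompositionData-class
#' @export
setGeneric("referenceIndex", function(object) standardGeneric("referenceIndex"))

#' @rdname CompositionData-class
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' @rdname CompositionData-class
#' @export
setGeneric("nFeatures", function(object) standardGeneric("nFeatures"))

#' @rdname CompositionData-class
#' @export
setGeneric("featureNames", function(object) standardGeneric("featureNames"))

#' Extract the interaction matrix estimate
#' @param object a fitted object
#' @export
setGeneric("interactionMatrix", function(object) standardGeneric("interactionMatrix"))

#' Extract location vector estimates
#' @param object a fitted object
#' @export
setGeneric("locationVectors", function(object) standardGeneric("locationVectors"))

#' The diagonal-multiplied Gamma matrix used by the optimizer
#' @param object a \linkS4class{ScoreSystem}
#' @export
setGeneric("gammaDelta", function(object) standardGeneric("gammaDelta"))

#' Support-recovery ROC of an estimated interaction matrix path
#'
#' Compares the off-diagonal support of estimated interaction matrices along
#' a regularization path against a ground-truth K, one (FPR, TPR) point per
#' path element (upper triangle, after symmetrization), with (0,0) and (1,1)
#' anchors, and computes the trapezoid AUC.
#'
#' @param path a \linkS4class{ScoreFitPath} or a list of p x p matrices.
#' @param Ktrue ground-truth interaction matrix.
#' @return a \code{recoveryROC} list with elements \code{fpr}, \code{tpr},
#'   \code{auc}.
#' @export
setGeneric("supportRecoveryROC", function(path, Ktrue) standardGeneric("supportRecoveryROC"))

#' @rdname DAResults-class
#' @param object a \linkS4class{DAResults}
#' @export
setGeneric("daTable", function(object) standardGeneric("daTable"))

# ---- accessors ----

#' @rdname CompositionData-class
#' @export
setMethod("compositions", "CompositionData", function(object) object@X)

#' @rdname CompositionData-class
#' @export
setMethod("covariate", "CompositionData", function(object) {
  if (length(object@y)) object@y else NULL
})

#' @rdname CompositionData-class
#' @export
setMethod("referenceIndex", "CompositionData", function(object) object@referenceIndex)

#' @rdname CompositionData-class
#' @export
setMethod("nSamples", "CompositionData", function(object) nrow(object@X))

#' @rdname CompositionData-class
#' @export
setMethod("nFeatures", "CompositionData", function(object) ncol(object@X))

#' @rdname CompositionData-class
#' @export
setMethod("featureNames", "CompositionData", function(object) colnames(object@X))

#' @rdname ScoreFit-class
#' @param object a \linkS4class{ScoreFit}
#' @export
setMethod("interactionMatrix", "ScoreFit", function(object) object@K)

#' @rdname ScoreFit-class
#' @export
setMethod("locationVectors", "ScoreFit", function(object) {
  list(eta0 = object@eta0, eta1 = object@eta1)
})

#' @rdname DAResults-class
#' @export
setMethod("daTable", "DAResults", function(object) object@table)

# ---- show methods ----

setMethod("show", "CompositionData", function(object) {
  cat(sprintf(
    "CompositionData: %d samples x %d features (reference: %s)\n",
    nrow(object@X), ncol(object@X),
    colnames(object@X)[object@referenceIndex]
  ))
  if (length(object@y)) {
    vals <- unique(object@y)
    if (length(vals) <= 2) {
      cat(sprintf("  covariate: binary (%s)\n", paste(sort(vals), collapse = "/")))
    } else {
      cat(sprintf(
        "  covariate: continuous, range [%.3g, %.3g]\n",
        min(object@y), max(object@y)
      ))
    }
  } else cat("  covariate: none\n")
  zf <- mean(object@X == 0)
  cat(sprintf("  zero fraction: %.1f%%\n", 100 * zf))
})

setMethod("show", "PowerModelParams", function(object) {
  p <- length(object@eta0)
  cat(sprintf(
    "PowerModelParams: p = %d, a = %g, b = %g\n", p, object@a, object@b
  ))
  off <- object@K[upper.tri(object@K)]
  cat(sprintf(
    "  K: %d / %d nonzero off-diagonal pairs; ||eta1|| = %.3g\n",
    sum(off != 0), length(off), sqrt(sum(object@eta1^2))
  ))
})

setMethod("show", "ScoreSystem", function(object) {
  r <- nTheta(object@p, object@hasCovariate)
  cat(sprintf(
    "ScoreSystem: n = %d, p = %d, r = %d (%s covariate), a = %g, b = %g\n",
    object@n, object@p, r,
    if (object@hasCovariate) "with" else "no", object@a, object@b
  ))
  cat(sprintf(
    "  delta = %.4f; per-sample components %s\n",
    object@delta, if (is.null(object@Cmat)) "dropped" else "retained"
  ))
})

setMethod("show", "ScoreFit", function(object) {
  p <- nrow(object@K)
  off <- object@K[upper.tri(object@K)]
  cat(sprintf(
    "ScoreFit: lambda1 = %.4g, lambda2 = %.4g; %d/%d off-diagonal pairs selected\n",
    object@lambda1, object@lambda2, sum(off != 0), length(off)
  ))
  cat(sprintf(
    "  %d sweeps, converged: %s, objective %.6g, KKT residual %.2g\n",
    object@nIter, object@converged, object@objective, object@kktResidual
  ))
})

setMethod("show", "ScoreFitPath", function(object) {
  cat(sprintf(
    "ScoreFitPath: %d lambda values in [%.3g, %.3g]; support sizes %d..%d\n",
    length(object@lambdas), min(object@lambdas), max(object@lambdas),
    min(object@supportSizes), max(object@supportSizes)
  ))
})

setMethod("show", "DAResults", function(object) {
  cat(sprintf(
    "DAResults: %d features tested (reference %s excluded), df = %d\n",
    sum(!object@table$is_reference), object@referenceFeature, object@df
  ))
  tab <- object@table[!object@table$is_reference, ]
  cat(sprintf("  %d features with adjusted p < 0.05\n", sum(tab$p_adj < 0.05)))
})
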