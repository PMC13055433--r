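# Core model family: containers, power transforms, unnormalized log density,
# propriety checks.

#' Construct a CompositionData object
#'
#' @param X numeric samples x features matrix of counts or relative
#'   abundances.
#' @param y optional per-sample covariate: numeric, or a two-level
#'   factor/character vector (mapped to 0/1 with the lexicographically
#'   smaller level as 0).
#' @param referenceIndex index or name of the reference feature profiled out
#'   of the model; default is the last column. A high-abundance, low-variance
#'   feature is recommended.
#' @param normalize divide each row by its sum (library size) before any
#'   modelling. Default TRUE.
#' @param pseudocount optional positive value replacing zero entries
#'   (on the input scale) before normalization; off by default, as the power
#'   model with a, b > 0 handles zeros natively.
#' @return a \linkS4class{CompositionData}
#' @examples
#' X <- matrix(c(4, 3, 3, 2, 5, 3), 2, byrow = TRUE)
#' cd <- CompositionData(X, y = c(0, 1))
#' rowSums(compositions(cd))
#' @export
CompositionData <- function(X, y = NULL, referenceIndex = ncol(X),
                            normalize = TRUE, pseudocount = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) {
    colnames(X) <- paste0("feature", seq_len(ncol(X)))
  }
  if (is.character(referenceIndex)) {
    referenceIndex <- match(referenceIndex, colnames(X))
    if (is.na(referenceIndex)) stop("reference feature not found among columns")
  }
  if (!is.null(pseudocount)) {
    stopifnot(pseudocount > 0)
    X[X == 0] <- pseudocount
  }
  if (normalize) {
    rs <- rowSums(X)
    if (any(rs <= 0)) stop("rows with nonpositive total abundance")
    X <- X / rs
  }
  if (!is.null(y)) {
    if (is.factor(y) || is.character(y)) {
      lev <- sort(unique(as.character(y)))
      if (length(lev) != 2) {
        stop("non-numeric covariate must have exactly two levels")
      }
      message(sprintf("covariate mapped: '%s' -> 0, '%s' -> 1", lev[1], lev[2]))
      y <- as.numeric(as.character(y) == lev[2])
    }
    y <- as.numeric(y)
  } else {
    y <- numeric(0)
  }
  new("CompositionData",
    X = X, y = y, referenceIndex = as.integer(referenceIndex)
  )
}

#' Construct model parameters
#'
#' @param a,b nonnegative power exponents (a = b = 0 gives the log-based
#'   family containing the Dirichlet and logistic normal distributions).
#' @param K symmetric p x p interaction matrix.
#' @param eta0 length-p baseline location vector.
#' @param eta1 length-p covariate effect vector (default zero).
#' @return a \linkS4class{PowerModelParams}
#' @export
PowerModelParams <- function(a, b, K, eta0, eta1 = numeric(length(eta0))) {
  new("PowerModelParams",
    a = as.numeric(a), b = as.numeric(b), K = as.matrix(K),
    eta0 = as.numeric(eta0), eta1 = as.numeric(eta1)
  )
}

# theta layout helpers ---------------------------------------------------

nTheta <- function(p, hasCovariate) p^2 + if (hasCovariate) 2L * p else p

thetaLayout <- function(p, hasCovariate) {
  kIdx <- seq_len(p^2)
  kDiag <- ((seq_len(p) - 1L) * p) + seq_len(p)
  eta0Idx <- p^2 + seq_len(p)
  eta1Idx <- if (hasCovariate) p^2 + p + seq_len(p) else integer(0)
  list(
    p = p, r = nTheta(p, hasCovariate),
    kIdx = kIdx, kDiag = kDiag, kOff = setdiff(kIdx, kDiag),
    eta0Idx = eta0Idx, eta1Idx = eta1Idx
  )
}

thetaFromParams <- function(params, hasCovariate = TRUE) {
  th <- c(as.vector(params@K), params@eta0)
  if (hasCovariate) th <- c(th, params@eta1)
  th
}

# transforms --------------------------------------------------------------

#' Elementwise power transform with the log convention at zero exponent
#'
#' Returns \code{x^a} for \code{a > 0} and \code{log(x)} for \code{a = 0},
#' together with the companion density scale factor \code{1/a} (1 at
#' \code{a = 0}).
#'
#' @param x nonnegative numeric vector (strictly positive when \code{a = 0}).
#' @param a nonnegative exponent.
#' @return list with elements \code{value} and \code{factor}.
#' @examples
#' powerTransform(c(0.25, 0.75), 0)$value  # log
#' powerTransform(c(0, 1), 0.5)$value      # zeros permitted for a > 0
#' @export
powerTransform <- function(x, a) {
  stopifnot(a >= 0, all(x >= 0))
  if (a == 0) {
    if (any(x == 0)) {
      stop(
        "zero entries are not in the domain of the log transform (a = 0); ",
        "use a > 0 or replace zeros (e.g. pseudocount = 0.5)"
      )
    }
    list(value = log(x), factor = 1)
  } else {
    list(value = x^a, factor = 1 / a)
  }
}

# Centered Box-Cox-type transform used in all sufficient statistics:
# u_a(x) = (x^a - 1)/a for a > 0, log(x) for a = 0. Continuous in a, so the
# a -> 0 limit is numerically stable; identical model family (K is rescaled
# by a relative to the x^a/a convention, eta only shifted by a constant
# absorbed in the normalizing constant).
boxcoxPower <- function(x, a) {
  if (a == 0) {
    if (any(x == 0)) {
      stop(
        "zero entries are not in the domain of the log transform (a = 0); ",
        "use a > 0 or replace zeros (e.g. pseudocount = 0.5)"
      )
    }
    log(x)
  } else {
    (x^a - 1) / a
  }
}

#' Unnormalized log density of the covariate-extended power interaction model
#'
#' Evaluates \eqn{-\tfrac12 u_a(x)^\top K u_a(x) + (\eta_0 + y
#' \eta_1)^\top u_b(x)} with \eqn{u_c(x) = (x^c - 1)/c} (log at c = 0).
#' The normalizing constant is never computed.
#'
#' @param x a point on the simplex (zeros only allowed when a > 0 and b > 0).
#' @param y scalar covariate value.
#' @param params a \linkS4class{PowerModelParams}.
#' @return scalar unnormalized log density.
#' @export
unnormLogDensity <- function(x, y, params) {
  ua <- boxcoxPower(x, params@a)
  ub <- if (params@b == params@a) ua else boxcoxPower(x, params@b)
  eta <- params@eta0 + y * params@eta1
  -0.5 * sum(ua * (params@K %*% ua)) + sum(eta * ub)
}

# propriety ---------------------------------------------------------------

#' Check the propriety conditions of the power interaction density
#'
#' The density is proper in four exponent regimes: (i) a > 0, b > 0 always;
#' (ii) a > 0, b = 0 if every component of eta exceeds -1; (iii) a = 0,
#' b = 0 if \eqn{\log(x)^\top K \log(x) > 0} on the simplex; (iv) a = 0,
#' b > 0 under the weak version of the same quadratic-form condition. For the
#' covariate model, eta = eta0 + y eta1 is checked at both extremes of the
#' observed covariate range. The quadratic-form conditions cannot be
#' certified by sampling; they are checked on a finite grid of simplex
#' points and reported as a necessary-condition check only.
#'
#' @param params a \linkS4class{PowerModelParams}.
#' @param yRange numeric length-2: observed covariate range (use c(0, 0)
#'   for a covariate-less model).
#' @param gridPoints optional matrix of simplex points for the a = 0 checks;
#'   default 1000 uniform-Dirichlet points.
#' @return a \code{validityReport} list: \code{is_valid}, \code{case_label},
#'   \code{violated_conditions}.
#' @export
validateParams <- function(params, yRange = c(0, 0), gridPoints = NULL) {
  a <- params@a; b <- params@b
  p <- length(params@eta0)
  caseLabel <- paste0(
    "a", if (a > 0) ">0" else "=0", "&b", if (b > 0) ">0" else "=0"
  )
  violated <- character()
  etas <- rbind(
    params@eta0 + yRange[1] * params@eta1,
    params@eta0 + yRange[2] * params@eta1
  )
  kZero <- max(abs(params@K)) < 1e-12
  needGrid <- (a == 0) && !kZero
  if (needGrid && is.null(gridPoints)) {
    gridPoints <- randomSimplexPoints(1000L, p)
  }
  if (a > 0 && b == 0) {
    if (any(etas <= -1)) {
      violated <- c(violated, "etaj > -1 for all j (at some observed y)")
    }
  } else if (a == 0 && kZero) {
    # K = 0 reduces the model to a Dirichlet-type kernel: proper iff all
    # Dirichlet parameters eta + 1 are positive (b = 0) / eta finite (b > 0)
    if (b == 0 && any(etas <= -1)) {
      violated <- c(violated, "etaj > -1 for all j (Dirichlet case, K = 0)")
    }
  } else if (a == 0) {
    L <- log(gridPoints)
    q <- rowSums((L %*% params@K) * L)
    if (b == 0 && any(q <= 0)) {
      violated <- c(violated, "log(x)' K log(x) > 0 on simplex grid")
    }
    if (b > 0 && any(q < 0)) {
      violated <- c(violated, "log(x)' K log(x) >= 0 on simplex grid")
    }
  }
  structure(
    list(
      is_valid = length(violated) == 0L,
      case_label = caseLabel,
      violated_conditions = violated,
      grid_checked = if (needGrid) nrow(gridPoints) else 0L
    ),
    class = "validityReport"
  )
}

#' @export
print.validityReport <- function(x, ...) {
  cat(sprintf(
    "Propriety check (case %s): %s\n", x$case_label,
    if (x$is_valid) "valid" else "VIOLATED"
  ))
  if (length(x$violated_conditions)) {
    cat(paste0("  - ", x$violated_conditions, collapse = "\n"), "\n")
  }
  if (x$grid_checked > 0) {
    cat(sprintf(
      "  (quadratic-form condition checked on %d grid points; necessary condition only)\n",
      x$grid_checked
    ))
  }
  invisible(x)
}

# Uniform Dirichlet(1,...,1) points on the simplex.
randomSimplexPoints <- function(n, p) {
  E <- matrix(-log(runif(n * p)), n, p)
  E / rowSums(E)
}
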