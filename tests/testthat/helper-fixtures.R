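# Shared fixtures: small random datasets and parameter sets built in code.

randomSymmetricK <- function(p, rowSumZero = FALSE) {
  K <- matrix(rnorm(p^2), p, p)
  K <- (K + t(K)) / 2
  if (rowSumZero) {
    # project onto the K 1p = 0 subspace (symmetrically)
    J <- diag(p) - matrix(1 / p, p, p)
    K <- J %*% K %*% J
    K <- (K + t(K)) / 2
  }
  K
}

randomParams <- function(p, a, b, rowSumZero = FALSE) {
  PowerModelParams(a, b, randomSymmetricK(p, rowSumZero), rnorm(p), rnorm(p))
}

smallDataset <- function(n = 12, p = 4, withCov = TRUE, ref = p,
                         alpha = rep(2, p)) {
  X <- rDirichletMatrix(n, alpha)
  CompositionData(X,
    y = if (withCov) rnorm(n) else NULL,
    referenceIndex = ref, normalize = FALSE
  )
}

# brute-force step-up BH, independent of stats::p.adjust
bruteForceBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
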