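# Shared fixtures: small random model instances and dense reference
# computations, built in code at test time.

# A random (y, K, X) instance with a GRM from simulated genotypes.
random_instance <- function(n, q, m = 4 * n, seed = 1) {
  set.seed(seed)
  g <- simulate_genotypes(n, m, maf_range = c(0.1, 0.5))
  K <- suppressWarnings(compute_grm(g)) # small n can leave SNPs monomorphic
  y <- rnorm(n)
  X <- if (q == 0) NULL else {
    X <- cbind(1, matrix(rnorm(n * (q - 1)), n))
    colnames(X) <- c("intercept", if (q > 1) paste0("c", seq_len(q - 1)))
    X
  }
  list(y = y, K = K, X = X)
}

# Dense pairwise GRM reference: explicit double loop over sample pairs,
# independent of the streamed/tcrossprod implementation path.
dense_grm_oracle <- function(dosages) {
  n <- nrow(dosages)
  p_all <- colMeans(dosages, na.rm = TRUE) / 2
  poly <- is.finite(p_all) & p_all > 0 & p_all < 1
  dosages <- dosages[, poly, drop = FALSE]
  p <- p_all[poly]
  m <- ncol(dosages)
  K <- matrix(0, n, n)
  for (j in seq_len(n)) {
    for (k in seq_len(j)) {
      acc <- 0
      for (i in seq_len(m)) {
        xj <- dosages[j, i]
        xk <- dosages[k, i]
        if (is.na(xj)) xj <- 2 * p[i]
        if (is.na(xk)) xk <- 2 * p[i]
        acc <- acc + (xj - 2 * p[i]) * (xk - 2 * p[i]) / (2 * p[i] * (1 - p[i]))
      }
      K[j, k] <- K[k, j] <- acc / m
    }
  }
  K
}

# Explicit-projection reference for the five quadratics, via an orthonormal
# basis U of the orthogonal complement of col(X).
explicit_quadratics_oracle <- function(y, K, X = NULL) {
  Kv <- if (inherits(K, "grm")) K$values else K
  n <- length(y)
  if (is.null(X)) {
    Kt <- Kv
    yt <- y
  } else {
    q <- ncol(X)
    U <- qr.Q(qr(X), complete = TRUE)[, (q + 1L):n, drop = FALSE]
    Kt <- crossprod(U, Kv %*% U)
    yt <- drop(crossprod(U, y))
  }
  list(trK = sum(diag(Kt)), trK2 = sum(Kt^2),
       yKy = drop(t(yt) %*% Kt %*% yt), yy = sum(yt^2),
       M = length(yt))
}
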