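# Closed-form moment-matching (Haseman-Elston-family) variance-component
# estimation with covariates removed by implicit projection.
#
# Model: y = X beta + g + e, cov[y] = sigma_g^2 K + sigma_e^2 I. Fixed
# effects are eliminated by an N x (N-q) semi-orthogonal U with U'U = I,
# UU' = P0 = I - X (X'X)^{-1} X', U'X = 0. All U-basis quantities are
# recovered from K through block-column identities, so nothing beyond one
# column block of K and O(Nq + q^2) workspace is ever materialized:
#   tr[K~]   = tr[K] - tr[(X'X)^{-1} X'KX]
#   tr[K~^2] = tr[K^2] - 2 tr[(X'X)^{-1} X'K^2X] + tr[((X'X)^{-1} X'KX)^2]
#   y~'K~y~  = (P0 y)' K (P0 y),  y~'y~ = y' P0 y

#' Projected quadratic forms for the moment-matching estimator
#'
#' Computes the five scalars (tr K-tilde, tr K-tilde^2, y-tilde' K-tilde
#' y-tilde, y-tilde' y-tilde, M = N - q) that fully determine the estimator
#' after covariate projection, streaming K one column block at a time.
#'
#' @param y Numeric phenotype vector of length N (no missing values).
#' @param K A `grm`, or a symmetric numeric N x N matrix.
#' @param X Covariate matrix N x q (include an intercept column if wanted),
#'   or `NULL` for no covariates. Must have full column rank.
#' @param block_size Number of GRM columns per streamed block.
#' @return An object of class `projected_quadratics`: list with `trK`,
#'   `trK2`, `yKy`, `yy`, `M`.
#' @export
compute_projected_quadratics <- function(y, K, X = NULL, block_size = 1024L) {
  Kv <- if (inherits(K, "grm")) K$values else as.matrix(K)
  n <- length(y)
  stopifnot(nrow(Kv) == n, ncol(Kv) == n)
  if (anyNA(y)) stop("missing values in phenotype; drop samples first")
  q <- 0L
  H <- NULL
  if (!is.null(X)) {
    X <- as.matrix(X)
    stopifnot(nrow(X) == n)
    if (anyNA(X)) stop("missing values in covariates; drop samples first")
    q <- ncol(X)
    qrX <- qr(X)
    if (qrX$rank < q) {
      bad <- qrX$pivot[(qrX$rank + 1L):q]
      nm <- colnames(X)
      nm <- if (is.null(nm)) as.character(bad) else nm[bad]
      stop("collinear-covariates: ", paste(nm, collapse = ", "))
    }
    H <- chol2inv(chol(crossprod(X)))
    r <- y - X %*% (H %*% crossprod(X, y))
    r <- drop(r)
  } else {
    r <- y
  }
  M <- n - q
  if (M < 2L) stop("degenerate model: N - q < 2")

  trK <- 0
  trK2 <- 0
  B <- if (q > 0L) matrix(0, n, q) else NULL  # accumulates K X
  Kr <- numeric(n)                            # accumulates K (P0 y)
  starts <- seq(1L, n, by = block_size)
  for (s in starts) {
    idx <- s:min(s + block_size - 1L, n)
    Kb <- Kv[, idx, drop = FALSE]
    trK <- trK + sum(Kb[cbind(idx, seq_along(idx))])
    trK2 <- trK2 + sum(Kb * Kb)
    if (q > 0L) B <- B + Kb %*% X[idx, , drop = FALSE]
    Kr <- Kr + Kb %*% r[idx]
  }
  if (q > 0L) {
    A <- crossprod(X, B)        # X' K X
    C <- H %*% A                # (X'X)^{-1} X' K X
    trK <- trK - sum(diag(C))
    trK2 <- trK2 - 2 * sum(H * crossprod(B)) + sum(C * t(C))
  }
  structure(list(trK = trK,
                 trK2 = trK2,
                 yKy = drop(crossprod(r, Kr)),
                 yy = sum(r^2),
                 M = M),
            class = "projected_quadratics")
}

#' Variance components from projected quadratics
#'
#' Ordinary least squares solution of the covariance regression
#' vec(y y') ~ sigma_g^2 vec(K) + sigma_e^2 vec(I) in the projected basis:
#' with tau = tr(K)/M, kappa = tr(K^2)/M, vK = M(kappa - tau^2),
#' sigma_g^2 = (y'Ky - tau y'y)/vK and sigma_e^2 = (kappa y'y - tau y'Ky)/vK.
#' The estimator is unconstrained; individual components may be negative.
#'
#' @param pq A `projected_quadratics`.
#' @return An object of class `variance_components`: list with `sigma_g2`,
#'   `sigma_e2`, `sigma_p2`, plus `tau`, `kappa`, `vK`, `M` carried along.
#' @export
estimate_variance_components <- function(pq) {
  stopifnot(inherits(pq, "projected_quadratics"))
  tau <- pq$trK / pq$M
  kappa <- pq$trK2 / pq$M
  vK <- pq$M * (kappa - tau^2)
  if (vK <= 0) {
    stop("unidentifiable: K is proportional to I after projection (vK <= 0)")
  }
  sigma_g2 <- (pq$yKy - tau * pq$yy) / vK
  sigma_e2 <- (kappa * pq$yy - tau * pq$yKy) / vK
  structure(list(sigma_g2 = sigma_g2,
                 sigma_e2 = sigma_e2,
                 sigma_p2 = sigma_g2 + sigma_e2,
                 tau = tau, kappa = kappa, vK = vK, M = pq$M),
            class = "variance_components")
}

#' Estimate SNP heritability by moment matching
#'
#' One-shot estimation: aligns phenotype, covariates and GRM (listwise
#' deletion of samples with missing phenotype or covariates, subsetting K
#' to the retained rows/columns before projection), computes the projected
#' quadratics, and returns the observed-scale heritability
#' h2 = sigma_g^2 / sigma_p^2 with standard error sqrt(2 / vK).
#'
#' @param y Numeric phenotype vector; names (or `ids`) identify samples.
#'   Binary 0/1 traits are detected automatically and their sample
#'   prevalence recorded; use [observed_to_liability()] to convert scale.
#' @param K A `grm` or symmetric matrix. If a `grm`, samples are matched by
#'   ID; otherwise positional alignment with `y` is assumed.
#' @param X Covariate matrix or data frame (q columns), or `NULL`.
#' @param ids Optional sample IDs for `y`/`X` rows; defaults to `names(y)`
#'   or, failing that, the GRM sample order.
#' @param intercept Add an intercept column to X (default `TRUE`; an
#'   intercept alone is used when `X` is `NULL`).
#' @param block_size GRM column block size for streaming.
#' @return An object of class `heritability_estimate`: list with `h2`,
#'   `se`, `h2_clamped`, `scale` ("observed"), `n`, `prevalence` (`NA` for
#'   continuous traits), and the underlying `components` and `quadratics`.
#' @examples
#' g <- simulate_genotypes(n_samples = 300, n_snps = 1000, seed = 2)
#' sim <- simulate_phenotype(g, h2 = 0.5, seed = 3)
#' K <- compute_grm(g)
#' estimate_h2(sim$y, K)
#' @export
estimate_h2 <- function(y, K, X = NULL, ids = NULL, intercept = TRUE,
                        block_size = 1024L) {
  if (is.null(ids)) ids <- names(y)
  if (!is.null(X)) X <- as.matrix(X)
  if (inherits(K, "grm")) {
    if (is.null(ids)) {
      if (length(y) != length(K$sample_ids)) {
        stop("phenotype length differs from GRM and no sample IDs supplied")
      }
      ids <- K$sample_ids
    }
    keep <- !is.na(y) & (if (is.null(X)) TRUE else stats::complete.cases(X))
    keep <- keep & ids %in% K$sample_ids
    ids <- ids[keep]
    y <- y[keep]
    if (!is.null(X)) X <- X[keep, , drop = FALSE]
    Ksub <- subset_grm(K, ids)
  } else {
    keep <- !is.na(y) & (if (is.null(X)) TRUE else stats::complete.cases(X))
    y <- y[keep]
    if (!is.null(X)) X <- X[keep, , drop = FALSE]
    Ksub <- as.matrix(K)[keep, keep, drop = FALSE]
  }
  n <- length(y)
  if (intercept) {
    X <- if (is.null(X)) matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
         else cbind("(Intercept)" = 1, X)
  }
  pq <- compute_projected_quadratics(y, Ksub, X, block_size = block_size)
  vc <- estimate_variance_components(pq)
  if (vc$sigma_p2 == 0) stop("undefined ratio: total variance is zero")
  h2 <- vc$sigma_g2 / vc$sigma_p2
  vals <- unique(y[!is.na(y)])
  prevalence <- if (all(vals %in% c(0, 1))) mean(y) else NA_real_
  new_heritability_estimate(
    h2 = h2, se = sqrt(2 / vc$vK), scale = "observed",
    n = n, prevalence = prevalence, components = vc, quadratics = pq)
}

new_heritability_estimate <- function(h2, se, scale, n, prevalence,
                                      components = NULL, quadratics = NULL) {
  structure(list(h2 = h2,
                 se = se,
                 h2_clamped = min(1, max(0, h2)),
                 scale = scale,
                 n = n,
                 prevalence = prevalence,
                 components = components,
                 quadratics = quadratics),
            class = "heritability_estimate")
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat(sprintf("SNP heritability (%s scale): h2 = %.4f (SE %.4f), clamped %.4f, N = %d\n",
              x$scale, x$h2, x$se, x$h2_clamped, x$n))
  if (!is.na(x$prevalence)) {
    cat(sprintf("  binary trait, prevalence %.4f\n", x$prevalence))
  }
  invisible(x)
}
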