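# Synthetic genotype/phenotype generation and independent estimation
# oracles (explicit-projection vec-OLS and eigendecomposition ReML).
#
# The generator emulates a post-QC panel of unrelated diploid individuals:
# SNPs in Hardy-Weinberg equilibrium with MAF drawn uniformly from a stated
# range (floor 0.01, mirroring the usual low-MAF exclusion), no LD, no
# relatedness, no population structure. Phenotypes follow the additive
# random-effects model y = X beta + g + e with causal effects drawn on
# standardized genotypes (the GCTA-consistent architecture the estimator
# implicitly assumes).

#' Simulate unrelated HWE genotypes
#'
#' Per SNP, MAF ~ Uniform(maf_range) and dosages ~ Binomial(2, MAF)
#' independently per sample. SNPs are spread over autosomes 1-22 with
#' 1 Mb spacing.
#'
#' @param n_samples,n_snps Panel dimensions.
#' @param maf_range Lower/upper MAF bounds; lower bound must be >= 0.01.
#' @param seed Optional integer seed (bit-reproducible output).
#' @return Integer dosage matrix (samples x SNPs) with a `snp_meta`
#'   attribute (`chrom`, `pos`, `id`) and sample IDs as rownames; directly
#'   usable as a [compute_grm()] source.
#' @export
simulate_genotypes <- function(n_samples, n_snps, maf_range = c(0.05, 0.5),
                               seed = NULL) {
  stopifnot(n_samples >= 1L)
  if (n_snps < 1L) stop("empty panel: n_snps must be >= 1")
  if (maf_range[1] < 0.01) stop("minimum MAF must be >= 0.01")
  stopifnot(maf_range[2] >= maf_range[1], maf_range[2] <= 0.5)
  if (!is.null(seed)) set.seed(seed)
  maf <- stats::runif(n_snps, maf_range[1], maf_range[2])
  x <- matrix(stats::rbinom(n_samples * n_snps, 2L, rep(maf, each = n_samples)),
              nrow = n_samples, ncol = n_snps)
  rownames(x) <- sprintf("S%04d", seq_len(n_samples))
  chrom <- sort(rep(1:22, length.out = n_snps))
  pos <- as.integer(1e6 * stats::ave(seq_len(n_snps), chrom, FUN = seq_along))
  attr(x, "snp_meta") <- data.frame(chrom = chrom, pos = pos,
                                    id = sprintf("rs%06d", seq_len(n_snps)),
                                    maf = maf, stringsAsFactors = FALSE)
  x
}

#' Simulate a polygenic quantitative phenotype
#'
#' Draws causal effects i.i.d. N(0, h2/n_causal) on column-standardized
#' dosages of `n_causal` SNPs chosen uniformly at random, adds environment
#' e ~ N(0, 1 - h2) and optional fixed effects, and returns the realized
#' components for diagnostics.
#'
#' @param genotypes Dosage matrix from [simulate_genotypes()] (or any
#'   samples x SNPs matrix with polymorphic columns).
#' @param h2 True heritability in [0, 1].
#' @param n_causal Number of causal SNPs (default: all).
#' @param X,beta Optional covariate matrix and fixed-effect vector added as
#'   `X %*% beta`.
#' @param seed Optional integer seed.
#' @return List with `y` (named by sample), `g`, `e`, and `causal` (SNP
#'   column indices).
#' @export
simulate_phenotype <- function(genotypes, h2 = 0.5, n_causal = ncol(genotypes),
                               X = NULL, beta = NULL, seed = NULL) {
  stopifnot(h2 >= 0, h2 <= 1, n_causal >= 1L, n_causal <= ncol(genotypes))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(genotypes)
  causal <- sort(sample.int(ncol(genotypes), n_causal))
  xc <- genotypes[, causal, drop = FALSE]
  p <- colMeans(xc) / 2
  z <- sweep(sweep(xc, 2L, 2 * p, `-`), 2L, sqrt(2 * p * (1 - p)), `/`)
  b <- stats::rnorm(n_causal, 0, sqrt(h2 / n_causal))
  g <- drop(z %*% b)
  e <- stats::rnorm(n, 0, sqrt(1 - h2))
  y <- g + e
  if (!is.null(X)) y <- y + drop(as.matrix(X) %*% beta)
  names(y) <- rownames(genotypes)
  list(y = y, g = g, e = e, causal = causal)
}

#' Threshold a liability into a binary trait
#'
#' Cases are the top-prevalence fraction of the observed liability
#' distribution, so the realized sample prevalence is within 1/N of the
#' target (ties broken by position).
#'
#' @param liability Numeric vector.
#' @param prevalence Target case fraction in (0, 1).
#' @return Integer 0/1 vector (names preserved).
#' @export
simulate_binary <- function(liability, prevalence) {
  stopifnot(prevalence > 0, prevalence < 1)
  n <- length(liability)
  k <- max(1L, round(prevalence * n))
  case_idx <- order(liability, decreasing = TRUE)[seq_len(k)]
  y <- integer(n)
  y[case_idx] <- 1L
  names(y) <- names(liability)
  y
}

#' Explicit-projection vec-OLS oracle
#'
#' Dense reference implementation of the moment-matching estimator:
#' projects with an explicit orthonormal basis U of the orthogonal
#' complement of col(X) and solves the vectorized covariance regression
#' vec(y~ y~') ~ sigma_g^2 vec(K~) + sigma_e^2 vec(I) by OLS (diagonal
#' included). Ground truth for [estimate_variance_components()]; O(N^2)
#' memory, small-N use only.
#'
#' @param y Phenotype vector.
#' @param K A `grm` or symmetric matrix.
#' @param X Covariate matrix or `NULL`.
#' @return A `variance_components`.
#' @export
vec_ols_oracle <- function(y, K, X = NULL) {
  Kv <- if (inherits(K, "grm")) K$values else as.matrix(K)
  n <- length(y)
  if (!is.null(X)) {
    X <- as.matrix(X)
    q <- ncol(X)
    if (qr(X)$rank < q) stop("collinear covariates")
    if (n - q < 2L) stop("degenerate model: N - q < 2")
    U <- qr.Q(qr(X), complete = TRUE)[, (q + 1L):n, drop = FALSE]
    Kt <- crossprod(U, Kv %*% U)
    yt <- drop(crossprod(U, y))
  } else {
    Kt <- Kv
    yt <- y
  }
  m_dim <- length(yt)
  design <- cbind(as.vector(Kt), as.vector(diag(m_dim)))
  target <- as.vector(tcrossprod(yt))
  xtx <- crossprod(design)
  if (rcond(xtx) < 1e-12) {
    stop("unidentifiable: K is proportional to I after projection")
  }
  coefs <- drop(solve(xtx, crossprod(design, target)))
  structure(list(sigma_g2 = coefs[1L], sigma_e2 = coefs[2L],
                 sigma_p2 = coefs[1L] + coefs[2L],
                 tau = sum(diag(Kt)) / m_dim,
                 kappa = sum(Kt^2) / m_dim,
                 vK = m_dim * (sum(Kt^2) / m_dim - (sum(diag(Kt)) / m_dim)^2),
                 M = m_dim),
            class = "variance_components")
}

#' Eigendecomposition ReML oracle
#'
#' Restricted maximum likelihood for the single-kernel model in the
#' projected basis: after eigendecomposing K~, the restricted likelihood
#' is profiled over h2 = sigma_g^2/sigma_p^2 on [0, 1] with a golden-section
#' search, and standard errors come from the inverse Fisher information at
#' the optimum via the delta method. Dense, small-N reference for
#' consistency checks against the moment-matching estimator.
#'
#' @param y Phenotype vector.
#' @param K A `grm` or symmetric matrix.
#' @param X Covariate matrix or `NULL`.
#' @param tol Convergence tolerance of the 1-D search.
#' @return List with `sigma_g2`, `sigma_e2`, `h2`, `se`, and `boundary`
#'   (`TRUE` when the optimum sits on h2 = 0 or 1 within `tol`).
#' @export
reml_oracle <- function(y, K, X = NULL, tol = 1e-8) {
  Kv <- if (inherits(K, "grm")) K$values else as.matrix(K)
  n <- length(y)
  if (!is.null(X)) {
    X <- as.matrix(X)
    q <- ncol(X)
    U <- qr.Q(qr(X), complete = TRUE)[, (q + 1L):n, drop = FALSE]
    Kt <- crossprod(U, Kv %*% U)
    yt <- drop(crossprod(U, y))
  } else {
    Kt <- Kv
    yt <- y
  }
  m_dim <- length(yt)
  eg <- eigen((Kt + t(Kt)) / 2, symmetric = TRUE)
  lam <- eg$values
  z2 <- drop(crossprod(eg$vectors, yt))^2
  # profile restricted log-likelihood over h2 (sigma_p profiled out)
  nll <- function(h) {
    d <- h * lam + (1 - h)
    if (any(d <= 0)) return(Inf)
    sp <- sum(z2 / d) / m_dim
    0.5 * (m_dim * log(sp) + sum(log(d)))
  }
  opt <- stats::optimize(nll, interval = c(0, 1), tol = tol)
  h <- opt$minimum
  # optimize() never returns the exact endpoints; snap when better
  if (nll(0) <= opt$objective) h <- 0
  if (nll(1 - 1e-12) <= opt$objective) h <- 1 - 1e-12
  d <- h * lam + (1 - h)
  sp <- sum(z2 / d) / m_dim
  sg <- h * sp
  se_comp <- (1 - h) * sp
  dd <- sg * lam + se_comp
  info <- 0.5 * matrix(c(sum(lam^2 / dd^2), sum(lam / dd^2),
                         sum(lam / dd^2), sum(1 / dd^2)), 2L, 2L)
  vcov2 <- solve(info)
  grad <- c(se_comp, -sg) / sp^2 # d h2 / d (sigma_g2, sigma_e2)
  var_h <- drop(t(grad) %*% vcov2 %*% grad)
  list(sigma_g2 = sg, sigma_e2 = se_comp, h2 = sg / sp,
       se = sqrt(max(var_h, 0)),
       boundary = h <= tol || h >= 1 - 1e-6)
}
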