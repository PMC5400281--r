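# Stratified heritability: sex difference tests, sliding age and
# socioeconomic (Townsend index) windows, inverse-SE-weighted trend
# regression, and the effective-number-of-tests correction.

#' z-test for the difference of two independent heritability estimates
#'
#' @param hA,hB Heritability estimates from disjoint strata.
#' @param seA,seB Their standard errors (must be positive).
#' @return List with `z = (hA - hB)/sqrt(seA^2 + seB^2)` and the two-sided
#'   normal p-value `2 * pnorm(-|z|)`.
#' @export
diff_z_test <- function(hA, seA, hB, seB) {
  if (seA <= 0 || seB <= 0) stop("standard errors must be positive")
  z <- (hA - hB) / sqrt(seA^2 + seB^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Sliding age windows
#'
#' Inclusive windows of `width` years stepping by one year, e.g. the
#' defaults give 40-49, 41-50, ..., 64-73 (25 windows).
#'
#' @param min_age,max_age Age range covered (years).
#' @param width Window width in years.
#' @return Data frame with columns `label`, `lo`, `hi` (inclusive bounds).
#' @export
make_age_windows <- function(min_age = 40, max_age = 73, width = 10) {
  if (max_age < min_age) stop("empty age range")
  if (width > max_age - min_age + 1) stop("window width exceeds the age range")
  lo <- seq(min_age, max_age - width + 1)
  hi <- lo + width - 1
  data.frame(label = sprintf("%d-%d", lo, hi), lo = lo, hi = hi,
             stringsAsFactors = FALSE)
}

#' Inverse-SE-weighted linear trend across strata
#'
#' Fits h2_k = alpha + gamma * x_k + eps_k by weighted least squares with
#' weights 1/se_k, and tests H0: gamma = 0 with the WLS t-statistic on
#' k - 2 degrees of freedom.
#'
#' @param h2 Per-stratum heritability estimates (length >= 3).
#' @param se Their standard errors (positive).
#' @param x Stratum centers (e.g. mean age of each window, years).
#' @return List with `gamma` (slope, heritability units per unit of `x`),
#'   `alpha` (intercept), and `p`.
#' @export
trend_test <- function(h2, se, x) {
  k <- length(h2)
  stopifnot(length(se) == k, length(x) == k)
  if (k < 3L) stop("need at least 3 strata for a trend test")
  if (any(se <= 0)) stop("standard errors must be positive")
  if (stats::var(x) == 0) stop("singular design: identical stratum centers")
  fit <- stats::lm(h2 ~ x, weights = 1 / se)
  sm <- suppressWarnings(summary(fit)) # perfect fits handled below
  cf <- sm$coefficients
  gamma <- unname(cf["x", "Estimate"])
  p <- unname(cf["x", "Pr(>|t|)"])
  # exact fit (zero residual variance up to rounding): a zero slope carries
  # no evidence of trend, a nonzero one is unambiguous
  if (!is.finite(p) || sm$sigma^2 < 1e-20 * mean(h2^2)) {
    flat <- abs(gamma) * diff(range(x)) < 1e-10 * max(abs(h2)) + 1e-300
    p <- if (flat) 1 else 0
  }
  list(gamma = gamma,
       alpha = unname(cf["(Intercept)", "Estimate"]),
       p = p)
}

#' Sliding quantile windows over a socioeconomic index
#'
#' Each window holds the samples between cumulative-rank quantiles
#' [a, a + window_mass], with the start a sliding uniformly from 0 to
#' 1 - window_mass over `n_windows` positions. `n_windows = 3` with mass
#' 1/3 gives disjoint tertiles.
#'
#' @param townsend Numeric index (e.g. Townsend deprivation score); `NA`
#'   values are excluded from all windows.
#' @param window_mass Fraction of the sample per window (default 1/3).
#' @param n_windows Number of sliding positions (default 10).
#' @param min_n Minimum window size; smaller windows are an error.
#' @return List of windows, each a list with `label`, `idx` (integer
#'   indices into `townsend`), and `center` (median index value).
#' @export
make_ses_windows <- function(townsend, window_mass = 1/3, n_windows = 10L,
                             min_n = 500L) {
  stopifnot(window_mass > 0, window_mass < 1, n_windows >= 1L)
  obs <- which(!is.na(townsend))
  n <- length(obs)
  if (n < 2L || stats::var(townsend[obs]) == 0) {
    stop("degenerate index: no quantile spread")
  }
  ord <- obs[order(townsend[obs])]
  size <- round(window_mass * n)
  if (size < min_n) {
    stop(sprintf("window size %d below the minimum stratum size %d", size, min_n))
  }
  starts_q <- if (n_windows == 1L) 0 else
    seq(0, 1 - window_mass, length.out = n_windows)
  lapply(seq_len(n_windows), function(j) {
    from <- floor(starts_q[j] * n) + 1L
    to <- min(from + size - 1L, n)
    idx <- ord[from:to]
    list(label = sprintf("q%.2f-%.2f", starts_q[j], starts_q[j] + window_mass),
         idx = idx,
         center = stats::median(townsend[idx]))
  })
}

#' Effective number of independent traits
#'
#' Pairwise Pearson correlations are computed on overlapping samples (set
#' to zero when fewer than `min_overlap` samples overlap); the resulting
#' correlation matrix is eigendecomposed with negative eigenvalues floored
#' at zero (the pairwise-patched matrix need not be positive
#' semi-definite), and the effective number of tests is the smallest k
#' whose top-k eigenvalues explain at least `var_explained` of the total.
#'
#' @param pheno Numeric matrix, samples in rows, traits in columns
#'   (missing values allowed).
#' @param var_explained Target fraction of variance (default 0.99).
#' @param min_overlap Minimum number of overlapping samples for a
#'   correlation to be used (default 3).
#' @return Integer Meff.
#' @export
effective_num_tests <- function(pheno, var_explained = 0.99, min_overlap = 3L) {
  pheno <- as.matrix(pheno)
  t_n <- ncol(pheno)
  if (t_n < 2L) stop("need at least 2 traits")
  obs <- !is.na(pheno)
  overlap <- crossprod(obs)
  C <- suppressWarnings(stats::cor(pheno, use = "pairwise.complete.obs"))
  C[overlap < min_overlap] <- 0
  C[is.na(C)] <- 0
  diag(C) <- 1
  isolated <- colSums(overlap >= min_overlap) <= 1L # only itself
  if (any(isolated)) {
    warning(sum(isolated), " trait(s) share <", min_overlap,
            " samples with every other trait; correlations set to 0")
  }
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  frac <- cumsum(ev) / sum(ev)
  as.integer(which(frac >= var_explained - 1e-12)[1L])
}

#' Bonferroni-style correction by the effective number of tests
#'
#' @param p Uncorrected p-value(s) in [0, 1].
#' @param Meff Effective number of independent tests (>= 1).
#' @return `pmin(1, p * Meff)`.
#' @export
adjust_pvalues <- function(p, Meff) {
  stopifnot(all(p >= 0 & p <= 1), Meff >= 1)
  pmin(1, p * Meff)
}

#' Per-stratum heritability estimates
#'
#' Applies [estimate_h2()] to each stratum (a subset of samples), subsetting
#' the GRM to the stratum rows/columns. For binary traits, the sample
#' prevalence is recomputed within each stratum and the liability transform
#' re-applied per stratum. Strata smaller than `min_n` are dropped with a
#' warning.
#'
#' @param y Named phenotype vector (names = sample IDs).
#' @param K A `grm`.
#' @param X Covariate matrix (rows aligned with `y`), or `NULL`.
#' @param strata Named list of sample-ID (or index) vectors, one per
#'   stratum.
#' @param liability Convert binary traits to the liability scale per
#'   stratum (default `TRUE`).
#' @param min_n Minimum stratum size (default 500).
#' @param ... Passed to [estimate_h2()].
#' @return Data frame with one row per retained stratum: `stratum`, `n`,
#'   `prevalence`, `h2`, `se`, `h2_clamped`, `scale`.
#' @export
estimate_h2_strata <- function(y, K, X = NULL, strata, liability = TRUE,
                               min_n = 500L, ...) {
  stopifnot(inherits(K, "grm"))
  ids <- if (is.null(names(y))) K$sample_ids else names(y)
  rows <- lapply(names(strata), function(lab) {
    sel <- strata[[lab]]
    pick <- if (is.character(sel)) ids %in% sel else seq_along(ids) %in% sel
    pick <- pick & !is.na(y)
    if (sum(pick) < min_n) {
      warning(sprintf("stratum '%s' has %d samples (< %d); dropped",
                      lab, sum(pick), min_n))
      return(NULL)
    }
    est <- estimate_h2(y[pick], K, X = if (is.null(X)) NULL else
                       X[pick, , drop = FALSE], ids = ids[pick], ...)
    if (liability && !is.na(est$prevalence)) {
      est <- observed_to_liability(est)
    }
    data.frame(stratum = lab, n = est$n, prevalence = est$prevalence,
               h2 = est$h2, se = est$se, h2_clamped = est$h2_clamped,
               scale = est$scale, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
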