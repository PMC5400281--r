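---
title: "Moment-matching SNP heritability: model, assumptions and design choices"
author: "mmherit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moment-matching SNP heritability: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmherit)
```

## The model

`mmherit` estimates the proportion of phenotypic variance tagged by
genotyped common variants (SNP heritability) under the standard additive
random-effects model. For an $N$-vector trait $y$,

$$y = X\beta + g + e, \qquad
\operatorname{cov}[y] = \sigma_g^2 K + \sigma_e^2 I,$$

where $K$ is the empirical genomic relatedness matrix (GRM), $X$ is an
$N \times q$ matrix of fixed covariates, $g$ collects additive genetic
effects of genotyped SNPs and $e$ subject-specific environmental noise.
SNP heritability is $h^2_{SNP} = \sigma_g^2 / (\sigma_g^2 + \sigma_e^2)$,
a lower bound on narrow-sense heritability because untyped and poorly
tagged variation (notably rare variants) is not captured.

The GRM follows the GCTA convention,

$$K_{jk} = \frac{1}{m} \sum_{i=1}^{m}
\frac{(x_{ij} - 2p_i)(x_{ik} - 2p_i)}{2p_i(1 - p_i)},$$

with in-sample allele frequencies $p_i$ estimated from non-missing
dosages and missing dosages mean-imputed per SNP (their standardized
contribution is zero). Only autosomal SNPs are accepted; monomorphic SNPs
are skipped (with a warning and a recorded count) rather than rejected,
because region masks can create them. `region_mask()` supports exclusion
of high-LD regions such as the MHC (chr6:25–35 Mb) and the chromosome 8
inversion (chr8:7–13 Mb), whose dense signal can dominate estimates for
immune-mediated traits; comparing masked and unmasked runs is the
intended sensitivity analysis.

## The estimator

Rather than maximizing a likelihood (ReML), the package matches moments:
the empirical phenotypic covariance is regressed on its model components,

$$\operatorname{vec}[y y^\top] = \sigma_g^2 \operatorname{vec}[K]
  + \sigma_e^2 \operatorname{vec}[I] + \epsilon.$$

This vectorized regression includes the diagonal of $yy^\top$, which
distinguishes it from off-diagonal-only Haseman–Elston regression; the
closed form below follows from this choice. With
$\tau = \operatorname{tr}[K]/M$, $\kappa = \operatorname{tr}[K^2]/M$ and
$v_K = M(\kappa - \tau^2)$, the OLS solution is

$$\hat\sigma_g^2 = \frac{1}{v_K} y^\top (K - \tau I)\, y, \qquad
  \hat\sigma_e^2 = \frac{1}{v_K} y^\top (\kappa I - \tau K)\, y.$$

The estimator is left unconstrained — components and $\hat h^2$ may fall
outside $[0, 1]$ — and a clamped copy in $[0, 1]$ is always reported
alongside, so boundary values in reports are recognizable as clamping
rather than constrained optimization. When $v_K \le 0$ (K proportional to
the identity after projection) the model is unidentifiable and the
package says so rather than returning numbers.

### Covariate projection without forming it

Covariates are eliminated, not estimated: an $N \times (N-q)$
semi-orthogonal $U$ with $U^\top U = I$, $UU^\top = P_0 = I -
X(X^\top X)^{-1}X^\top$ and $U^\top X = 0$ turns the model into a
covariate-free one in $\tilde y = U^\top y$, $\tilde K = U^\top K U$.
Neither $U$ nor $P_0$ is ever materialized. All four $\tilde{}$-basis
quantities reduce to block-column identities in $K$:

- $\operatorname{tr}[\tilde K] = \operatorname{tr}[K] -
  \operatorname{tr}[(X^\top X)^{-1} X^\top K X]$
- $\operatorname{tr}[\tilde K^2] = \operatorname{tr}[K^2] -
  2\operatorname{tr}[(X^\top X)^{-1} X^\top K^2 X] +
  \operatorname{tr}[((X^\top X)^{-1} X^\top K X)^2]$
- $\tilde y^\top \tilde K \tilde y = (P_0 y)^\top K (P_0 y)$, and
  $\tilde y^\top \tilde y = y^\top P_0 y$

`compute_projected_quadratics()` accumulates every $K$-dependent term one
column block at a time (default 1024 columns, configurable), so peak
memory beyond one block is $O(Nq + q^2)$, never $O(N^2)$; accumulation is
always in double precision even though the on-disk GRM is single
precision. Results are invariant to the block size (a tested property),
so the iteration order is immaterial.

After the transform the problem has dimension $M = N - q$, and the
package uses $M$ in the denominators of $\tau$, $\kappa$ and $v_K$. The
covariate-free formulas are often written with $N$; with $q \ll N$ the
difference is negligible, and $M$ is the mathematically consistent choice
in the projected basis, so it is used throughout.

### Standard error

The sampling variance uses the near-identity approximation: when the
off-diagonal entries of $K$ are small (unrelated individuals), $V =
\operatorname{cov}[y] \approx \sigma_p^2 I$ and

$$\operatorname{var}[\hat h^2_{SNP}] \approx 2 / v_K.$$

This assumes a Gaussian trait and a precisely estimated $\sigma_p^2$; the
same formula is applied to binary traits on the observed scale, which is
known empirically to be accurate at large sample sizes. The
approximation's calibration is itself a tested property: across 200
simulated replicates at $N = 1000$ the empirical spread of $\hat h^2$
must sit within 25% of $\sqrt{2/v_K}$.

## Binary traits and the liability scale

A binary trait is modeled as a thresholded latent standard-normal
liability. With prevalence $P$ and threshold $t = \Phi^{-1}(1-P)$, the
observed-scale estimate converts linearly:

$$h^2_{SNP,L} = c\, h^2_{SNP}, \qquad
  c = \frac{P(1-P)}{\varphi(t)^2}, \qquad
  \operatorname{var}[h^2_{SNP,L}] = c^2 \operatorname{var}[h^2_{SNP}].$$

$c = \pi/2$ at $P = 0.5$, is symmetric in $P \leftrightarrow 1-P$, and
grows as prevalence moves away from one half. By default the population
prevalence is taken equal to the sample prevalence, which is appropriate
for population-based cohorts; `observed_to_liability(est, P = ...)`
overrides it for under-ascertained diseases. No case-control
(PCGC-style) ascertainment correction is applied — the package targets
population samples, and applying the plain transform to strongly
ascertained data will underestimate liability-scale heritability.

## Trait preprocessing

The preprocessing rules are deliberately simple and are applied in a
fixed order by `run_scan()`:

- **Outliers** (continuous): samples more than 5 SD from the mean are
  excluded in a single pass — mean and SD are computed once on all
  non-missing values and not re-estimated after exclusion. The rule is
  idempotent on its own output.
- **Binarization** (categorical): ordinal values are split at a stated
  cutoff (cases are `>= cutoff`); nominal values by a case label set.
  Missing stays missing; a cutoff outside the observed support is an
  error, not an empty class.
- **Prevalence floor** (binary): the trait passes only if the *minor*
  class frequency exceeds 1% — a two-sided reading, so near-unanimous
  traits fail for the same information-content reason as near-empty
  ones.
- **Precision filter**: estimates with SE $\ge$ 0.1 are excluded from
  reporting, strictly, and post hoc — the trait is analyzed, then
  flagged, mirroring how underpowered disease codes are typically
  dropped from published tables.
- **Sex specificity**: a disease is called sex-specific when one sex's
  prevalence exceeds 100 times the other's (zero denominators with
  nonzero numerators count as specific); analysis is then restricted to
  the affected sex.

## Stratified heritability

`estimate_h2_strata()` re-runs the estimator on subset rows/columns of
the same GRM; a stratum equal to the full sample reproduces the
unstratified estimate exactly (tested). For binary traits the prevalence
is recomputed within each stratum and the liability transform re-applied
per stratum. Strata below 500 samples (configurable) are dropped with a
warning — below that size $v_K$ is typically so small that the SE is
uninformative.

Two strata are compared with a normal z-test on independent estimates,
$z = (\hat h^2_A - \hat h^2_B)/\sqrt{se_A^2 + se_B^2}$. Age trends use
sliding 10-year windows stepping by one year (40–49 through 64–73 by
default, 25 windows) and a weighted linear regression of the per-window
estimates on the window mean age. Weights are $1/se_k$ — the inverse of
the standard error, as stated, not inverse variance — and the slope is
tested against zero with a t-reference on $k - 2$ degrees of freedom
(the small number of windows argues for t rather than z). When the fit
is numerically exact (zero residual variance), the p-value convention is
1 for a zero slope and 0 otherwise, so constant inputs do not produce
spurious significance. Disease codes should be excluded from age
stratification via the manifest flag: age at recruitment does not
reflect disease onset.

Socioeconomic stratification slides a window holding one third of the
sample (by rank of the Townsend deprivation index) from the bottom to
the top of the distribution. The number of sliding positions is not
canonical; the default is 10 equally spaced quantile starts with window
mass 1/3, both exposed as arguments (`make_ses_windows()`), and 3
positions with mass 1/3 reduce to disjoint tertiles.

### Multiple testing

Stratification scans test many correlated traits. `effective_num_tests()`
computes pairwise Pearson correlations on overlapping samples (zero when
fewer than 3 samples overlap, e.g. sex-specific trait pairs),
eigendecomposes the patched correlation matrix, and returns the smallest
number of principal components explaining 99% of total variance. Because
pairwise-complete correlations with zero patching need not form a
positive semi-definite matrix, negative eigenvalues are floored at zero
before summing. Uncorrected p-values are multiplied by this effective
number and capped at 1.

## The synthetic-data generator

`simulate_genotypes()` emulates a post-QC biobank panel: unrelated
diploid individuals, each SNP in Hardy–Weinberg equilibrium with MAF
drawn uniformly from a stated range (floor 0.01, mirroring the usual
exclusion of rare variants), dosages binomial(2, MAF) independent across
samples and SNPs. `simulate_phenotype()` draws causal effects i.i.d.
$N(0, h^2/n_{causal})$ on *standardized* dosages — the GCTA-consistent
architecture the estimator implicitly assumes — with causal SNPs placed
uniformly at random, and environmental noise $N(0, 1-h^2)$.
`simulate_binary()` thresholds the realized liability at its empirical
quantile so the sample prevalence lands within $1/N$ of the target;
binary traits are generated unascertained.

What the generator deliberately does **not** emulate: linkage
disequilibrium, MAF-dependent effect sizes, relatedness, population
stratification, ascertainment, genotyping error. Passing the recovery
tests therefore shows the estimator is correct *under its own model
assumptions*; it does not certify robustness to LD-structured or
stratified real data, where the same assumptions are known to bias any
single-component GRM method.

## Validation strategy and problem sizes

Every estimator path is checked against an independent oracle:

- `vec_ols_oracle()` solves the vectorized regression densely after
  explicit projection with an orthonormal basis — the streamed closed
  form must agree to $10^{-10}$ on random instances ($N \le 100$,
  $q \in \{0, 1, 5\}$, block sizes 1, 7 and $N$).
- `reml_oracle()` maximizes the restricted likelihood by
  eigendecomposition and a 1-D profile search over $h^2 \in [0,1]$, with
  SEs from the inverse Fisher information; moment matching must agree
  within 3 pooled SEs on Gaussian traits ($N = 500$, $m = 2000$).
- Parameter recovery uses panels of $N = 2000$, $m = 5000$ with 50
  phenotype replicates per heritability level
  ($h^2 \in \{0, 0.2, 0.5, 0.8\}$; binary at prevalence 0.1 and 0.5 with
  liability $h^2 = 0.4$), sharing one genotype panel per level — the
  estimator is unbiased conditional on $K$, and sharing the panel keeps
  the suite fast without weakening the check. SE calibration uses
  $N = 1000$, $m = 5000$, 200 replicates.

These sizes were chosen as the smallest at which the near-identity SE
regime ($N/m$ small enough that $K$ is diagonally dominant) clearly
holds while the whole suite stays quick to run.

## Numerical choices

- GRM accumulation, projection and quadratics: double precision
  throughout; the GCTA on-disk format is single precision by definition,
  so round-trips are exact only to ~$10^{-6}$ relative.
- Collinear covariates are an error naming the offending columns, not a
  silent drop; $M < 2$ is a degenerate-model error.
- `estimate_h2()` drops samples listwise on missing phenotype or
  covariates and subsets the GRM before projection, so each trait uses
  its own complete-case $N$.
- The ReML oracle's profile search snaps to the boundary when the
  endpoint likelihood beats the interior optimum, and flags boundary
  solutions.
- Ties in liability thresholding are broken by position; the case count
  is `round(P * N)` with a floor of one case.

## Limitations

Beyond the generator's idealizations listed above: the moment estimator
is statistically less efficient than ReML (a price that vanishes in
relative terms at biobank $N$); the liability transform is first-order
and degrades for very high liability heritability at low prevalence; the
SE formula leans on near-identity $K$ and Gaussianity; and a
single-component GRM cannot separate MAF or LD strata — traits whose
causal variants concentrate in high-LD regions (e.g. MHC-driven
autoimmune disease) need the region-exclusion sensitivity analysis, and
properly MAF/LD-stratified models are out of scope.
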