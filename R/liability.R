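# Observed-to-liability scale conversion for binary traits.
#
# Under the classical liability threshold model a binary trait is a
# thresholded latent standard-normal liability; the observed-scale
# heritability of the 0/1 indicator maps linearly onto the liability scale
# through c = P(1-P)/phi(t)^2, where P is the population prevalence and
# t = qnorm(1-P) the threshold. The conversion makes estimates independent
# of prevalence and hence comparable across traits.

#' Liability-scale conversion factor
#'
#' @param P Population prevalence, strictly inside (0, 1).
#' @return An object of class `liability_params`: list with `P`, the
#'   threshold `t = qnorm(1 - P)`, and the factor
#'   `c = P(1 - P) / dnorm(t)^2`. At `P = 0.5`, `c = pi/2`; the factor is
#'   symmetric in `P` and `1 - P` and grows as prevalence moves away from
#'   one half.
#' @examples
#' liability_factor(0.5)$c  # pi/2
#' liability_factor(0.01)$c # ~13.94
#' @export
liability_factor <- function(P) {
  if (!is.numeric(P) || length(P) != 1L || is.na(P) || P <= 0 || P >= 1) {
    stop("prevalence must be a single value strictly inside (0, 1)")
  }
  t <- stats::qnorm(1 - P)
  c_fac <- P * (1 - P) / stats::dnorm(t)^2
  structure(list(P = P, t = t, c = c_fac), class = "liability_params")
}

#' Convert an observed-scale estimate to the liability scale
#'
#' Applies the linear transform h2_L = c * h2 and se_L = c * se (variance
#' scales by c^2). No ascertainment correction is applied: the factor is
#' exact for population-based samples where the sample prevalence estimates
#' the population prevalence; for case-control ascertained data a
#' PCGC-style correction would be required instead.
#'
#' @param est A `heritability_estimate` on the observed scale.
#' @param P Population prevalence; defaults to the sample prevalence
#'   recorded in `est`. Supply explicitly for under-ascertained diseases.
#' @return A `heritability_estimate` with `scale = "liability"`.
#' @export
observed_to_liability <- function(est, P = est$prevalence) {
  stopifnot(inherits(est, "heritability_estimate"))
  if (identical(est$scale, "liability")) {
    stop("estimate is already on the liability scale")
  }
  if (is.null(P) || is.na(P)) {
    stop("no prevalence available: trait is not binary and P not supplied")
  }
  lp <- liability_factor(P)
  new_heritability_estimate(
    h2 = lp$c * est$h2, se = lp$c * est$se, scale = "liability",
    n = est$n, prevalence = P,
    components = est$components, quadratics = est$quadratics)
}
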