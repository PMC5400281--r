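# Trait preprocessing: outlier exclusion, binarization of categorical
# variables, prevalence/precision filters, and sex-specificity detection.

#' Exclude extreme outliers from a continuous trait
#'
#' Single-pass rule: samples more than `n_sd` standard deviations from the
#' mean (both computed once, on all non-missing values) are excluded. The
#' mean/SD are not re-estimated after exclusion.
#'
#' @param y Numeric vector; names are used as sample IDs when present.
#' @param n_sd Exclusion threshold in standard deviations (default 5).
#' @return List with `values` (the retained vector, names preserved) and
#'   `excluded` (IDs, or integer positions when `y` is unnamed, of the
#'   excluded samples). A zero-variance input is returned unchanged with a
#'   warning.
#' @export
filter_outliers <- function(y, n_sd = 5) {
  ids <- if (is.null(names(y))) seq_along(y) else names(y)
  ok <- !is.na(y)
  if (sum(ok) < 2L) stop("need at least 2 non-missing values")
  mu <- mean(y[ok])
  sdev <- stats::sd(y[ok])
  if (sdev == 0) {
    warning("zero variance; no outlier exclusion possible")
    return(list(values = y, excluded = ids[0L]))
  }
  out <- ok & abs(y - mu) > n_sd * sdev
  list(values = y[!out], excluded = ids[out])
}

#' Binarize a categorical or ordinal trait
#'
#' Ordinal/numeric values are cases when `>= cutoff`; character or factor
#' values are cases when they match the `cutoff` label set (e.g. skin
#' colour "very fair"/"fair" vs. other). Missing values stay missing.
#'
#' @param values Numeric/ordered vector, or character/factor.
#' @param cutoff Numeric threshold, or character vector of case labels.
#' @return List with `values` (0/1 integer vector, `NA` preserved),
#'   `prevalence` (case fraction among non-missing), and `case_definition`
#'   (human-readable rule applied). Errors if the rule puts all non-missing
#'   samples in one class.
#' @export
binarize <- function(values, cutoff) {
  if (is.character(cutoff) || is.factor(cutoff)) {
    b <- ifelse(is.na(values), NA_integer_,
                as.integer(as.character(values) %in% as.character(cutoff)))
    def <- paste0("in {", paste(cutoff, collapse = ", "), "}")
  } else {
    if (is.factor(values) && !is.ordered(values)) {
      stop("numeric cutoff requires numeric or ordered values")
    }
    v <- if (is.ordered(values)) as.integer(values) else values
    b <- ifelse(is.na(v), NA_integer_, as.integer(v >= cutoff))
    def <- paste0(">= ", cutoff)
  }
  p <- mean(b, na.rm = TRUE)
  if (is.nan(p) || p == 0 || p == 1) {
    stop("all-one-class: cutoff (", def, ") outside the observed support")
  }
  list(values = b, prevalence = p, case_definition = def)
}

#' Minimum-prevalence filter for binary traits
#'
#' Passes when the minor class frequency min(p, 1-p) exceeds
#' `min_prevalence`, so both near-empty and near-unanimous traits fail.
#'
#' @param y Binary 0/1 vector (`NA` allowed).
#' @param min_prevalence Prevalence floor (default 0.01).
#' @return `TRUE`/`FALSE`.
#' @export
prevalence_filter <- function(y, min_prevalence = 0.01) {
  v <- y[!is.na(y)]
  stopifnot(all(v %in% c(0, 1)))
  p <- mean(v)
  min(p, 1 - p) > min_prevalence
}

#' Precision filter on a heritability estimate
#'
#' Passes when the standard error is strictly smaller than `max_se`;
#' intended as a post hoc reporting filter on completed estimates.
#'
#' @param est A `heritability_estimate` (or anything with an `se` field).
#' @param max_se SE ceiling (default 0.1).
#' @return `TRUE`/`FALSE`.
#' @export
precision_filter <- function(est, max_se = 0.1) {
  est$se < max_se
}

#' Detect sex-specific diseases from sex-stratified prevalence
#'
#' A disease is called male-specific when its prevalence in males exceeds
#' 100 times the prevalence in females (and symmetrically female-specific);
#' a zero denominator with a nonzero numerator also triggers specificity.
#'
#' @param prev_male,prev_female Sample prevalences in [0, 1].
#' @param ratio Specificity threshold (default 100).
#' @return `"both"`, `"male_only"` or `"female_only"`; `NA` (with a
#'   warning) when both prevalences are zero.
#' @export
detect_sex_specific <- function(prev_male, prev_female, ratio = 100) {
  stopifnot(prev_male >= 0, prev_male <= 1, prev_female >= 0, prev_female <= 1)
  if (prev_male == 0 && prev_female == 0) {
    warning("both prevalences are zero; sex specificity undefined")
    return(NA_character_)
  }
  if (prev_female == 0 || prev_male / prev_female > ratio) return("male_only")
  if (prev_male == 0 || prev_female / prev_male > ratio) return("female_only")
  "both"
}
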