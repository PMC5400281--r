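# Phenome-scan orchestration: many traits against one GRM, with
# preprocessing, estimation, liability conversion, reporting filters and
# optional stratification.

#' Read a trait manifest
#'
#' Tab-delimited manifest with one row per trait: `name` (column in the
#' phenotype table), `kind` ("continuous", "binary" or "categorical"),
#' `cutoff` (binarization rule for categorical traits: a number, or a
#' comma-separated label set), `covariates` (comma-separated covariate
#' column names, may be empty), and optionally `age_stratify` (0/1 flag;
#' disease codes are excluded from age stratification since age at
#' recruitment does not reflect onset).
#'
#' @param path Path to the TSV manifest.
#' @return Data frame with normalized columns.
#' @export
read_trait_manifest <- function(path) {
  man <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           na.strings = c("NA", ""))
  stopifnot(all(c("name", "kind") %in% names(man)))
  if (nrow(man) == 0L) stop("empty trait manifest")
  bad <- !man$kind %in% c("continuous", "binary", "categorical")
  if (any(bad)) stop("unknown trait kind: ", man$kind[bad][1L])
  if (is.null(man$cutoff)) man$cutoff <- NA
  if (is.null(man$covariates)) man$covariates <- NA_character_
  if (is.null(man$age_stratify)) man$age_stratify <- 1L
  man
}

.scan_covariates <- function(pheno, spec_str, default_covars) {
  covs <- if (is.na(spec_str) || !nzchar(spec_str)) default_covars
          else trimws(strsplit(spec_str, ",")[[1L]])
  covs <- covs[nzchar(covs)]
  if (length(covs) == 0L) return(NULL)
  missing_cols <- setdiff(covs, names(pheno))
  if (length(missing_cols) > 0L) {
    stop("covariate column(s) not found: ", paste(missing_cols, collapse = ", "))
  }
  X <- as.matrix(pheno[, covs, drop = FALSE])
  storage.mode(X) <- "double"
  X
}

.scan_one_trait <- function(trait, pheno, K, default_covars, n_sd,
                            min_prevalence, max_se, block_size) {
  y_raw <- pheno[[trait$name]]
  ids <- pheno$iid
  kind <- trait$kind
  prevalence <- NA_real_
  if (kind == "categorical") {
    cutoff <- trait$cutoff
    cutoff_num <- suppressWarnings(as.numeric(cutoff))
    cutoff <- if (!is.na(cutoff_num)) cutoff_num
              else trimws(strsplit(as.character(cutoff), ",")[[1L]])
    bz <- binarize(y_raw, cutoff)
    y <- bz$values
    kind <- "binary"
  } else {
    y <- as.numeric(y_raw)
  }
  excluded_ids <- character(0)
  if (kind == "continuous") {
    names(y) <- ids
    fo <- filter_outliers(y, n_sd = n_sd)
    excluded_ids <- as.character(fo$excluded)
    y[names(y) %in% excluded_ids] <- NA
  }
  if (kind == "binary") {
    if (!prevalence_filter(y, min_prevalence)) {
      stop("prevalence: minor class below ", min_prevalence)
    }
  }
  names(y) <- ids
  X <- .scan_covariates(pheno, trait$covariates, default_covars)
  est <- estimate_h2(y, K, X = X, ids = ids, block_size = block_size)
  row <- data.frame(
    trait = trait$name, type = kind, n = est$n,
    prevalence = est$prevalence,
    h2_observed = est$h2, se_observed = est$se,
    h2_liability = NA_real_, se_liability = NA_real_,
    h2_clamped = est$h2_clamped,
    covariates = if (is.null(X)) "" else paste(colnames(X), collapse = ","),
    n_outliers_excluded = length(excluded_ids),
    status = "ok", stringsAsFactors = FALSE)
  if (kind == "binary") {
    li <- observed_to_liability(est)
    row$h2_liability <- li$h2
    row$se_liability <- li$se
  }
  if (!precision_filter(est, max_se)) {
    row$status <- "excluded: precision"
  }
  row
}

#' Run a phenome scan
#'
#' For each manifest trait: preprocess (outlier exclusion for continuous
#' traits, binarization for categorical ones, prevalence floor for binary
#' ones), align samples, estimate heritability with covariates, convert
#' binary traits to the liability scale, and apply the precision filter
#' post hoc. Per-trait failures are isolated: the trait is reported with
#' an exclusion reason and the scan continues. The report is deterministic
#' given the inputs.
#'
#' @param pheno Data frame with a sample-ID column `iid`, trait columns,
#'   and covariate columns.
#' @param K A `grm` covering (at least) the scanned samples.
#' @param manifest Data frame as from [read_trait_manifest()].
#' @param default_covars Character vector of covariate columns used when a
#'   trait row does not specify its own (e.g. array/center factors, age,
#'   sex, top genotype PCs, all supplied as columns).
#' @param n_sd Outlier threshold for continuous traits (default 5 SD).
#' @param min_prevalence Prevalence floor for binary traits (default 0.01).
#' @param max_se Precision ceiling on the SE (default 0.1).
#' @param block_size GRM streaming block size.
#' @return Data frame (`scan_report`), one row per manifest trait, with
#'   S1/S2-style columns: trait, type, N, prevalence, observed- and
#'   liability-scale h2 and SE, clamped h2, covariates used, and a status
#'   ("ok" or an exclusion reason).
#' @export
run_scan <- function(pheno, K, manifest,
                     default_covars = character(0), n_sd = 5,
                     min_prevalence = 0.01, max_se = 0.1,
                     block_size = 1024L) {
  stopifnot(is.data.frame(pheno), "iid" %in% names(pheno))
  if (nrow(manifest) == 0L) stop("empty trait manifest")
  missing_traits <- setdiff(manifest$name, names(pheno))
  if (length(missing_traits) > 0L) {
    stop("manifest trait(s) not in phenotype table: ",
         paste(missing_traits, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    trait <- manifest[i, ]
    tryCatch(
      .scan_one_trait(trait, pheno, K, default_covars, n_sd,
                      min_prevalence, max_se, block_size),
      error = function(e) {
        message(sprintf("trait '%s' excluded: %s", trait$name,
                        conditionMessage(e)))
        data.frame(trait = trait$name, type = trait$kind, n = NA_integer_,
                   prevalence = NA_real_, h2_observed = NA_real_,
                   se_observed = NA_real_, h2_liability = NA_real_,
                   se_liability = NA_real_, h2_clamped = NA_real_,
                   covariates = "", n_outliers_excluded = NA_integer_,
                   status = paste0("excluded: ", conditionMessage(e)),
                   stringsAsFactors = FALSE)
      })
  })
  report <- do.call(rbind, rows)
  class(report) <- c("scan_report", "data.frame")
  report
}

#' Write a scan report as TSV
#'
#' @param report A `scan_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_scan_report <- function(report, path) {
  utils::write.table(report, path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}
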