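# Genomic relatedness matrix (GRM) construction and GCTA-format I/O.

#' Construct a genotype block
#'
#' A genotype block is a slice of the SNP panel: an N x m_block integer
#' dosage matrix with per-SNP metadata, used to stream GRM accumulation.
#' Dosages count one of the two alleles (0/1/2, `NA` missing); which allele
#' is counted is immaterial to the GRM (standardization is sign-symmetric).
#'
#' @param dosages Integer matrix, samples x SNPs, values in \{0, 1, 2, NA\}.
#' @param chrom Integer vector of chromosomes (autosomes 1-22 only).
#' @param pos Integer vector of base-pair positions.
#' @param id Character vector of SNP identifiers.
#' @param sample_ids Character vector of sample identifiers.
#' @return An object of class `genotype_block`.
#' @export
genotype_block <- function(dosages, chrom, pos, id = NULL,
                           sample_ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  m <- ncol(dosages)
  if (is.null(id)) id <- sprintf("snp%d_%d", chrom, pos)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%d", seq_len(nrow(dosages)))
  stopifnot(length(chrom) == m, length(pos) == m, length(id) == m)
  if (anyDuplicated(sample_ids)) stop("duplicate sample IDs")
  bad <- !(dosages %in% c(0L, 1L, 2L) | is.na(dosages))
  if (any(bad)) {
    stop("dosage values outside {0, 1, 2, NA}: e.g. ",
         dosages[which(bad)[1L]])
  }
  if (any(chrom < 1L | chrom > 22L)) {
    stop("only autosomal SNPs (chromosomes 1-22) are accepted")
  }
  structure(list(dosages = dosages,
                 snp_meta = data.frame(chrom = as.integer(chrom),
                                       pos = as.integer(pos),
                                       id = as.character(id),
                                       stringsAsFactors = FALSE),
                 sample_ids = as.character(sample_ids)),
            class = "genotype_block")
}

#' Define genomic regions to exclude from the GRM
#'
#' Closed base-pair intervals on autosomes, e.g. the MHC (chr6:25-35Mb) or
#' the chromosome 8 inversion (chr8:7-13Mb), whose dense long-range LD can
#' dominate heritability estimates for some traits.
#'
#' @param chrom Integer vector of chromosomes (1-22).
#' @param start_bp,end_bp Integer vectors of interval bounds, `start_bp <=
#'   end_bp`, both inclusive.
#' @return An object of class `region_mask` (data frame of intervals).
#' @examples
#' region_mask(c(6, 8), c(25e6, 7e6), c(35e6, 13e6)) # MHC + chr8 inversion
#' @export
region_mask <- function(chrom, start_bp, end_bp) {
  chrom <- as.integer(chrom)
  stopifnot(length(chrom) == length(start_bp),
            length(chrom) == length(end_bp))
  if (any(chrom < 1L | chrom > 22L)) stop("mask chromosomes must be in 1-22")
  if (any(start_bp > end_bp)) stop("mask start_bp must be <= end_bp")
  structure(data.frame(chrom = chrom,
                       start_bp = as.numeric(start_bp),
                       end_bp = as.numeric(end_bp)),
            class = c("region_mask", "data.frame"))
}

#' Parse a region string such as "chr6:25e6-35e6"
#'
#' @param x Character vector, each element "chr<C>:<start>-<end>" (the
#'   "chr" prefix is optional; numbers may use scientific notation).
#' @return A `region_mask`.
#' @export
parse_region <- function(x) {
  m <- regmatches(x, regexec("^(?:chr)?([0-9]+):([0-9eE.+]+)-([0-9eE.+]+)$", x))
  if (any(lengths(m) != 4L)) stop("cannot parse region: ", x[lengths(m) != 4L][1L])
  parts <- do.call(rbind, m)
  region_mask(as.integer(parts[, 2L]),
              as.numeric(parts[, 3L]),
              as.numeric(parts[, 4L]))
}

.in_mask <- function(chrom, pos, mask) {
  if (is.null(mask) || nrow(mask) == 0L) return(rep(FALSE, length(chrom)))
  hit <- rep(FALSE, length(chrom))
  for (k in seq_len(nrow(mask))) {
    hit <- hit | (chrom == mask$chrom[k] &
                  pos >= mask$start_bp[k] & pos <= mask$end_bp[k])
  }
  hit
}

# Normalize the accepted genotype sources to a block iterator: a closure
# returning the next genotype_block, or NULL when exhausted.
.block_iterator <- function(source, block_size) {
  if (inherits(source, "genotype_block")) source <- list(source)
  if (is.character(source) && length(source) == 1L) {
    # PLINK prefix: stream SNP blocks off disk
    bim <- utils::read.table(paste0(source, ".bim"), header = FALSE,
                             stringsAsFactors = FALSE)
    m <- nrow(bim)
    starts <- seq(1L, m, by = block_size)
    i <- 0L
    return(function() {
      i <<- i + 1L
      if (i > length(starts)) return(NULL)
      idx <- starts[i]:min(starts[i] + block_size - 1L, m)
      pl <- read_plink(source, snp_idx = idx)
      genotype_block(pl$dosages, pl$snp_meta$chrom, pl$snp_meta$pos,
                     pl$snp_meta$id, sample_ids = pl$fam$iid)
    })
  }
  if (is.matrix(source)) {
    meta <- attr(source, "snp_meta")
    if (is.null(meta)) {
      stop("matrix source requires a 'snp_meta' attribute (chrom, pos, id)")
    }
    starts <- seq(1L, ncol(source), by = block_size)
    i <- 0L
    return(function() {
      i <<- i + 1L
      if (i > length(starts)) return(NULL)
      idx <- starts[i]:min(starts[i] + block_size - 1L, ncol(source))
      genotype_block(source[, idx, drop = FALSE],
                     meta$chrom[idx], meta$pos[idx], meta$id[idx],
                     sample_ids = rownames(source))
    })
  }
  if (is.list(source)) {
    i <- 0L
    return(function() {
      i <<- i + 1L
      if (i > length(source)) return(NULL)
      source[[i]]
    })
  }
  if (is.function(source)) return(source)
  stop("unsupported genotype source")
}

#' Compute the genomic relatedness matrix
#'
#' Accumulates the GCTA-convention GRM
#' \deqn{K_{jk} = \frac{1}{m}\sum_i \frac{(x_{ij}-2p_i)(x_{ik}-2p_i)}
#'   {2p_i(1-p_i)}}
#' over all unmasked autosomal SNPs. Allele frequencies are estimated
#' in-sample from non-missing dosages; missing dosages are mean-imputed per
#' SNP (standardized contribution zero). Monomorphic SNPs are skipped with
#' a warning and excluded from the SNP count m. Accumulation is in double
#' precision.
#'
#' @param source Genotype source: a `genotype_block`, a list of blocks, an
#'   integer dosage matrix with a `snp_meta` attribute, a PLINK fileset
#'   prefix, or a no-argument function returning successive blocks (`NULL`
#'   when exhausted). Sample order must be identical across blocks.
#' @param mask Optional `region_mask`; SNPs inside any interval are dropped.
#' @param block_size Number of SNPs per block when the source is a matrix
#'   or a PLINK prefix.
#' @return An object of class `grm`: list with `values` (symmetric N x N
#'   matrix), `sample_ids`, `n_snps` (SNPs contributing), and
#'   `n_monomorphic` (skipped).
#' @examples
#' g <- simulate_genotypes(n_samples = 50, n_snps = 200, seed = 1)
#' K <- compute_grm(g)
#' mean(diag(K$values)) # close to 1 for HWE genotypes
#' @export
compute_grm <- function(source, mask = NULL, block_size = 1024L) {
  nxt <- .block_iterator(source, block_size)
  K <- NULL
  sample_ids <- NULL
  m <- 0L
  n_mono <- 0L
  repeat {
    blk <- nxt()
    if (is.null(blk)) break
    stopifnot(inherits(blk, "genotype_block"))
    if (is.null(sample_ids)) {
      sample_ids <- blk$sample_ids
      K <- matrix(0, length(sample_ids), length(sample_ids))
    } else if (!identical(blk$sample_ids, sample_ids)) {
      stop("sample IDs differ across genotype blocks")
    }
    keep <- !.in_mask(blk$snp_meta$chrom, blk$snp_meta$pos, mask)
    if (!any(keep)) next
    x <- blk$dosages[, keep, drop = FALSE]
    p <- colMeans(x, na.rm = TRUE) / 2
    poly <- is.finite(p) & p > 0 & p < 1
    n_mono <- n_mono + sum(!poly)
    if (!any(poly)) next
    x <- x[, poly, drop = FALSE]
    p <- p[poly]
    z <- sweep(x, 2L, 2 * p, `-`)
    z <- sweep(z, 2L, sqrt(2 * p * (1 - p)), `/`)
    z[is.na(z)] <- 0
    K <- K + tcrossprod(z)
    m <- m + ncol(z)
  }
  if (is.null(K)) stop("empty genotype source")
  if (n_mono > 0L) {
    warning(sprintf("%d monomorphic SNP(s) skipped", n_mono))
  }
  if (m == 0L) stop("empty-panel: no polymorphic SNP survives the mask")
  structure(list(values = K / m,
                 sample_ids = sample_ids,
                 n_snps = m,
                 n_monomorphic = n_mono),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("GRM: %d samples, %d SNPs (mean diagonal %.4f)\n",
              length(x$sample_ids), x$n_snps, mean(diag(x$values))))
  invisible(x)
}

#' Subset a GRM to a set of samples
#'
#' @param K A `grm`.
#' @param ids Character vector of sample IDs (order preserved), or an
#'   integer/logical index vector.
#' @return A `grm` restricted to the requested samples.
#' @export
subset_grm <- function(K, ids) {
  if (is.character(ids)) {
    idx <- match(ids, K$sample_ids)
    if (anyNA(idx)) stop("unknown sample IDs: ", ids[is.na(idx)][1L], " ...")
  } else {
    idx <- seq_along(K$sample_ids)[ids]
  }
  structure(list(values = K$values[idx, idx, drop = FALSE],
                 sample_ids = K$sample_ids[idx],
                 n_snps = K$n_snps,
                 n_monomorphic = K$n_monomorphic),
            class = "grm")
}

#' Write a GRM as a GCTA binary triple
#'
#' Writes `<prefix>.grm.bin` (IEEE single-precision packed lower triangle,
#' row-major by individual, diagonal included), `<prefix>.grm.N.bin`
#' (single-precision per-pair SNP counts) and `<prefix>.grm.id`
#' (tab-delimited FID IID).
#'
#' @param K A `grm`.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_grm_gcta <- function(K, prefix) {
  v <- K$values
  if (!all(is.finite(v))) stop("GRM contains non-finite values")
  tri <- t(v)[upper.tri(v, diag = TRUE)] # (1,1),(2,1),(2,2),(3,1),...
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(tri), con, size = 4L)
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(K$n_snps), length(tri)), con, size = 4L)
  close(con)
  utils::write.table(data.frame(K$sample_ids, K$sample_ids),
                     paste0(prefix, ".grm.id"),
                     quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a GRM from a GCTA binary triple
#'
#' @param prefix Path prefix of the `.grm.bin`/`.grm.N.bin`/`.grm.id` triple.
#' @return A `grm` (values in double precision, symmetric by construction;
#'   `n_snps` is the rounded maximum of the per-pair counts).
#' @export
read_grm_gcta <- function(prefix) {
  idf <- paste0(prefix, ".grm.id")
  binf <- paste0(prefix, ".grm.bin")
  nf <- paste0(prefix, ".grm.N.bin")
  for (f in c(idf, binf, nf)) {
    if (!file.exists(f)) stop("missing GRM file: ", f)
  }
  ids <- utils::read.table(idf, header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(ids)
  len <- n * (n + 1) / 2
  con <- file(binf, "rb")
  tri <- readBin(con, "numeric", n = len + 1L, size = 4L)
  close(con)
  if (length(tri) != len) {
    stop(sprintf("GRM format error: %s holds %d values, expected %d for %d IDs",
                 binf, length(tri), len, n))
  }
  v <- matrix(0, n, n)
  v[upper.tri(v, diag = TRUE)] <- tri
  v <- t(v)
  v[upper.tri(v)] <- t(v)[upper.tri(v)]
  con <- file(nf, "rb")
  nsnp <- readBin(con, "numeric", n = len, size = 4L)
  close(con)
  structure(list(values = v,
                 sample_ids = as.character(ids[[2L]]),
                 n_snps = as.integer(round(max(nsnp))),
                 n_monomorphic = NA_integer_),
            class = "grm")
}
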