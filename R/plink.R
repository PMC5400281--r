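# PLINK 1 binary genotype I/O (.bed/.bim/.fam).
#
# The .bed payload is SNP-major: one SNP per record of ceiling(N/4) bytes,
# four samples per byte, two bits per sample starting from the lowest-order
# pair. Two-bit codes: 00 = homozygous A1 (dosage 2 copies of A1),
# 01 = missing, 10 = heterozygous, 11 = homozygous A2 (dosage 0).

.bed_magic <- as.raw(c(0x6c, 0x1b, 0x01))

# 256 x 4 dosage lookup: row = byte value + 1, column = sample slot in byte
.bed_decode_lut <- local({
  code_to_dosage <- c(2L, NA_integer_, 1L, 0L) # indexed by 2-bit code + 1
  lut <- matrix(NA_integer_, nrow = 256L, ncol = 4L)
  for (b in 0:255) {
    for (s in 0:3) {
      code <- bitwAnd(bitwShiftR(b, 2L * s), 3L)
      lut[b + 1L, s + 1L] <- code_to_dosage[code + 1L]
    }
  }
  lut
})

#' Read a PLINK 1 binary fileset
#'
#' Reads `<prefix>.bed`, `<prefix>.bim` and `<prefix>.fam` into an integer
#' dosage matrix (samples x SNPs, counting A1 alleles; `NA` for missing)
#' plus SNP and sample metadata.
#'
#' @param prefix Path prefix of the fileset (without extension).
#' @param snp_idx Optional integer vector of SNP indices (1-based, sorted)
#'   to read; defaults to all SNPs. Used for block-wise streaming.
#' @return A list with components `dosages` (integer matrix with sample IDs
#'   as rownames and SNP IDs as colnames), `snp_meta` (data frame with
#'   columns `chrom`, `id`, `pos`, `a1`, `a2`), and `fam` (the .fam table).
#' @export
read_plink <- function(prefix, snp_idx = NULL) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) {
    if (!file.exists(f)) stop("missing PLINK file: ", f)
  }
  bim_df <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                              col.names = c("chrom", "id", "cm", "pos", "a1", "a2"))
  fam_df <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE,
                              col.names = c("fid", "iid", "pid", "mid", "sex", "pheno"))
  n <- nrow(fam_df)
  m <- nrow(bim_df)
  bytes_per_snp <- (n + 3L) %/% 4L

  con <- file(bed, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 3L)
  if (length(magic) < 3L || !identical(magic, .bed_magic)) {
    stop(".bed magic bytes invalid or file not SNP-major: ", bed)
  }
  if (is.null(snp_idx)) snp_idx <- seq_len(m)
  stopifnot(all(snp_idx >= 1L), all(snp_idx <= m), !is.unsorted(snp_idx))

  out <- matrix(NA_integer_, nrow = n, ncol = length(snp_idx))
  slot <- rep(1:4, length.out = 4L * bytes_per_snp)[seq_len(n)]
  byte_of_sample <- rep(seq_len(bytes_per_snp), each = 4L)[seq_len(n)]
  for (j in seq_along(snp_idx)) {
    seek(con, where = 3 + (snp_idx[j] - 1) * bytes_per_snp, origin = "start")
    raw_j <- readBin(con, "raw", n = bytes_per_snp)
    if (length(raw_j) < bytes_per_snp) stop("truncated .bed record in ", bed)
    b <- as.integer(raw_j)
    out[, j] <- .bed_decode_lut[cbind(b[byte_of_sample] + 1L, slot)]
  }
  rownames(out) <- fam_df$iid
  colnames(out) <- bim_df$id[snp_idx]
  list(dosages = out,
       snp_meta = bim_df[snp_idx, c("chrom", "id", "pos", "a1", "a2")],
       fam = fam_df)
}

#' Write a PLINK 1 binary fileset
#'
#' @param dosages Integer matrix, samples x SNPs, values in \{0, 1, 2, NA\}
#'   counted as copies of allele A1.
#' @param snp_meta Data frame with columns `chrom`, `id`, `pos` and
#'   optionally `a1`, `a2` (defaults "A"/"B").
#' @param sample_ids Character vector of sample IDs (defaults to rownames).
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(dosages, snp_meta, prefix,
                        sample_ids = rownames(dosages)) {
  n <- nrow(dosages)
  m <- ncol(dosages)
  stopifnot(nrow(snp_meta) == m)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%d", seq_len(n))
  bad <- !(dosages %in% c(0L, 1L, 2L) | is.na(dosages))
  if (any(bad)) stop("dosage values outside {0, 1, 2, NA}")
  a1 <- if ("a1" %in% names(snp_meta)) snp_meta$a1 else rep("A", m)
  a2 <- if ("a2" %in% names(snp_meta)) snp_meta$a2 else rep("B", m)

  utils::write.table(
    data.frame(snp_meta$chrom, snp_meta$id, 0L, snp_meta$pos, a1, a2),
    paste0(prefix, ".bim"),
    quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(sample_ids, sample_ids, 0L, 0L, 0L, -9L),
    paste0(prefix, ".fam"),
    quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)

  dosage_to_code <- function(x) {
    code <- integer(length(x))          # dosage 2 -> 00
    code[is.na(x)] <- 1L                # missing  -> 01
    code[!is.na(x) & x == 1L] <- 2L     # het      -> 10
    code[!is.na(x) & x == 0L] <- 3L     # hom A2   -> 11
    code
  }
  bytes_per_snp <- (n + 3L) %/% 4L
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(.bed_magic, con)
  shift <- 2L * (0:3)
  for (j in seq_len(m)) {
    code <- dosage_to_code(dosages[, j])
    length(code) <- 4L * bytes_per_snp  # pads with NA
    code[is.na(code)] <- 0L
    quads <- matrix(code, nrow = 4L)
    bytes <- as.integer(colSums(quads * 2L^shift))
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}
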