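test_that("a single SNP with dosages {0,2} gives the +/-sqrt(2) product matrix", {
  blk <- genotype_block(matrix(c(0L, 2L), 2, 1), chrom = 1, pos = 100)
  K <- compute_grm(blk)
  expect_equal(K$values, matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12)
  expect_identical(K$n_snps, 1L)
})

test_that("streamed GRM matches the dense pairwise oracle, with missing dosages mean-imputed", {
  set.seed(11)
  g <- simulate_genotypes(5, 10, maf_range = c(0.2, 0.5))
  K <- suppressWarnings(compute_grm(g)) # tiny n can leave SNPs monomorphic
  expect_lt(max(abs(K$values - dense_grm_oracle(g))), 1e-12)

  gm <- g
  gm[sample(length(gm), 6)] <- NA_integer_
  attr(gm, "snp_meta") <- attr(g, "snp_meta")
  Km <- suppressWarnings(compute_grm(gm)) # NA injection may create monomorphs
  expect_lt(max(abs(Km$values - dense_grm_oracle(gm))), 1e-12)
})

test_that("region masks drop SNPs inside the interval only", {
  d <- matrix(c(0L, 1L, 2L, 2L, 1L, 0L), nrow = 3)
  blk <- genotype_block(d, chrom = c(6L, 7L), pos = c(30e6, 30e6))
  mhc <- region_mask(6, 25e6, 35e6)
  K <- compute_grm(blk, mask = mhc)
  expect_identical(K$n_snps, 1L)
  expect_equal(K$values, dense_grm_oracle(d[, 2, drop = FALSE]),
               tolerance = 1e-12)
  # parse_region gives the same mask
  expect_equal(as.data.frame(parse_region("chr6:25e6-35e6")),
               as.data.frame(mhc))
})

test_that("GRM accumulation is invariant to block size", {
  set.seed(12)
  g <- simulate_genotypes(40, 33, maf_range = c(0.1, 0.5))
  K_full <- compute_grm(g, block_size = ncol(g))
  for (b in c(1L, 7L)) {
    expect_lt(max(abs(compute_grm(g, block_size = b)$values - K_full$values)),
              1e-10)
  }
})

test_that("allele relabeling (x -> 2 - x) leaves the GRM unchanged", {
  set.seed(13)
  g <- simulate_genotypes(30, 50, maf_range = c(0.1, 0.5))
  g_flip <- 2L - g
  attr(g_flip, "snp_meta") <- attr(g, "snp_meta")
  expect_lt(max(abs(compute_grm(g)$values - compute_grm(g_flip)$values)),
            1e-12)
})

test_that("HWE panels give near-unit diagonal and near-zero off-diagonal", {
  set.seed(14)
  g <- simulate_genotypes(500, 5000, maf_range = c(0.05, 0.5))
  K <- compute_grm(g)$values
  expect_gt(mean(diag(K)), 0.95)
  expect_lt(mean(diag(K)), 1.05)
  off <- K[upper.tri(K)]
  expect_lt(abs(mean(off)), 3 / sqrt(5000))
})

test_that("monomorphic SNPs are skipped with a warning; an empty panel errors", {
  d <- cbind(c(0L, 1L, 2L), c(2L, 2L, 2L))
  blk <- genotype_block(d, chrom = c(1L, 1L), pos = c(1L, 2L))
  expect_warning(K <- compute_grm(blk), "monomorphic")
  expect_identical(K$n_snps, 1L)

  mono <- genotype_block(cbind(c(2L, 2L, 2L)), chrom = 1L, pos = 1L)
  expect_error(suppressWarnings(compute_grm(mono)), "empty-panel")
  blk6 <- genotype_block(d, chrom = c(6L, 6L), pos = c(26e6, 30e6))
  expect_error(compute_grm(blk6, mask = region_mask(6, 25e6, 35e6)),
               "empty-panel")
})

test_that("non-autosomal chromosomes and bad dosage values are rejected", {
  expect_error(genotype_block(cbind(c(0L, 1L)), chrom = 23L, pos = 1L),
               "autosomal")
  expect_error(genotype_block(cbind(c(0L, 3L)), chrom = 1L, pos = 1L),
               "dosage")
})

test_that("GCTA GRM round-trip preserves values to float32 and IDs exactly", {
  blk <- genotype_block(matrix(c(0L, 2L), 2, 1), chrom = 1, pos = 100,
                        sample_ids = c("A", "B"))
  K <- compute_grm(blk)
  prefix <- file.path(withr::local_tempdir(), "toy")
  write_grm_gcta(K, prefix)
  K2 <- read_grm_gcta(prefix)
  expect_lt(max(abs(K2$values - K$values)), 1e-6)
  expect_identical(K2$sample_ids, c("A", "B"))
  expect_identical(K2$n_snps, K$n_snps)

  set.seed(15)
  g <- simulate_genotypes(25, 60, maf_range = c(0.1, 0.5))
  Kg <- compute_grm(g)
  prefix2 <- file.path(withr::local_tempdir(), "sim")
  write_grm_gcta(Kg, prefix2)
  Kg2 <- read_grm_gcta(prefix2)
  expect_lt(max(abs(Kg2$values - Kg$values)) / max(abs(Kg$values)), 1e-6)
})

test_that("a hand-written 3-sample lower triangle reads as a symmetric matrix", {
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "hand")
  tri <- c(1, 0.1, 1, 0.2, 0.3, 1) # (1,1),(2,1),(2,2),(3,1),(3,2),(3,3)
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(tri, con, size = 4L)
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(100, 6), con, size = 4L)
  close(con)
  writeLines(c("F1\tI1", "F2\tI2", "F3\tI3"), paste0(prefix, ".grm.id"))
  K <- read_grm_gcta(prefix)
  expected <- matrix(c(1, 0.1, 0.2,
                       0.1, 1, 0.3,
                       0.2, 0.3, 1), 3, byrow = TRUE)
  expect_equal(K$values, expected, tolerance = 1e-7)
  expect_identical(K$sample_ids, c("I1", "I2", "I3"))
})

test_that("a truncated GRM binary raises a format error", {
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "trunc")
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(c(1, 0.1, 1), con, size = 4L) # 3 of the 6 required values
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(10, 6), con, size = 4L)
  close(con)
  writeLines(c("F1\tI1", "F2\tI2", "F3\tI3"), paste0(prefix, ".grm.id"))
  expect_error(read_grm_gcta(prefix), "format error")
})
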