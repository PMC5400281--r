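test_that("the difference z-test matches the normal-CDF oracle", {
  eq <- diff_z_test(0.3, 0.05, 0.3, 0.05)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)

  dt <- diff_z_test(0.3, 0.05, 0.1, 0.05)
  expect_equal(dt$z, 0.2 / sqrt(0.005), tolerance = 1e-10) # 2.8284
  expect_equal(dt$p, 2 * pnorm(-0.2 / sqrt(0.005)), tolerance = 1e-12)
  expect_equal(dt$p, 0.00468, tolerance = 1e-3)

  sw <- diff_z_test(0.1, 0.05, 0.3, 0.05)
  expect_equal(sw$z, -dt$z)
  expect_equal(sw$p, dt$p)

  expect_error(diff_z_test(0.3, 0, 0.1, 0.05), "positive")
})

test_that("null difference p-values are uniform", {
  set.seed(60)
  p <- replicate(500, {
    se <- runif(2, 0.02, 0.08)
    diff_z_test(rnorm(1, 0.3, se[1]), se[1], rnorm(1, 0.3, se[2]), se[2])$p
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("sliding age windows enumerate inclusive 10-year ranges", {
  w <- make_age_windows()
  expect_identical(nrow(w), 25L)
  expect_identical(w$label[1], "40-49")
  expect_identical(w$label[25], "64-73")
  expect_true(all(w$hi - w$lo == 9))

  w1 <- make_age_windows(40, 73, width = 34)
  expect_identical(nrow(w1), 1L)
  expect_identical(c(w1$lo, w1$hi), c(40, 73))

  # enumeration oracle: starts 40..45 for width 5 on 40-49
  expect_identical(make_age_windows(40, 49, width = 5)$lo, 40:45)
  expect_error(make_age_windows(40, 49, width = 11), "width")
})

test_that("the weighted trend regression recovers exact linear signals", {
  x <- 44.5:68.5
  se <- runif(length(x), 0.02, 0.05)
  h2 <- 0.5 - 0.0035 * x
  tr <- trend_test(h2, se, x)
  expect_equal(tr$gamma, -0.0035, tolerance = 1e-10)
  expect_equal(tr$alpha, 0.5, tolerance = 1e-8)

  flat <- trend_test(rep(0.3, 25), se, x)
  expect_equal(flat$gamma, 0, tolerance = 1e-12)
  expect_equal(flat$p, 1)

  expect_error(trend_test(h2, se, rep(50, 25)), "singular")
  expect_error(trend_test(h2[1:2], se[1:2], x[1:2]), "at least 3")
})

test_that("trend test holds its nominal size under the null", {
  set.seed(61)
  reps <- 500
  x <- 44.5:68.5
  se <- runif(25, 0.04, 0.06)
  rejections <- mean(replicate(reps, {
    h2 <- rnorm(25, 0.3, se)
    trend_test(h2, se, x)$p < 0.05
  }))
  expect_gt(rejections, 0.03)
  expect_lt(rejections, 0.07)
})

test_that("SES windows slide over quantile ranks as expected", {
  set.seed(62)
  ses <- rnorm(900)
  w5 <- make_ses_windows(ses, window_mass = 1/3, n_windows = 5, min_n = 100)
  expect_length(w5, 5L)
  expect_true(all(vapply(w5, function(w) length(w$idx), integer(1)) == 300L))
  ord <- order(ses)
  starts <- vapply(w5, function(w) which(ord == w$idx[1]), integer(1))
  expect_identical(starts, c(1L, 151L, 301L, 451L, 601L))

  # non-overlapping limit: exact disjoint tertiles
  w3 <- make_ses_windows(ses, window_mass = 1/3, n_windows = 3, min_n = 100)
  all_idx <- sort(unlist(lapply(w3, `[[`, "idx")))
  expect_identical(all_idx, seq_len(900))
  expect_identical(length(unique(unlist(lapply(w3, `[[`, "idx")))), 900L)

  expect_error(make_ses_windows(rep(1, 900)), "degenerate")
  expect_error(make_ses_windows(ses, n_windows = 5, min_n = 500), "minimum")
})

test_that("Meff collapses duplicated traits and counts independent ones", {
  set.seed(63)
  base <- rnorm(200)
  dup <- matrix(base, 200, 10)
  expect_identical(effective_num_tests(dup), 1L)

  # exactly uncorrelated columns via principal component scores
  raw <- matrix(rnorm(200 * 100), 200)
  indep <- prcomp(raw, center = TRUE, scale. = TRUE)$x
  expect_identical(effective_num_tests(indep), 99L)
})

test_that("Meff is additive over disjoint-sample trait blocks", {
  # two rank-1 blocks on disjoint samples: eigenvalues of the patched
  # correlation matrix are (6, 4, 0, ...), so Meff = 1 + 1
  set.seed(64)
  n <- 120
  blockA <- matrix(rnorm(n), n, 6) * rep(runif(6, 0.5, 2), each = n)
  blockB <- matrix(rnorm(n), n, 4)
  pheno <- matrix(NA_real_, 2 * n, 10)
  pheno[1:n, 1:6] <- blockA
  pheno[(n + 1):(2 * n), 7:10] <- blockB
  m_all <- effective_num_tests(pheno)
  m_a <- effective_num_tests(blockA)
  m_b <- effective_num_tests(blockB)
  expect_identical(m_a, 1L)
  expect_identical(m_b, 1L)
  expect_identical(m_all, m_a + m_b)
})

test_that("p-value adjustment multiplies by Meff and caps at 1", {
  expect_equal(adjust_pvalues(0.0001, 31), 0.0031)
  expect_equal(adjust_pvalues(0.01, 400), 1)
  expect_equal(adjust_pvalues(0.2, 1), 0.2)
  expect_error(adjust_pvalues(1.2, 3), "p >= 0")
})

test_that("a stratum equal to the full sample reproduces the unstratified estimate", {
  set.seed(65)
  g <- simulate_genotypes(300, 600, maf_range = c(0.05, 0.5))
  sim <- simulate_phenotype(g, h2 = 0.5)
  K <- compute_grm(g)
  full <- estimate_h2(sim$y, K)
  strat <- estimate_h2_strata(sim$y, K, strata = list(all = K$sample_ids),
                              min_n = 100)
  expect_identical(nrow(strat), 1L)
  expect_equal(strat$h2, full$h2, tolerance = 1e-12)
  expect_equal(strat$se, full$se, tolerance = 1e-12)
})

test_that("binary traits get per-stratum prevalence and liability conversion", {
  set.seed(66)
  g <- simulate_genotypes(400, 600, maf_range = c(0.05, 0.5))
  sim <- simulate_phenotype(g, h2 = 0.5)
  yb <- simulate_binary(sim$y, 0.2)
  K <- compute_grm(g)
  halves <- list(first = K$sample_ids[1:200], second = K$sample_ids[201:400])
  strat <- estimate_h2_strata(yb, K, strata = halves, min_n = 100)
  expect_identical(strat$scale, c("liability", "liability"))
  expect_equal(strat$prevalence[1], mean(yb[1:200]), tolerance = 1e-12)
  expect_equal(strat$prevalence[2], mean(yb[201:400]), tolerance = 1e-12)

  expect_warning(
    small <- estimate_h2_strata(yb, K,
                                strata = list(tiny = K$sample_ids[1:50],
                                              rest = K$sample_ids[51:400]),
                                min_n = 100),
    "dropped")
  expect_identical(nrow(small), 1L)
})
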