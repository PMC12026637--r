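test_that("theta hits its analytic extremes", {
  fixed <- gm_from_counts(A = c(20, 0, 0), B = c(0, 0, 20))
  expect_equal(wc_theta(fixed)$theta, 1)
  # estimator bias is O(1/n), so "no differentiation" needs moderate n
  same <- gm_from_counts(A = c(100, 50, 50), B = c(100, 50, 50))
  expect_lt(abs(wc_theta(same)$theta), 0.01)
})

test_that("theta equals a direct evaluation of the component formulas", {
  g <- gm_from_counts(A = c(10, 5, 5), B = c(2, 6, 12))
  expect_equal(wc_theta(g)$theta,
               naive_theta_one_locus(list(c(10, 5, 5), c(2, 6, 12))),
               tolerance = 1e-12)
  # several random count configurations
  set.seed(42)
  for (i in 1:10) {
    c1 <- as.vector(rmultinom(1, 30, runif(3, 0.05, 1)))
    c2 <- as.vector(rmultinom(1, 50, runif(3, 0.05, 1)))
    c3 <- as.vector(rmultinom(1, 20, runif(3, 0.05, 1)))
    g <- gm_from_counts(A = c1, B = c2, C = c3)
    th <- suppressWarnings(wc_theta(g))
    if (is.finite(th$theta))
      expect_equal(th$theta, naive_theta_one_locus(list(c1, c2, c3)),
                   tolerance = 1e-10)
  }
})

test_that("theta is invariant to locus order and allele label swaps", {
  g <- generate_genotypes(study_preset(), seed = 21)
  base <- suppressWarnings(wc_theta(g))$theta
  perm <- sample(ncol(g$calls))
  g_perm <- genotype_matrix(g$calls[, perm], g$population, g$type)
  expect_equal(suppressWarnings(wc_theta(g_perm))$theta, base)
  g_swap <- genotype_matrix(2L - g$calls, g$population, g$type)
  expect_equal(suppressWarnings(wc_theta(g_swap))$theta, base)
})

test_that("pairwise theta matrix is symmetric with ~0 self-distance", {
  g <- generate_genotypes(study_preset(), seed = 22)
  pw <- suppressWarnings(pairwise_fst(g))
  expect_true(isSymmetric(pw$theta))
  expect_true(all(diag(pw$theta) == 0))
  # a population against a copy of itself
  idx <- g$population == "ITA"
  half <- which(idx)[1:116]
  pop2 <- g$population; pop2[half] <- "ITA2"
  g2 <- genotype_matrix(g$calls[pop2 %in% c("ITA", "ITA2"), ],
                        pop2[pop2 %in% c("ITA", "ITA2")])
  expect_lt(abs(suppressWarnings(wc_theta(g2))$theta), 0.02)
})

test_that("Nei G_ST spans its trivial extremes and the published global", {
  ft_same <- data.frame(population = rep(c("A", "B"), each = 2),
                        locus = rep(c("L1", "L2"), 2),
                        p_ref = c(0.3, 0.6, 0.3, 0.6), n_typed = 50L)
  expect_equal(nei_gst(ft_same, "equal")$gst, 0)
  ft_opp <- data.frame(population = rep(c("A", "B"), each = 1),
                       locus = "L1", p_ref = c(0, 1), n_typed = 50L)
  expect_equal(nei_gst(ft_opp, "equal")$gst, 1)
  # the published global differentiation (0.2143) is reproduced by the
  # sample-size-weighted form on the published frequencies
  expect_equal(nei_gst(study_frequencies(), "by_n")$gst, 0.2143,
               tolerance = 0.005 / 0.2143)
  # equal weighting, frozen from a direct H_T/H_S evaluation
  expect_equal(nei_gst(study_frequencies(), "equal")$gst, 0.2394634,
               tolerance = 1e-6)
  mono <- data.frame(population = c("A", "B"), locus = "L1",
                     p_ref = c(1, 1), n_typed = 10L)
  expect_error(nei_gst(mono), "monomorphic")
})

test_that("permutation p-values behave at the extremes and under the null", {
  fixed <- gm_from_counts(A = c(20, 0, 0), B = c(0, 0, 20))
  res <- fst_permutation_test(fixed, B = 999, seed = 1)
  expect_equal(res$p, 1 / 1000)
  # identical populations: p should be moderate, not extreme
  set.seed(99)
  ps <- replicate(51, {
    calls <- matrix(rbinom(20 * 2, 2, 0.4), 20, 2)
    g <- genotype_matrix(calls, rep(c("A", "B"), each = 10))
    fst_permutation_test(g, B = 99, seed = sample.int(1e6, 1))$p
  })
  expect_gte(median(ps), 0.3)
  expect_lte(median(ps), 0.7)
  expect_error(fst_permutation_test(fixed, B = 0), "B must be")
})

test_that("exhaustive enumeration matches an independent combn oracle", {
  calls <- matrix(c(0L, 0L, 1L, 2L, 2L, 1L,
                    0L, 1L, 0L, 2L, 1L, 2L), 6, 2)
  g <- genotype_matrix(calls, rep(c("A", "B"), each = 3))
  res <- fst_permutation_test(g, B = "exhaustive")
  theta_of <- function(labels)
    suppressWarnings(wc_theta(genotype_matrix(calls, labels))$theta)
  obs <- theta_of(g$population)
  picks <- combn(6, 3)
  stats <- apply(picks, 2, function(idx) {
    lab <- rep("B", 6); lab[idx] <- "A"; theta_of(lab)
  })
  expect_identical(res$B, 20L)
  expect_equal(res$p, mean(stats >= obs - 1e-12))
})

test_that("Holm adjustment matches hand results and is monotone", {
  expect_equal(holm_adjust(c(0.001, 0.01, 0.04)), c(0.003, 0.02, 0.04))
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_identical(holm_adjust(numeric(0)), numeric(0))
  set.seed(1)
  p <- runif(20)
  adj <- holm_adjust(p)
  expect_true(all(adj[order(p)] == cummax(adj[order(p)])))
})

test_that("allele heterogeneity chi-square matches hand contingency math", {
  # 2x2 table of allele counts 30/10 vs 10/30
  g <- gm_from_counts(A = c(15, 0, 5), B = c(5, 0, 15))
  g$type <- c(rep("river", 20), rep("swamp", 20))
  het <- allele_heterogeneity_chi2(g, by = "type")
  expect_equal(het$chi2, 20)
  expect_identical(het$df, 1L)
  expect_equal(het$p, 7.744216e-06, tolerance = 1e-4)
  # identical allele counts -> chi2 = 0, p = 1
  eq <- gm_from_counts(A = c(10, 0, 10), B = c(10, 0, 10))
  eq$type <- c(rep("river", 20), rep("swamp", 20))
  het0 <- allele_heterogeneity_chi2(eq, by = "type")
  expect_equal(het0$chi2, 0)
  expect_equal(het0$p, 1)
  # opposite fixation -> extreme heterogeneity
  opp <- gm_from_counts(A = c(30, 0, 0), B = c(0, 0, 30))
  opp$type <- c(rep("river", 30), rep("swamp", 30))
  expect_lt(allele_heterogeneity_chi2(opp, by = "type")$p, 0.001)
})

test_that("theta recovers the Balding-Nichols parameter", {
  # single moderate-size check; the full calibration lives in the
  # acceptance suite
  set.seed(7)
  g <- generate_balding_nichols(runif(30, 0.2, 0.8), fst = 0.1,
                                n_pops = 8, n_per_pop = 60, seed = 1234)
  th <- suppressWarnings(wc_theta(g))$theta
  expect_equal(th, 0.1, tolerance = 0.35)
})
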