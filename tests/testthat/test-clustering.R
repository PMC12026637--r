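test_that("genotype PCA satisfies its algebraic invariants", {
  set.seed(77)
  calls <- matrix(rbinom(60 * 8, 2, 0.4), 60, 8)
  g <- genotype_matrix(calls, rep(c("A", "B", "C"), each = 20))
  pr <- pca_genotypes(g)
  expect_equal(sum(pr$variance_explained), 1, tolerance = 1e-9)
  expect_true(all(abs(colMeans(pr$scores)) < 1e-9))
  expect_equal(crossprod(pr$loadings),
               diag(ncol(pr$loadings)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("rank-1 genotype data put all variance on PC1", {
  calls <- cbind(c(0L, 1L, 2L, 0L, 2L), c(0L, 1L, 2L, 0L, 2L))
  g <- genotype_matrix(calls, rep("A", 5))
  pr <- pca_genotypes(g)
  expect_equal(pr$variance_explained[1], 1, tolerance = 1e-12)
  mono <- genotype_matrix(matrix(1L, 4, 2), rep("A", 4))
  expect_error(pca_genotypes(mono), "monomorphic")
})

test_that("a locus carrying all between-group difference dominates PC1", {
  set.seed(13)
  n <- 80
  neutral <- matrix(rbinom(n * 4, 2, 0.5), n, 4)
  marker <- c(rbinom(n / 2, 2, 0.05), rbinom(n / 2, 2, 0.95))
  calls <- cbind(neutral, marker)
  colnames(calls) <- c(paste0("N", 1:4), "DIV")
  g <- genotype_matrix(calls, rep(c("river", "swamp"), each = n / 2),
                       type = rep(c("river", "swamp"), each = n / 2))
  pr <- pca_genotypes(g)
  expect_identical(rownames(pr$loadings)[which.max(abs(pr$loadings[, 1]))],
                   "DIV")
  expect_named(pr$group_ellipses, c("river", "swamp"))
})

test_that("missing dosages are mean-imputed, not dropped", {
  calls <- rbind(c(0L, 2L), c(2L, 0L), c(NA, 1L), c(1L, NA))
  g <- genotype_matrix(calls, rep("A", 4))
  pr <- pca_genotypes(g)
  expect_identical(nrow(pr$scores), 4L)
  expect_true(all(is.finite(pr$scores)))
})

test_that("distance-matrix PCA handles identical rows and PCoA geometry", {
  d <- rbind(c(0, 1, 5, 5), c(1, 0, 5, 5), c(5, 5, 0, 1), c(5, 5, 1, 0))
  dimnames(d) <- list(letters[1:4], letters[1:4])
  # rows a and b are identical feature vectors up to their own columns?
  # use exactly identical rows instead:
  d2 <- d; d2[1, ] <- d2[2, ]; d2[, 1] <- d2[, 2]; d2[1, 1] <- 0
  pr <- pca_distance_matrix(d2, "rows_as_features")
  expect_equal(pr$scores[1, ], pr$scores[2, ], tolerance = 1e-9)
  expect_identical(pr$mode, "rows_as_features")
  # 3 collinear points (d = 1, 2, 3) embed perfectly in 1-D under PCoA
  d3 <- rbind(c(0, 1, 3), c(1, 0, 2), c(3, 2, 0))
  dimnames(d3) <- list(c("x", "y", "z"), c("x", "y", "z"))
  pc <- pca_distance_matrix(d3, "pcoa")
  expect_equal(pc$variance_explained[1], 1, tolerance = 1e-9)
  expect_error(pca_distance_matrix(rbind(c(0, 1), c(2, 0)), "pcoa"),
               "symmetric")
})

test_that("k-means recovers structure and matches a naive reference", {
  pts <- rbind(matrix(rnorm(40, 0, 0.3), 20),
               matrix(rnorm(40, 8, 0.3), 20))
  km <- kmeans_fit(pts, 2, seed = 3)
  expect_identical(length(unique(km$assignments[1:20])), 1L)
  expect_identical(length(unique(km$assignments[21:40])), 1L)
  expect_equal(km$inertia, naive_lloyd(pts, 2, n_init = 5, seed = 99),
               tolerance = 1e-6)
  # K = n gives zero inertia
  small <- matrix(rnorm(10), 5)
  expect_equal(kmeans_fit(small, 5, seed = 1)$inertia, 0, tolerance = 1e-12)
  expect_error(kmeans_fit(small, 6), "exceed")
  # determinism under fixed seed
  expect_identical(kmeans_fit(pts, 2, seed = 3)$assignments, km$assignments)
})

test_that("silhouette matches the hand-computed two-pair value", {
  pts <- cbind(c(0, 1, 10, 11))
  cl <- c(1, 1, 2, 2)
  expect_equal(silhouette_score(pts, cl), 0.8997494, tolerance = 1e-6)
  # two clusters drawn from the same distribution score ~0; zero
  # intra-distance with clear separation scores 1
  set.seed(41)
  co <- matrix(rnorm(80), 40)
  expect_lt(abs(silhouette_score(co, rep(1:2, 20))), 0.15)
  sep <- cbind(c(0, 0, 5, 5))
  expect_equal(silhouette_score(sep, c(1, 1, 2, 2)), 1)
  expect_error(silhouette_score(pts, c(1, 1, 1, 1)), "single cluster")
  # invariant to global scaling
  set.seed(2)
  p2 <- matrix(rnorm(40), 20)
  c2 <- rep(1:2, 10)
  expect_equal(silhouette_score(p2 * 37, c2), silhouette_score(p2, c2))
})

test_that("silhouette agrees with the cluster package on random data", {
  skip_if_not_installed("cluster")
  set.seed(4)
  pts <- matrix(rnorm(60), 30)
  cl <- sample(1:3, 30, replace = TRUE)
  ref <- mean(cluster::silhouette(cl, dist(pts))[, "sil_width"])
  expect_equal(silhouette_score(pts, cl), ref, tolerance = 1e-9)
})

test_that("Davies-Bouldin matches hand values and its invariances", {
  pts <- cbind(c(0, 1, 10, 11))
  expect_equal(davies_bouldin(pts, c(1, 1, 2, 2)), 0.1, tolerance = 1e-12)
  zv <- cbind(c(0, 0, 9, 9))
  expect_equal(davies_bouldin(zv, c(1, 1, 2, 2)), 0)
  w <- capture_warnings(dbi_inf <- davies_bouldin(cbind(c(0, 1, 0, 1)),
                                                  c(1, 1, 2, 2)))
  expect_true(all(grepl("coincident", w)))
  expect_identical(dbi_inf, Inf)
  # translation invariance and non-negativity
  set.seed(6)
  p2 <- matrix(rnorm(40), 20)
  c2 <- rep(1:2, 10)
  expect_equal(davies_bouldin(p2 + 100, c2), davies_bouldin(p2, c2),
               tolerance = 1e-9)
  expect_gte(davies_bouldin(p2, c2), 0)
})

test_that("select_k recovers planted cluster counts", {
  # planted Gaussian blobs with guaranteed >= 5 sigma separation
  set.seed(8)
  ok <- 0L
  n_rep <- 20L
  for (rep in seq_len(n_rep)) {
    k_true <- sample(3:6, 1)
    ang <- 2 * pi * seq_len(k_true) / k_true
    centers <- 15 * cbind(cos(ang), sin(ang))
    pts <- do.call(rbind, lapply(seq_len(k_true), function(j)
      cbind(rnorm(12, centers[j, 1]), rnorm(12, centers[j, 2]))))
    cv <- select_k(pts, k_range = 2:7, seed = rep)
    if (cv$chosen_k == k_true) ok <- ok + 1L
  }
  expect_gte(ok / n_rep, 0.95)
  # degenerate range of length 1
  pts <- matrix(rnorm(40), 20)
  cv1 <- select_k(pts, k_range = 3, seed = 1)
  expect_identical(cv1$chosen_k, 3)
  expect_identical(nrow(cv1$table), 1L)
  # one row per K with both metrics
  cv <- select_k(pts, k_range = 2:4, seed = 1)
  expect_identical(cv$table$K, 2:4)
  expect_true(all(is.finite(cv$table$silhouette)))
  expect_true(all(is.finite(cv$table$dbi)))
})
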