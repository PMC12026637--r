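#' Seeded k-means (Lloyd's algorithm with restarts)
#'
#' Thin wrapper over [stats::kmeans()] running Lloyd's algorithm with
#' `n_init` random restarts under an explicit seed; the restart with the
#' lowest within-cluster sum of squares (inertia) is kept.
#'
#' @param points numeric matrix (points x features).
#' @param k number of clusters (`k <= nrow(points)`).
#' @param n_init random restarts.
#' @param max_iter Lloyd iterations per restart.
#' @param seed RNG seed.
#' @return list with `assignments`, `centroids`, `inertia`, `k`, `seed`.
#' @export
kmeans_fit <- function(points, k, n_init = 10, max_iter = 100, seed = 1) {
  points <- as.matrix(points)
  if (k > nrow(points))
    stop("k cannot exceed the number of points", call. = FALSE)
  km <- withr::with_seed(seed, withCallingHandlers(
    stats::kmeans(points, centers = k, nstart = n_init,
                  iter.max = max_iter, algorithm = "Lloyd"),
    # an empty cluster in one random restart is recovered by the others
    warning = function(w) {
      if (grepl("empty cluster", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  list(assignments = unname(km$cluster), centroids = km$centers,
       inertia = km$tot.withinss, k = k, seed = seed)
}

#' Mean silhouette score
#'
#' For each point, `s = (b - a) / max(a, b)` with `a` the mean Euclidean
#' distance to its own cluster (excluding itself) and `b` the smallest mean
#' distance to another cluster; points in singleton clusters score 0. The
#' mean over points is returned.
#'
#' @param points numeric matrix.
#' @param assignments integer cluster labels (>= 2 distinct).
#' @return mean silhouette in `[-1, 1]`.
#' @export
#' @examples
#' silhouette_score(cbind(c(0, 1, 10, 11)), c(1, 1, 2, 2))  # 0.8997
silhouette_score <- function(points, assignments) {
  points <- as.matrix(points)
  cl <- as.integer(factor(assignments))
  if (length(unique(cl)) < 2L)
    stop("silhouette undefined for a single cluster", call. = FALSE)
  dm <- as.matrix(stats::dist(points))
  n <- nrow(dm)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(cl == cl[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(dm[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(cl), cl[i]), function(g)
      mean(dm[i, cl == g]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Davies-Bouldin index
#'
#' With `sigma_i` the mean distance of cluster-i points to their centroid
#' and `d(c_i, c_j)` the centroid separation,
#' `DBI = mean_i max_{j != i} (sigma_i + sigma_j) / d(c_i, c_j)`.
#' Lower is better; the index is unbounded above (coincident centroids give
#' `Inf` with a warning).
#'
#' @param points numeric matrix.
#' @param assignments integer cluster labels (>= 2 non-empty clusters).
#' @return the index (>= 0).
#' @export
#' @examples
#' davies_bouldin(cbind(c(0, 1, 10, 11)), c(1, 1, 2, 2))  # 0.1
davies_bouldin <- function(points, assignments) {
  points <- as.matrix(points)
  cl <- as.integer(factor(assignments))
  ks <- sort(unique(cl))
  if (length(ks) < 2L)
    stop("need at least two non-empty clusters", call. = FALSE)
  cent <- do.call(rbind, lapply(ks, function(g)
    colMeans(points[cl == g, , drop = FALSE])))
  sig <- vapply(ks, function(g) {
    pts <- points[cl == g, , drop = FALSE]
    mean(sqrt(rowSums(sweep(pts, 2, cent[g, ])^2)))
  }, numeric(1))
  cd <- as.matrix(stats::dist(cent))
  r <- vapply(seq_along(ks), function(i) {
    max(vapply(seq_along(ks)[-i], function(j) {
      if (cd[i, j] == 0) {
        warning("coincident centroids: DBI is infinite", call. = FALSE)
        return(Inf)
      }
      (sig[i] + sig[j]) / cd[i, j]
    }, numeric(1)))
  }, numeric(1))
  mean(r)
}

#' Choose the number of clusters by silhouette and Davies-Bouldin
#'
#' Runs [kmeans_fit()] for every K in `k_range`, scores each solution with
#' the mean silhouette (higher better) and the Davies-Bouldin index (lower
#' better), and picks the K maximising the silhouette, ties broken by the
#' smaller DBI.
#'
#' @param points numeric matrix.
#' @param k_range candidate K values (within `[2, n - 1]`).
#' @param seed RNG seed (one stream per K, derived from `seed`).
#' @param n_init restarts per K.
#' @return list of class `cluster_validity`: `table` (data.frame K,
#'   silhouette, dbi), `chosen_k`, `assignments` (for the chosen K).
#' @export
select_k <- function(points, k_range = 2:7, seed = 1, n_init = 10) {
  points <- as.matrix(points)
  k_range <- k_range[k_range >= 2 & k_range <= nrow(points) - 1]
  if (!length(k_range)) stop("empty usable k_range", call. = FALSE)
  fits <- lapply(seq_along(k_range), function(i)
    kmeans_fit(points, k_range[i], n_init = n_init, seed = seed + i))
  tab <- data.frame(
    K = k_range,
    silhouette = vapply(fits, function(f)
      silhouette_score(points, f$assignments), numeric(1)),
    dbi = vapply(fits, function(f)
      davies_bouldin(points, f$assignments), numeric(1))
  )
  best <- order(-tab$silhouette, tab$dbi)[1]
  structure(list(table = tab, chosen_k = k_range[best],
                 assignments = fits[[best]]$assignments),
            class = "cluster_validity")
}

#' @export
print.cluster_validity <- function(x, ...) {
  print(x$table, digits = 3, row.names = FALSE)
  cat("chosen K:", x$chosen_k, "\n")
  invisible(x)
}
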