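#' PCA of individual genotype dosages
#'
#' Missing dosages are imputed by the per-locus mean, columns are centered
#' (optionally scaled to unit variance), and the principal components are
#' obtained from the eigendecomposition of the covariance matrix
#' (via [stats::prcomp()]). Per-group 95% ellipses are computed from the
#' group score covariance on the first two components scaled by the 2-df
#' chi-square 0.95 quantile.
#'
#' @param x a [genotype_matrix()].
#' @param scale scale columns to unit variance?
#' @param groups grouping for the ellipses: `"type"` or `"population"`.
#' @return list of class `pca_result`: `scores` (samples x PCs), `loadings`
#'   (loci x PCs, orthonormal columns), `variance_explained` (fractions
#'   summing to 1), `group_ellipses`, `mode = "genotypes"`.
#' @export
pca_genotypes <- function(x, scale = FALSE, groups = c("type", "population")) {
  groups <- match.arg(groups)
  m <- x$calls
  if (nrow(m) < 2L) stop("need at least two samples", call. = FALSE)
  mu <- colMeans(m, na.rm = TRUE)
  for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- mu[j]
  keep <- apply(m, 2, stats::var) > 0
  if (!any(keep)) stop("all loci monomorphic", call. = FALSE)
  pc <- stats::prcomp(m[, keep, drop = FALSE], center = TRUE, scale. = scale)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  gg <- if (groups == "type") x$type else x$population
  structure(list(scores = pc$x, loadings = pc$rotation,
                 variance_explained = ve,
                 group_ellipses = group_ellipses(pc$x, gg),
                 mode = "genotypes"),
            class = "pca_result")
}

#' PCA (or PCoA) of a population distance matrix
#'
#' `rows_as_features` treats each population's row of distances as its
#' feature vector and runs an ordinary PCA; `pcoa` performs classical
#' metric scaling (Torgerson) on the double-centered `-d^2/2` matrix, with
#' variance fractions taken over the positive eigenvalues.
#'
#' @param d symmetric finite distance matrix.
#' @param mode `"rows_as_features"` (default) or `"pcoa"`.
#' @return a `pca_result` (no loadings for `pcoa`).
#' @export
pca_distance_matrix <- function(d, mode = c("rows_as_features", "pcoa")) {
  mode <- match.arg(mode)
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric", call. = FALSE)
  if (mode == "rows_as_features") {
    pc <- stats::prcomp(d, center = TRUE, scale. = FALSE)
    ve <- pc$sdev^2 / sum(pc$sdev^2)
    structure(list(scores = pc$x, loadings = pc$rotation,
                   variance_explained = ve, group_ellipses = NULL,
                   mode = mode),
              class = "pca_result")
  } else {
    k <- nrow(d) - 1L
    cs <- stats::cmdscale(stats::as.dist(d), k = k, eig = TRUE)
    pos <- cs$eig[cs$eig > 1e-12]
    ncomp <- ncol(cs$points)
    ve <- cs$eig[seq_len(ncomp)] / sum(pos)
    scores <- cs$points
    colnames(scores) <- paste0("PC", seq_len(ncomp))
    structure(list(scores = scores, loadings = NULL,
                   variance_explained = ve, group_ellipses = NULL,
                   mode = mode),
              class = "pca_result")
  }
}

#' 95% ellipse parameters per group on the first two components
#'
#' @param scores samples x components score matrix.
#' @param groups group label per sample.
#' @param level coverage level of the chi-square scaling (2 df).
#' @return named list per group: `center` (length 2), `cov` (2 x 2),
#'   `scale` (chi-square quantile), `n`. Groups with < 3 samples are
#'   skipped.
#' @export
group_ellipses <- function(scores, groups, level = 0.95) {
  s2 <- scores[, 1:2, drop = FALSE]
  out <- lapply(split(seq_along(groups), groups), function(idx) {
    if (length(idx) < 3L) return(NULL)
    list(center = colMeans(s2[idx, , drop = FALSE]),
         cov = stats::cov(s2[idx, , drop = FALSE]),
         scale = stats::qchisq(level, df = 2),
         n = length(idx))
  })
  out[!vapply(out, is.null, logical(1))]
}

#' @export
print.pca_result <- function(x, ...) {
  ve <- x$variance_explained
  cat(sprintf("pca_result (%s): %d points, PC1 %.1f%%, PC2 %.1f%%\n",
              x$mode, nrow(x$scores), 100 * ve[1],
              if (length(ve) > 1) 100 * ve[2] else 0))
  invisible(x)
}
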