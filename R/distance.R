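#' Nei's standard genetic distance between two frequency vectors
#'
#' With per-locus allele frequency vectors `x` and `y` (biallelic:
#' `(p, 1 - p)`), the gene identities are `J_x = mean(sum x^2)`,
#' `J_y = mean(sum y^2)`, `J_xy = mean(sum x y)` over loci, the normalized
#' identity is `I = J_xy / sqrt(J_x J_y)` and `D = -ln I`. `I = 0`
#' (populations fixed for opposite alleles at every locus) gives `Inf`.
#'
#' @param px,py numeric vectors of reference-allele frequencies over a
#'   shared locus panel.
#' @return Nei standard distance D (non-negative, possibly `Inf`).
#' @export
#' @examples
#' nei_distance_pair(0.822, 0.868)
nei_distance_pair <- function(px, py) {
  ok <- !is.na(px) & !is.na(py)
  if (!any(ok)) return(NA_real_)
  px <- px[ok]; py <- py[ok]
  jx <- mean(px^2 + (1 - px)^2)
  jy <- mean(py^2 + (1 - py)^2)
  jxy <- mean(px * py + (1 - px) * (1 - py))
  i <- jxy / sqrt(jx * jy)
  if (i <= 0) return(Inf)
  max(0, -log(i))
}

#' Nei standard distance matrix between populations
#'
#' @param freq a frequency table covering a shared locus panel.
#' @return symmetric matrix (populations x populations) with attribute
#'   `metric = "nei_standard"`; `Inf` entries are allowed and flagged by a
#'   warning.
#' @export
nei_distance <- function(freq) {
  p <- freq_matrix(freq)
  pops <- colnames(p)
  k <- length(pops)
  d <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    d[i, j] <- d[j, i] <- nei_distance_pair(p[, i], p[, j])
  if (any(is.infinite(d)))
    warning("infinite Nei distance(s): populations fixed for opposite ",
            "alleles at every locus; see cap_distances()", call. = FALSE)
  attr(d, "metric") <- "nei_standard"
  d
}

#' Cap non-finite distances before tree building
#'
#' Replaces infinite entries by `factor` times the largest finite
#' off-diagonal entry.
#'
#' @param d symmetric distance matrix.
#' @param factor multiple of the largest finite entry used as the ceiling.
#' @return the capped matrix.
#' @export
cap_distances <- function(d, factor = 2) {
  if (!any(is.infinite(d))) return(d)
  top <- max(d[is.finite(d)])
  warning("capping ", sum(is.infinite(d)), " infinite distance(s) at ",
          factor, " x the largest finite entry", call. = FALSE)
  d[is.infinite(d)] <- factor * top
  d
}

#' Locus-bootstrap uncertainty for Nei distances
#'
#' Resamples loci with replacement and recomputes the full Nei distance
#' matrix per replicate, giving per-pair spread (the classical way to attach
#' uncertainty to a distance computed from few loci).
#'
#' @param freq frequency table.
#' @param n_boot replicates.
#' @param seed RNG seed.
#' @return list with `mean`, `sd` (matrices) and `replicates` (array
#'   k x k x n_boot).
#' @export
nei_distance_bootstrap <- function(freq, n_boot = 100, seed = 1) {
  p <- freq_matrix(freq)
  loci <- rownames(p)
  reps <- withr::with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      idx <- sample(length(loci), replace = TRUE)
      sub <- freq[freq$locus %in% loci, ]
      # rebuild a frequency table restricted to the resampled loci
      res <- do.call(rbind, lapply(seq_along(idx), function(i) {
        d <- sub[sub$locus == loci[idx[i]], ]
        d$locus <- paste0(d$locus, "_b", i)
        d
      }))
      nei_distance(res)
    })
  })
  arr <- simplify2array(reps)
  list(mean = apply(arr, c(1, 2), mean),
       sd = apply(arr, c(1, 2), stats::sd),
       replicates = arr)
}
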