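#' Weir-Cockerham theta (F_ST) with variance components
#'
#' Method-of-moments estimator of F_ST from genotype data. Per locus, with
#' `r` populations of typed sizes `n_i`, reference-allele frequencies `p_i`
#' and observed heterozygote proportions `h_i`:
#' \deqn{\bar n = \sum n_i / r,\quad
#'       n_c = (r\bar n - \sum n_i^2/(r\bar n))/(r-1),\quad
#'       \bar p = \sum n_i p_i/(r\bar n)}
#' \deqn{s^2 = \sum n_i (p_i-\bar p)^2/((r-1)\bar n),\quad
#'       \bar h = \sum n_i h_i/(r\bar n)}
#' and the components
#' \deqn{a = \frac{\bar n}{n_c}\left[s^2 - \frac{1}{\bar n - 1}
#'   \left(\bar p(1-\bar p) - \frac{r-1}{r}s^2 - \frac{\bar h}{4}\right)\right]}
#' \deqn{b = \frac{\bar n}{\bar n - 1}\left[\bar p(1-\bar p) -
#'   \frac{r-1}{r}s^2 - \frac{2\bar n - 1}{4\bar n}\bar h\right],\qquad
#'   c = \bar h / 2.}
#' The multilocus estimate is `sum(a) / sum(a + b + c)` over loci; loci
#' monomorphic across all included populations contribute nothing and are
#' excluded (with a warning).
#'
#' @param x a [genotype_matrix()].
#' @param by grouping, `"population"` or `"type"`.
#' @param populations optional subset of group labels to include.
#' @return list with `theta` (multilocus), `per_locus` (named numeric), and
#'   `components` (data.frame: locus, a, b, c, n_bar, n_c, p_bar, s2, h_bar).
#' @export
wc_theta <- function(x, by = c("population", "type"), populations = NULL) {
  by <- match.arg(by)
  grp <- if (by == "population") x$population else x$type
  if (!is.null(populations)) {
    keep <- grp %in% populations
    x <- genotype_matrix(x$calls[keep, , drop = FALSE], x$population[keep],
                         x$type[keep], x$loci)
    grp <- grp[keep]
  }
  if (length(unique(grp)) < 2L)
    stop("at least two populations required", call. = FALSE)
  comp <- do.call(rbind, lapply(colnames(x$calls), function(loc)
    wc_components_locus(x$calls[, loc], grp, loc)))
  mono <- is.na(comp$a) | (comp$a + comp$b + comp$c) == 0
  if (any(mono))
    warning(sum(mono), " locus/loci monomorphic across populations excluded",
            call. = FALSE)
  use <- comp[!mono, , drop = FALSE]
  if (!nrow(use)) stop("no polymorphic locus available", call. = FALSE)
  per_locus <- stats::setNames(use$a / (use$a + use$b + use$c), use$locus)
  list(theta = sum(use$a) / sum(use$a + use$b + use$c),
       per_locus = per_locus, components = comp)
}

# W&C (1984) biallelic variance components for one locus
wc_components_locus <- function(calls_col, grp, locus_name) {
  tabs <- lapply(split(calls_col, grp), function(v) v[!is.na(v)])
  tabs <- tabs[vapply(tabs, length, integer(1)) > 0L]
  r <- length(tabs)
  empty <- data.frame(locus = locus_name, a = NA_real_, b = NA_real_,
                      c = NA_real_, n_bar = NA_real_, n_c = NA_real_,
                      p_bar = NA_real_, s2 = NA_real_, h_bar = NA_real_,
                      stringsAsFactors = FALSE)
  if (r < 2L) return(empty)
  ni <- vapply(tabs, length, numeric(1))
  pi <- vapply(tabs, function(v) 1 - mean(v) / 2, numeric(1))
  hi <- vapply(tabs, function(v) mean(v == 1L), numeric(1))
  n_bar <- sum(ni) / r
  if (n_bar <= 1) return(empty)
  n_c <- (r * n_bar - sum(ni^2) / (r * n_bar)) / (r - 1)
  p_bar <- sum(ni * pi) / (r * n_bar)
  if (p_bar == 0 || p_bar == 1) {
    empty$a <- empty$b <- empty$c <- 0
    empty$n_bar <- n_bar; empty$n_c <- n_c; empty$p_bar <- p_bar
    empty$s2 <- 0; empty$h_bar <- 0
    return(empty)
  }
  s2 <- sum(ni * (pi - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- sum(ni * hi) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2
  data.frame(locus = locus_name, a = a, b = b, c = cc, n_bar = n_bar,
             n_c = n_c, p_bar = p_bar, s2 = s2, h_bar = h_bar,
             stringsAsFactors = FALSE)
}

#' Nei's G_ST from a frequency table
#'
#' Per locus `H_T = 2 p_bar (1 - p_bar)` from the (weighted or unweighted)
#' mean reference-allele frequency and `H_S` the matching mean of
#' `2 p_i (1 - p_i)`; the multilocus value is
#' `(sum H_T - sum H_S) / sum H_T`.
#'
#' @param freq a frequency table.
#' @param weights `"by_n"` weights populations by typed size; `"equal"`
#'   weights them equally.
#' @return list with `gst` (multilocus) and `per_locus` (named numeric; loci
#'   monomorphic overall are `NA`).
#' @export
nei_gst <- function(freq, weights = c("by_n", "equal")) {
  weights <- match.arg(weights)
  p <- freq_matrix(freq)
  n <- freq_n_matrix(freq)
  w <- if (weights == "by_n") n else (n * 0 + 1)
  w <- w / rowSums(w, na.rm = TRUE)
  p_bar <- rowSums(w * p, na.rm = TRUE)
  ht <- 2 * p_bar * (1 - p_bar)
  hs <- rowSums(w * 2 * p * (1 - p), na.rm = TRUE)
  if (sum(ht) == 0) stop("all loci monomorphic overall", call. = FALSE)
  per <- ifelse(ht > 0, (ht - hs) / ht, NA_real_)
  list(gst = (sum(ht) - sum(hs)) / sum(ht),
       per_locus = stats::setNames(per, rownames(p)))
}

#' Permutation test for Weir-Cockerham theta
#'
#' Permutes individuals among populations (holding sizes fixed) and compares
#' the permuted multilocus theta to the observed value. With
#' `B = "exhaustive"` and two populations, all distinct relabelings are
#' enumerated and the p-value is the exact proportion (identity included)
#' with `theta_perm >= theta_obs`; otherwise `p = (1 + k) / (B + 1)` over
#' `B` random permutations.
#'
#' @param x a [genotype_matrix()].
#' @param populations optional subset (e.g. a pair) of populations.
#' @param B number of permutations (`>= 1`), or `"exhaustive"`.
#' @param seed RNG seed (required for random permutations).
#' @return list with `theta_obs`, `p`, `B`.
#' @export
fst_permutation_test <- function(x, populations = NULL, B = 999, seed = 1) {
  grp <- x$population
  if (!is.null(populations)) {
    keep <- grp %in% populations
    x <- genotype_matrix(x$calls[keep, , drop = FALSE], x$population[keep],
                         x$type[keep], x$loci)
    grp <- grp[keep]
  }
  theta_of <- function(labels) {
    comp <- do.call(rbind, lapply(colnames(x$calls), function(loc)
      wc_components_locus(x$calls[, loc], labels, loc)))
    ok <- !is.na(comp$a) & (comp$a + comp$b + comp$c) != 0
    if (!any(ok)) return(NA_real_)
    sum(comp$a[ok]) / sum(comp$a[ok] + comp$b[ok] + comp$c[ok])
  }
  obs <- theta_of(grp)
  if (identical(B, "exhaustive")) {
    ug <- unique(grp)
    if (length(ug) != 2L)
      stop("exhaustive enumeration supports exactly two populations",
           call. = FALSE)
    n1 <- sum(grp == ug[1])
    picks <- utils::combn(length(grp), n1)
    stats <- apply(picks, 2, function(idx) {
      lab <- rep(ug[2], length(grp)); lab[idx] <- ug[1]
      theta_of(lab)
    })
    p <- mean(stats >= obs - 1e-12, na.rm = TRUE)
    return(list(theta_obs = obs, p = p, B = ncol(picks)))
  }
  if (!is.numeric(B) || B < 1) stop("B must be >= 1", call. = FALSE)
  k <- withr::with_seed(seed, {
    sum(vapply(seq_len(B), function(i) theta_of(sample(grp)), numeric(1)) >=
          obs - 1e-12, na.rm = TRUE)
  })
  list(theta_obs = obs, p = (1 + k) / (B + 1), B = B)
}

#' Pairwise theta matrix with permutation p-values
#'
#' Weir-Cockerham theta for every population pair (loci monomorphic within
#' a pair drop out of the sums), optional permutation p-values, and Holm
#' (sequential Bonferroni) adjusted p-values across all pairs.
#'
#' @param x a [genotype_matrix()].
#' @param B permutations per pair (0 skips the tests).
#' @param seed RNG seed.
#' @return list with matrices `theta`, `p` (raw), `p_adj` (Holm), each
#'   populations x populations (diagonal 0 / NA).
#' @export
pairwise_fst <- function(x, B = 0, seed = 1) {
  pops <- unique(x$population)
  k <- length(pops)
  th <- matrix(0, k, k, dimnames = list(pops, pops))
  pv <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  prs <- utils::combn(k, 2)
  for (m in seq_len(ncol(prs))) {
    i <- prs[1, m]; j <- prs[2, m]
    if (B > 0) {
      res <- fst_permutation_test(x, populations = c(pops[i], pops[j]),
                                  B = B, seed = seed + m)
      th[i, j] <- th[j, i] <- res$theta_obs
      pv[i, j] <- pv[j, i] <- res$p
    } else {
      th[i, j] <- th[j, i] <-
        suppressWarnings(wc_theta(x, populations = c(pops[i], pops[j]))$theta)
    }
  }
  p_adj <- pv
  if (B > 0) {
    up <- pv[upper.tri(pv)]
    adj <- holm_adjust(up)
    p_adj[upper.tri(p_adj)] <- adj
    p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
  }
  list(theta = th, p = pv, p_adj = p_adj)
}

#' Sequential Bonferroni (Holm) adjustment
#'
#' Step-down adjustment: with p-values sorted ascending, the i-th adjusted
#' value is `max_{j <= i} (m - j + 1) p_(j)`, capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the original order.
#' @export
#' @examples
#' holm_adjust(c(0.001, 0.01, 0.04))  # 0.003 0.020 0.040
holm_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "holm")
}

#' Allele-count heterogeneity chi-square across groups
#'
#' Per locus, a 2 x g contingency table of allele counts (2 alleles, g
#' groups) tested for homogeneity: `chi2 = sum (obs - exp)^2 / exp`,
#' `df = g - 1`, upper-tail p. Groups with zero typed alleles at a locus
#' are dropped with a warning.
#'
#' @param x a [genotype_matrix()].
#' @param by grouping, `"type"` (default: e.g. river/swamp/wild) or
#'   `"population"`.
#' @return data.frame with `locus`, `chi2`, `df`, `p`.
#' @export
allele_heterogeneity_chi2 <- function(x, by = c("type", "population")) {
  by <- match.arg(by)
  grp <- if (by == "type") x$type else x$population
  if (length(unique(grp)) < 2L)
    stop("at least two groups required", call. = FALSE)
  out <- do.call(rbind, lapply(colnames(x$calls), function(loc) {
    col <- x$calls[, loc]
    ref <- tapply(ifelse(is.na(col), 0, 2 - col), grp, sum)
    alt <- tapply(ifelse(is.na(col), 0, col), grp, sum)
    tot <- ref + alt
    if (any(tot == 0)) {
      warning("group(s) with zero typed alleles dropped at ", loc,
              call. = FALSE)
      ref <- ref[tot > 0]; alt <- alt[tot > 0]
    }
    g <- length(ref)
    if (g < 2L || sum(ref) == 0 || sum(alt) == 0)
      return(data.frame(locus = loc, chi2 = NA_real_, df = g - 1L,
                        p = NA_real_, stringsAsFactors = FALSE))
    obs <- rbind(ref, alt)
    expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
    chi2 <- sum((obs - expd)^2 / expd)
    data.frame(locus = loc, chi2 = chi2, df = g - 1L,
               p = stats::pchisq(chi2, df = g - 1, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
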