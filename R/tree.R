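#' Agglomerative clustering of a distance matrix
#'
#' Hierarchical agglomeration with UPGMA (size-weighted average linkage),
#' complete linkage, or Ward's method (Lance-Williams update on squared
#' dissimilarities, `hclust`'s `ward.D2`). UPGMA trees are ultrametric:
#' every leaf sits at the same distance from the root, and leaf branch
#' lengths are half the merge height.
#'
#' @param d symmetric finite distance matrix with labels.
#' @param method `"upgma"`, `"complete"` or `"ward"`.
#' @return An object of class `pop_tree`: list with `phylo` (an
#'   [ape::as.phylo()] tree), `hclust`, `method`, and `support` (`NULL`
#'   until [bootstrap_support()] fills it).
#' @export
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' to_newick(agglomerate(d, "upgma"))  # ((A:1,B:1):1,C:2);
agglomerate <- function(d, method = c("upgma", "complete", "ward")) {
  method <- match.arg(method)
  d <- as.matrix(d)
  if (any(!is.finite(d)))
    stop("non-finite distances; cap them first with cap_distances()",
         call. = FALSE)
  if (nrow(d) < 2L) stop("need at least two labels", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(d),
                      method = switch(method, upgma = "average",
                                      complete = "complete",
                                      ward = "ward.D2"))
  structure(list(phylo = ape::as.phylo(hc), hclust = hc, method = method,
                 support = NULL, consensus = NULL),
            class = "pop_tree")
}

#' @export
print.pop_tree <- function(x, ...) {
  cat(sprintf("pop_tree (%s): %d tips%s\n", x$method,
              length(x$phylo$tip.label),
              if (!is.null(x$support)) ", with bootstrap support" else ""))
  cat(" ", to_newick(x), "\n")
  invisible(x)
}

#' Locus-bootstrap support for a population tree
#'
#' Resamples loci with replacement, recomputes the Nei distance matrix and
#' the tree per replicate, and scores each internal edge of the full-data
#' tree by the percentage of replicates containing the same bipartition
#' (clade, trees being rooted). Also returns the majority-rule (> 50%)
#' consensus of the replicate trees.
#'
#' @param freq frequency table (resampling unit is the locus; needs >= 2
#'   loci).
#' @param n_boot bootstrap replicates (>= 1).
#' @param method linkage passed to [agglomerate()].
#' @param seed RNG seed.
#' @param cap_factor passed to [cap_distances()] for replicates with
#'   infinite entries.
#' @return a `pop_tree` whose `support` holds percentages per internal node
#'   (in `phylo` node order) and whose `consensus` is the majority-rule
#'   consensus `phylo`.
#' @export
bootstrap_support <- function(freq, n_boot = 1000,
                              method = c("upgma", "complete", "ward"),
                              seed = 1, cap_factor = 2) {
  method <- match.arg(method)
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  loci <- unique(freq$locus)
  if (length(loci) < 2L)
    stop("locus bootstrap needs at least two loci", call. = FALSE)
  base_d <- suppressWarnings(cap_distances(nei_distance(freq), cap_factor))
  ref <- agglomerate(base_d, method)
  boot_trees <- withr::with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      idx <- sample(length(loci), replace = TRUE)
      res <- do.call(rbind, lapply(seq_along(idx), function(i) {
        d <- freq[freq$locus == loci[idx[i]], ]
        d$locus <- paste0(d$locus, "_b", i)
        d
      }))
      dm <- suppressWarnings(cap_distances(nei_distance(res), cap_factor))
      agglomerate(dm, method)$phylo
    })
  })
  class(boot_trees) <- "multiPhylo"
  counts <- ape::prop.clades(ref$phylo, boot_trees, rooted = TRUE)
  counts[is.na(counts)] <- 0
  ref$support <- 100 * counts / n_boot
  ref$phylo$node.label <- formatC(ref$support, format = "f", digits = 0)
  cons <- ape::consensus(boot_trees, p = 0.5, rooted = TRUE)
  ref$consensus <- cons
  ref$n_boot <- n_boot
  ref
}

#' Serialize a tree to Newick
#'
#' Branch lengths come from the merge heights (UPGMA leaves sit at half the
#' merge height); bootstrap supports, when present, are written as internal
#' node labels.
#'
#' @param tree a `pop_tree` or `phylo`.
#' @param digits significant digits for branch lengths.
#' @return a Newick string ending in `;`.
#' @export
to_newick <- function(tree, digits = 10) {
  phy <- if (inherits(tree, "pop_tree")) tree$phylo else tree
  ape::write.tree(phy, digits = digits)
}

# leaves of the smallest clade containing all of `tips`
mrca_clade_tips <- function(phy, tips) {
  if (length(tips) == 1L) return(tips)
  node <- ape::getMRCA(phy, tips)
  ape::extract.clade(phy, node)$tip.label
}

#' Do some tips form a contiguous block in the tree?
#'
#' `TRUE` when the smallest clade containing `tips` contains no tip from
#' `excluding` — i.e. the two groups are not interleaved. With
#' `excluding = NULL`, checks strict monophyly (the clade holds exactly
#' `tips`).
#'
#' @param tree a `pop_tree` or `phylo`.
#' @param tips character vector of tip labels.
#' @param excluding labels that must not fall inside the group's clade.
#' @return logical.
#' @export
is_tree_group <- function(tree, tips, excluding = NULL) {
  phy <- if (inherits(tree, "pop_tree")) tree$phylo else tree
  clade <- mrca_clade_tips(phy, tips)
  if (is.null(excluding)) setequal(clade, tips)
  else !any(excluding %in% setdiff(clade, tips))
}
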