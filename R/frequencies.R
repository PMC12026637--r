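#' Per-group allele frequencies
#'
#' Reference-allele frequency per (group, locus), counting only non-missing
#' calls: `p_ref = (2 n_refref + n_het) / (2 n_typed)`. Groups with zero
#' typed calls at a locus get `p_ref = NA` (undefined).
#'
#' @param x a [genotype_matrix()].
#' @param by group samples by `"population"` (default) or `"type"`.
#' @return A frequency table (`freq_table` data.frame) with columns
#'   `population`, `locus`, `p_ref`, `n_typed`.
#' @export
allele_frequencies <- function(x, by = c("population", "type")) {
  stopifnot(inherits(x, "genotype_matrix"))
  by <- match.arg(by)
  grp <- if (by == "population") x$population else x$type
  groups <- unique(grp)
  loci <- colnames(x$calls)
  res <- do.call(rbind, lapply(groups, function(gg) {
    sub <- x$calls[grp == gg, , drop = FALSE]
    n_typed <- colSums(!is.na(sub))
    alt <- colSums(sub, na.rm = TRUE)
    p_ref <- ifelse(n_typed > 0, 1 - alt / (2 * n_typed), NA_real_)
    data.frame(population = gg, locus = loci, p_ref = p_ref,
               n_typed = as.integer(n_typed), stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  structure(res, class = c("freq_table", "data.frame"))
}

#' Pool per-population frequencies into a per-locus frequency
#'
#' @param freq a frequency table ([allele_frequencies()] or
#'   [study_frequencies()]).
#' @param weights `"by_n"` (default) weights populations by typed sample
#'   size, giving `sum(n_i p_i) / sum(n_i)` per locus; `"equal"` takes the
#'   unweighted mean of the defined frequencies.
#' @return data.frame with columns `locus`, `p_ref`, `n_typed` (total).
#' @export
pool_frequencies <- function(freq, weights = c("by_n", "equal")) {
  weights <- match.arg(weights)
  if (!nrow(freq)) stop("empty frequency table", call. = FALSE)
  sp <- split(freq, factor(freq$locus, levels = unique(freq$locus)))
  out <- do.call(rbind, lapply(sp, function(d) {
    ok <- !is.na(d$p_ref) & d$n_typed > 0
    p <- if (weights == "by_n")
      sum(d$n_typed[ok] * d$p_ref[ok]) / sum(d$n_typed[ok])
    else mean(d$p_ref[ok])
    data.frame(locus = d$locus[1], p_ref = p,
               n_typed = sum(d$n_typed[ok]), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Minor allele frequency per locus
#'
#' @param freq a frequency table.
#' @param pooled if `TRUE` (default) pool populations first (weighting by
#'   `weights`), then take `min(p, 1 - p)` per locus; otherwise return the
#'   per-(population, locus) MAF.
#' @param weights pooling weights, see [pool_frequencies()].
#' @return data.frame with columns `locus` (and `population` if
#'   `pooled = FALSE`) and `maf`.
#' @export
minor_allele_frequency <- function(freq, pooled = TRUE,
                                   weights = c("by_n", "equal")) {
  weights <- match.arg(weights)
  if (pooled) {
    pf <- pool_frequencies(freq, weights)
    data.frame(locus = pf$locus, maf = pmin(pf$p_ref, 1 - pf$p_ref),
               stringsAsFactors = FALSE)
  } else {
    data.frame(population = freq$population, locus = freq$locus,
               maf = pmin(freq$p_ref, 1 - freq$p_ref),
               stringsAsFactors = FALSE)
  }
}

# frequency table -> loci x populations matrix of p_ref
freq_matrix <- function(freq) {
  loci <- unique(freq$locus)
  pops <- unique(freq$population)
  m <- matrix(NA_real_, length(loci), length(pops),
              dimnames = list(loci, pops))
  m[cbind(match(freq$locus, loci), match(freq$population, pops))] <- freq$p_ref
  m
}

# matching matrix of typed sample sizes
freq_n_matrix <- function(freq) {
  loci <- unique(freq$locus)
  pops <- unique(freq$population)
  m <- matrix(NA_real_, length(loci), length(pops),
              dimnames = list(loci, pops))
  m[cbind(match(freq$locus, loci), match(freq$population, pops))] <- freq$n_typed
  m
}
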