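#' Construct a genotype matrix
#'
#' The central container: individuals x biallelic loci, coded as alt-allele
#' dosage (0 = ref/ref, 1 = het, 2 = alt/alt), with `NA` for missing calls.
#' Every sample carries a population label and, optionally, a broader group
#' label ("type", e.g. river/swamp/wild buffalo).
#'
#' @param calls integer matrix (samples x loci) of dosages in `{0, 1, 2, NA}`.
#'   Row names are sample ids, column names locus names (generated if absent).
#' @param population character vector of population codes, one per sample.
#' @param type optional character vector of group labels per sample
#'   (defaults to `"unknown"`).
#' @param loci optional locus definition data.frame as returned by
#'   [study_loci()]; row order must match the columns of `calls`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls`, `population`, `type`, `loci`.
#' @export
#' @examples
#' g <- genotype_matrix(rbind(c(0, 1), c(1, 2), c(0, NA)),
#'                      population = c("A", "A", "B"))
#' g
genotype_matrix <- function(calls, population, type = NULL, loci = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("S%03d", seq_len(nrow(calls)))
  if (is.null(colnames(calls)))
    colnames(calls) <- sprintf("L%02d", seq_len(ncol(calls)))
  if (length(population) != nrow(calls))
    stop("`population` must have one entry per sample", call. = FALSE)
  if (anyNA(population) || any(!nzchar(population)))
    stop("every sample must map to a declared population", call. = FALSE)
  bad <- calls[!is.na(calls) & !(calls %in% 0:2)]
  if (length(bad))
    stop("genotype codes must be 0, 1, 2 or NA", call. = FALSE)
  if (is.null(type)) type <- rep("unknown", nrow(calls))
  if (length(type) != nrow(calls))
    stop("`type` must have one entry per sample", call. = FALSE)
  if (!is.null(loci)) {
    if (nrow(loci) != ncol(calls))
      stop("`loci` must have one row per locus column", call. = FALSE)
    if (anyDuplicated(loci$name))
      stop("locus names must be unique within a panel", call. = FALSE)
    if (any(loci$ref_allele == loci$alt_allele))
      stop("ref and alt alleles must differ", call. = FALSE)
    if (any(loci$position < 1))
      stop("positions are 1-based and must be >= 1", call. = FALSE)
    colnames(calls) <- loci$name
  }
  structure(list(calls = calls,
                 population = as.character(population),
                 type = as.character(type),
                 loci = loci),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d loci, %d populations\n",
              nrow(x$calls), ncol(x$calls),
              length(unique(x$population))))
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Validate a genotype matrix
#'
#' Report-only quality checks: per-population monomorphic loci, per-locus
#' missingness, and duplicated sample ids. The input is never modified.
#'
#' @param x a [genotype_matrix()].
#' @return A list with elements `monomorphic` (data.frame population/locus),
#'   `missingness` (named numeric per locus), `duplicated_samples`
#'   (character), `n_samples`, `n_loci`.
#' @export
validate_genotypes <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  pops <- unique(x$population)
  mono <- do.call(rbind, lapply(pops, function(pp) {
    sub <- x$calls[x$population == pp, , drop = FALSE]
    is_mono <- apply(sub, 2, function(col) {
      col <- col[!is.na(col)]
      length(col) == 0L || all(col == 0L) || all(col == 2L)
    })
    if (!any(is_mono)) return(NULL)
    data.frame(population = pp, locus = colnames(sub)[is_mono],
               stringsAsFactors = FALSE)
  }))
  if (is.null(mono))
    mono <- data.frame(population = character(), locus = character(),
                       stringsAsFactors = FALSE)
  list(
    monomorphic = mono,
    missingness = colMeans(is.na(x$calls)),
    duplicated_samples =
      unique(rownames(x$calls)[duplicated(rownames(x$calls))]),
    n_samples = nrow(x$calls),
    n_loci = ncol(x$calls)
  )
}

# genotype count triple (ref/ref, het, alt/alt) for one population x locus
geno_counts <- function(calls_col) {
  c(n_rr = sum(calls_col == 0L, na.rm = TRUE),
    n_het = sum(calls_col == 1L, na.rm = TRUE),
    n_aa = sum(calls_col == 2L, na.rm = TRUE))
}
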