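#' Nei's unbiased expected heterozygosity
#'
#' Gene diversity with the small-sample correction
#' `He = (2n / (2n - 1)) * (1 - p^2 - (1 - p)^2)`, where `n` is the number
#' of typed individuals. This is the estimator that reproduces published
#' per-locus gene-diversity tables computed by FSTAT/PopGene-style software.
#'
#' @param p reference-allele frequency in `[0, 1]` (vectorised).
#' @param n typed individuals (`n >= 1`; `n = 0` gives `NA`).
#' @return He, same length as `p`.
#' @export
#' @examples
#' expected_het_unbiased(0.822, 45)  # 0.296 at 3 decimals
expected_het_unbiased <- function(p, n) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  out <- (2 * n / (2 * n - 1)) * (1 - p^2 - (1 - p)^2)
  out[n < 1] <- NA_real_
  out
}

#' Observed heterozygosity
#'
#' `Ho = n_het / n_typed` per (population, locus), with the unweighted mean
#' over loci per population.
#'
#' @param x a [genotype_matrix()].
#' @param by grouping, `"population"` or `"type"`.
#' @return list with `per_locus` (data.frame population/locus/Ho/n_typed)
#'   and `mean` (named numeric per population).
#' @export
observed_heterozygosity <- function(x, by = c("population", "type")) {
  by <- match.arg(by)
  grp <- if (by == "population") x$population else x$type
  per <- do.call(rbind, lapply(unique(grp), function(gg) {
    sub <- x$calls[grp == gg, , drop = FALSE]
    n_typed <- colSums(!is.na(sub))
    ho <- ifelse(n_typed > 0, colSums(sub == 1L, na.rm = TRUE) / n_typed,
                 NA_real_)
    data.frame(population = gg, locus = colnames(sub), Ho = ho,
               n_typed = as.integer(n_typed), stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  list(per_locus = per,
       mean = tapply(per$Ho, per$population, mean, na.rm = TRUE))
}

#' Hardy-Weinberg chi-square test from a genotype count triple
#'
#' Three-class goodness-of-fit test without continuity correction: expected
#' counts `(n p^2, 2 n p q, n q^2)` from the sample allele frequency, 1
#' degree of freedom. A monomorphic sample has no test; `chi2` and `p` are
#' `NA` (rendered "-" in formatted tables).
#'
#' @param counts integer vector `(n_refref, n_het, n_altalt)`.
#' @return list with `chi2`, `p`, `df = 1`.
#' @export
#' @examples
#' hwe_chi2_test(c(30, 40, 30))  # chi2 = 4, p = 0.0455
hwe_chi2_test <- function(counts) {
  if (length(counts) != 3L || any(counts < 0))
    stop("`counts` must be three non-negative genotype counts", call. = FALSE)
  n <- sum(counts)
  if (n < 1) stop("at least one typed individual required", call. = FALSE)
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  if (p == 0 || p == 1)
    return(list(chi2 = NA_real_, p = NA_real_, df = 1L))
  expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((counts - expd)^2 / expd)
  list(chi2 = unname(chi2),
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE), df = 1L)
}

#' Wright's fixation index from observed and expected heterozygosity
#'
#' `Fis = 1 - Ho / He` (heterozygote deficit positive, excess negative);
#' undefined (`NA`) at monomorphic loci where `He = 0`.
#'
#' @param Ho,He observed and (unbiased) expected heterozygosity (vectorised).
#' @return Fis.
#' @export
fis <- function(Ho, He) ifelse(!is.na(He) & He > 0, 1 - Ho / He, NA_real_)

#' Per-population, per-locus diversity summary
#'
#' Computes, for every (population, locus): reference-allele frequency and
#' typed sample size, Ho, unbiased He, Fis (`1 - Ho/He` by default, or the
#' Weir-Cockerham single-population small-sample f), and the Hardy-Weinberg
#' chi-square test; plus per-population unweighted means of Ho and He over
#' the locus panel (monomorphic loci counting as zero).
#'
#' @param x a [genotype_matrix()].
#' @param by grouping, `"population"` or `"type"`.
#' @param fis_mode `"ratio"` for `1 - Ho/He`, `"wc"` for the Weir-Cockerham
#'   within-population f computed from the variance components of a
#'   one-population analysis.
#' @return An object of class `diversity_summary`: list with `per_locus`
#'   (data.frame: population, locus, p_ref, n_typed, Ho, He, Fis, hwe_chi2,
#'   hwe_p) and `per_population` (data.frame: population, Ho_mean, He_mean).
#' @export
diversity_summary <- function(x, by = c("population", "type"),
                              fis_mode = c("ratio", "wc")) {
  by <- match.arg(by)
  fis_mode <- match.arg(fis_mode)
  grp <- if (by == "population") x$population else x$type
  per <- do.call(rbind, lapply(unique(grp), function(gg) {
    sub <- x$calls[grp == gg, , drop = FALSE]
    rows <- lapply(colnames(sub), function(loc) {
      cts <- geno_counts(sub[, loc])
      n <- sum(cts)
      if (n == 0)
        return(data.frame(population = gg, locus = loc, p_ref = NA_real_,
                          n_typed = 0L, Ho = NA_real_, He = NA_real_,
                          Fis = NA_real_, hwe_chi2 = NA_real_,
                          hwe_p = NA_real_, stringsAsFactors = FALSE))
      p <- (2 * cts[1] + cts[2]) / (2 * n)
      ho <- cts[2] / n
      he <- expected_het_unbiased(p, n)
      f <- if (fis_mode == "ratio") fis(ho, he) else wc_f_single(cts)
      hw <- hwe_chi2_test(cts)
      data.frame(population = gg, locus = loc, p_ref = unname(p),
                 n_typed = as.integer(n), Ho = unname(ho), He = unname(he),
                 Fis = unname(f), hwe_chi2 = hw$chi2, hwe_p = hw$p,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }))
  rownames(per) <- NULL
  means <- population_mean_heterozygosity(per)
  structure(list(per_locus = per, per_population = means),
            class = "diversity_summary")
}

# Weir-Cockerham small-sample inbreeding coefficient f for one population:
# with r = 1 the among-population component vanishes and f = 1 - c/(b + c)
# evaluated from the single-sample components.
wc_f_single <- function(counts) {
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  if (p == 0 || p == 1) return(NA_real_)
  h <- counts[2] / n
  b <- (n / (n - 1)) * (p * (1 - p) - (2 * n - 1) / (4 * n) * h)
  cc <- h / 2
  unname(1 - cc / (b + cc))
}

#' Per-population mean heterozygosity over the locus panel
#'
#' Unweighted means of Ho and He over loci, with monomorphic loci entering
#' as zero (not dropped).
#'
#' @param per_locus the `per_locus` data.frame of a [diversity_summary()]
#'   (or a compatible data.frame with `population`, `Ho`, `He`).
#' @return data.frame with `population`, `Ho_mean`, `He_mean`.
#' @export
population_mean_heterozygosity <- function(per_locus) {
  if (inherits(per_locus, "diversity_summary")) per_locus <- per_locus$per_locus
  sp <- split(per_locus, factor(per_locus$population,
                                levels = unique(per_locus$population)))
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(population = d$population[1],
               Ho_mean = mean(d$Ho, na.rm = TRUE),
               He_mean = mean(d$He, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Count Hardy-Weinberg deviations across a summary
#'
#' @param summary a [diversity_summary()].
#' @param alpha significance level in (0, 1).
#' @return list with `k` (tests with defined p below `alpha`), `m`
#'   (populations x loci, undefined tests included) and `fraction = k/m`.
#' @export
count_hwe_deviations <- function(summary, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  per <- if (inherits(summary, "diversity_summary")) summary$per_locus else summary
  k <- sum(per$hwe_p < alpha, na.rm = TRUE)
  m <- nrow(per)
  list(k = k, m = m, fraction = k / m)
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat(sprintf("diversity_summary: %d populations x %d loci\n",
              nrow(x$per_population),
              length(unique(x$per_locus$locus))))
  print(x$per_population, digits = 3)
  invisible(x)
}

#' Write publication-shaped diversity tables
#'
#' Emits two TSV files shaped like the classic frequency/HWE table (loci as
#' row blocks, populations as columns, sizes in a header row, "-" for
#' undefined chi-square tests) and the heterozygosity/Fis table.
#'
#' @param summary a [diversity_summary()].
#' @param dir output directory (created if needed).
#' @return invisible character vector of the files written.
#' @export
write_diversity_tables <- function(summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  per <- summary$per_locus
  pops <- unique(per$population)
  loci <- unique(per$locus)
  fmt <- function(v) ifelse(is.na(v), UNDEF_MARK, sprintf("%.3f", v))
  grab <- function(col, loc)
    fmt(per[[col]][match(paste(pops, loc), paste(per$population, per$locus))])
  sizes <- vapply(pops, function(pp)
    max(per$n_typed[per$population == pp]), integer(1))
  f1 <- file.path(dir, "frequencies_hwe.tsv")
  con <- file(f1, "w");
  writeLines(paste(c("locus", "row", pops), collapse = "\t"), con)
  writeLines(paste(c("", "n", sizes), collapse = "\t"), con)
  for (loc in loci) {
    writeLines(paste(c(loc, "p_ref", grab("p_ref", loc)), collapse = "\t"), con)
    writeLines(paste(c("", "chi2", grab("hwe_chi2", loc)), collapse = "\t"), con)
    writeLines(paste(c("", "P_HW", grab("hwe_p", loc)), collapse = "\t"), con)
  }
  close(con)
  f2 <- file.path(dir, "heterozygosity_fis.tsv")
  con <- file(f2, "w")
  writeLines(paste(c("row", pops), collapse = "\t"), con)
  mh <- summary$per_population
  writeLines(paste(c("Ho_mean", fmt(mh$Ho_mean[match(pops, mh$population)])),
                   collapse = "\t"), con)
  writeLines(paste(c("He_mean", fmt(mh$He_mean[match(pops, mh$population)])),
                   collapse = "\t"), con)
  for (loc in loci)
    writeLines(paste(c(paste0("He:", loc), grab("He", loc)), collapse = "\t"), con)
  for (loc in loci)
    writeLines(paste(c(paste0("Fis:", loc), grab("Fis", loc)), collapse = "\t"), con)
  close(con)
  invisible(c(f1, f2))
}
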