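#' Specification of one synthetic population
#'
#' @param code population code.
#' @param n number of individuals (>= 1).
#' @param freqs per-locus reference-allele frequencies in `[0, 1]`
#'   (named vector; names become locus names).
#' @param F_inbreeding within-population fixation index in `[0, 1]`:
#'   genotypes are drawn from `(p^2 + Fpq, 2pq(1 - F), q^2 + Fpq)`.
#' @param missing_rate per-call missing probability in `[0, 1)`.
#' @param type group label (e.g. river/swamp/wild).
#' @return list of class `population_spec`.
#' @export
population_spec <- function(code, n, freqs, F_inbreeding = 0,
                            missing_rate = 0, type = "unknown") {
  stopifnot(n >= 1, all(freqs >= 0 & freqs <= 1),
            missing_rate >= 0, missing_rate < 1)
  if (F_inbreeding < 0 || F_inbreeding > 1)
    stop("F_inbreeding must lie in [0, 1]", call. = FALSE)
  if (is.null(names(freqs)))
    names(freqs) <- sprintf("L%02d", seq_along(freqs))
  structure(list(code = code, n = as.integer(n), freqs = freqs,
                 F_inbreeding = F_inbreeding, missing_rate = missing_rate,
                 type = type),
            class = "population_spec")
}

# deterministic substream seed per (base seed, population, locus), kept
# below 2^31 so adding populations or loci never perturbs other draws
substream_seed <- function(seed, pop, locus) {
  h <- 0
  for (ch in utf8ToInt(paste(pop, locus, sep = "\r")))
    h <- (h * 131 + ch) %% 1897177291
  as.integer((h + seed * 7919) %% 2147483647L)
}

#' Generate a genotype matrix from population specs
#'
#' Per individual and locus, the genotype is drawn from the inbreeding-
#' adjusted Hardy-Weinberg proportions `(p^2 + Fpq, 2pq(1 - F), q^2 + Fpq)`
#' (so `F = 0` gives HWE and `F = 1` never produces heterozygotes), then
#' masked to missing with probability `missing_rate`. Random streams are
#' split per (population, locus): editing one spec never changes the draws
#' of another.
#'
#' @param specs list of [population_spec()] (or a single spec).
#' @param seed RNG seed.
#' @return a [genotype_matrix()].
#' @export
#' @examples
#' g <- generate_genotypes(study_preset(), seed = 42)
#' dim(g)
generate_genotypes <- function(specs, seed = 1) {
  if (inherits(specs, "population_spec")) specs <- list(specs)
  loci <- names(specs[[1]]$freqs)
  for (sp in specs)
    if (!identical(names(sp$freqs), loci))
      stop("all populations must share the locus panel", call. = FALSE)
  blocks <- lapply(specs, function(sp) {
    m <- matrix(NA_integer_, sp$n, length(loci),
                dimnames = list(paste0(sp$code, "_", seq_len(sp$n)), loci))
    for (loc in loci) {
      p <- sp$freqs[[loc]]
      q <- 1 - p
      f <- sp$F_inbreeding
      probs <- c(p^2 + f * p * q, 2 * p * q * (1 - f), q^2 + f * p * q)
      m[, loc] <- withr::with_seed(substream_seed(seed, sp$code, loc), {
        g <- sample.int(3L, sp$n, replace = TRUE, prob = probs) - 1L
        if (sp$missing_rate > 0)
          g[stats::runif(sp$n) < sp$missing_rate] <- NA_integer_
        g
      })
    }
    m
  })
  calls <- do.call(rbind, blocks)
  panel <- study_loci()
  loci_def <- if (all(loci %in% panel$name))
    panel[match(loci, panel$name), ] else NULL
  genotype_matrix(calls,
                  population = rep(vapply(specs, `[[`, "", "code"),
                                   vapply(specs, `[[`, 1L, "n")),
                  type = rep(vapply(specs, `[[`, "", "type"),
                             vapply(specs, `[[`, 1L, "n")),
                  loci = loci_def)
}

#' Balding-Nichols population allele frequencies
#'
#' Draws per-population frequencies around ancestral frequencies `p` with
#' differentiation `Fst`: `p_i ~ Beta(p (1-F)/F, (1-p)(1-F)/F)`, which has
#' mean `p` and variance `F p (1 - p)`. Ancestral frequencies of exactly 0
#' or 1 stay fixed.
#'
#' @param ancestral_freqs numeric vector of ancestral frequencies (one per
#'   locus).
#' @param fst differentiation parameter strictly in (0, 1).
#' @param n_pops number of populations.
#' @param seed RNG seed.
#' @return matrix n_pops x loci of population frequencies.
#' @export
balding_nichols_frequencies <- function(ancestral_freqs, fst, n_pops,
                                        seed = 1) {
  stopifnot(fst > 0, fst < 1, n_pops >= 1)
  withr::with_seed(seed, {
    out <- vapply(ancestral_freqs, function(p) {
      if (p <= 0 || p >= 1) return(rep(p, n_pops))
      stats::rbeta(n_pops, p * (1 - fst) / fst, (1 - p) * (1 - fst) / fst)
    }, numeric(n_pops))
    out <- matrix(out, nrow = n_pops)
    dimnames(out) <- list(sprintf("P%02d", seq_len(n_pops)),
                          if (!is.null(names(ancestral_freqs)))
                            names(ancestral_freqs)
                          else sprintf("L%02d", seq_along(ancestral_freqs)))
    out
  })
}

#' Simulate a Balding-Nichols structured dataset
#'
#' Convenience wrapper: draw population frequencies with
#' [balding_nichols_frequencies()], then HWE genotypes within each
#' population. Used to calibrate F_ST estimators against a known truth.
#'
#' @inheritParams balding_nichols_frequencies
#' @param n_per_pop individuals per population.
#' @return a [genotype_matrix()].
#' @export
generate_balding_nichols <- function(ancestral_freqs, fst, n_pops,
                                     n_per_pop, seed = 1) {
  fr <- balding_nichols_frequencies(ancestral_freqs, fst, n_pops, seed)
  specs <- lapply(rownames(fr), function(pp)
    population_spec(pp, n_per_pop, fr[pp, ]))
  generate_genotypes(specs, seed = seed + 1)
}

#' Reconstruct a genotype count triple from published summary statistics
#'
#' Inverts the (frequency, sample size, He, Fis) summary of one population
#' x locus cell into integer genotype counts: the target heterozygote count
#' is `round((1 - Fis) He n)` (ties toward fewer heterozygotes), the
#' reference-allele count is `round(2 n p)`, and parity between the two is
#' restored by moving the heterozygote count (preferring fewer
#' heterozygotes). The result is re-validated: the recomputed frequency
#' must lie within `max(0.001, 0.25/n)` of `p` and the recomputed Ho within
#' `0.015 + 1.5/n` of the target (integer rounding at small `n` makes the
#' nominal 0.001/0.015 unreachable in general).
#'
#' @param p published reference-allele frequency.
#' @param n published number of individuals.
#' @param He published unbiased expected heterozygosity.
#' @param Fis published fixation index (`Ho = (1 - Fis) He`).
#' @return integer vector `(n_refref, n_het, n_altalt)`.
#' @export
#' @examples
#' reconstruct_counts(0.822, 45, 0.296, 0.254)  # 32 10 3
reconstruct_counts <- function(p, n, He, Fis) {
  stopifnot(p >= 0, p <= 1, n >= 1)
  if (p %in% c(0, 1))
    return(stats::setNames(as.integer(c(n * p, 0, n * (1 - p))),
                           c("n_refref", "n_het", "n_altalt")))
  ho_target <- (1 - Fis) * He
  round_down_ties <- function(z) {
    fl <- floor(z)
    if (z - fl > 0.5) fl + 1 else fl  # exact .5 ties -> fewer hets
  }
  n_het <- round_down_ties(ho_target * n)
  a_ref <- round(2 * n * p)
  feasible <- function(h) {
    h >= 0 && h <= n && (a_ref - h) %% 2 == 0 &&
      (a_ref - h) / 2 >= 0 && n - (a_ref - h) / 2 - h >= 0
  }
  if (!feasible(n_het)) {
    cand <- c(n_het - 1, n_het + 1, n_het - 2, n_het + 2)
    ok <- cand[vapply(cand, feasible, logical(1))]
    if (!length(ok))
      stop("no feasible genotype triple near (p = ", p, ", n = ", n,
           ", He = ", He, ", Fis = ", Fis, "); nearest heterozygote ",
           "candidates: ", paste(cand, collapse = ", "), call. = FALSE)
    n_het <- ok[1]
  }
  n_rr <- (a_ref - n_het) / 2
  counts <- c(n_refref = n_rr, n_het = n_het, n_altalt = n - n_rr - n_het)
  p_hat <- (2 * counts[1] + counts[2]) / (2 * n)
  ho_hat <- counts[2] / n
  if (abs(p_hat - p) > max(0.001, 0.25 / n) + 1e-9 ||
      abs(ho_hat - ho_target) > 0.015 + 1.5 / n + 1e-9)
    stop("reconstructed counts (", paste(counts, collapse = ", "),
         ") fail validation: recomputed p = ", round(p_hat, 4),
         ", Ho = ", round(ho_hat, 4), call. = FALSE)
  stats::setNames(as.integer(counts), names(counts))
}
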