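#' The five-SNP dairy-trait locus panel
#'
#' Definitions of the five biallelic SNPs in milk-protein and fat-metabolism
#' genes (CSN1S1, CSN3, DGAT1, SCD, LPL) used throughout the package's
#' examples and presets. Positions are 1-based coordinates on the water
#' buffalo reference genome (UOA_WB_1).
#'
#' @return A data.frame with one row per locus and columns `name`,
#'   `chromosome`, `position`, `ref_allele`, `alt_allele`, `gene`, `region`.
#' @export
#' @examples
#' study_loci()
study_loci <- function() {
  data.frame(
    name = c("LPL_g.129635007G>A", "CSN1S1_g.32148856A>G",
             "CSN3_g.31917000A>G", "DGAT1_g.81685203G>A",
             "SCD_g.21066603C>A"),
    chromosome = c("3", "7", "7", "15", "23"),
    position = c(129635007L, 32148856L, 31917000L, 81685203L, 21066603L),
    ref_allele = c("G", "A", "A", "G", "C"),
    alt_allele = c("A", "G", "G", "A", "A"),
    gene = c("LPL", "CSN1S1", "CSN3", "DGAT1", "SCD"),
    region = c("Exon 1", "Exon 17", "Exon 4", "Exon 13", "Promoter"),
    stringsAsFactors = FALSE
  )
}

#' Published per-population reference-allele frequencies for the study panel
#'
#' Reference-allele frequencies (3 decimals) and sample sizes for the 11
#' water-buffalo populations typed at the five-SNP panel. These are the
#' published summary data the package uses as its default preset; the
#' bracketed per-population sizes sum to 917.
#'
#' @param sizes `"table"` (default) uses the per-population sizes printed
#'   with the frequency table (BGD = 45, total 917); `"methods"` uses the
#'   sampling-section counts (BGD = 46, total 918).
#' @return A frequency table: data.frame with columns `population`, `locus`,
#'   `p_ref`, `n_typed`, of class `c("freq_table", "data.frame")`, plus
#'   attributes `pop_sizes` (named integer) and `pop_types` (named character,
#'   river/swamp/wild).
#' @export
#' @examples
#' head(study_frequencies())
study_frequencies <- function(sizes = c("table", "methods")) {
  sizes <- match.arg(sizes)
  pops <- c(BGD = 45L, CHN = 149L, EGY = 19L, IDN = 56L, IRN = 132L,
            ITA = 232L, NPL = 53L, PAK = 27L, ROM = 98L, THA = 91L,
            VNM = 15L)
  if (sizes == "methods") pops["BGD"] <- 46L
  types <- c(BGD = "river", CHN = "swamp", EGY = "river", IDN = "swamp",
             IRN = "river", ITA = "river", NPL = "wild", PAK = "river",
             ROM = "river", THA = "swamp", VNM = "swamp")
  loci <- study_loci()$name
  p <- rbind(
    c(0.822, 0.225, 0.947, 0.096, 0.943, 0.567, 0.868, 0.944, 0.954, 0.423, 0.233),
    c(0.211, 0.000, 0.474, 0.000, 0.333, 0.306, 0.208, 0.222, 0.194, 0.115, 0.000),
    c(0.178, 0.000, 0.211, 0.000, 0.356, 0.422, 0.283, 0.259, 0.597, 0.324, 0.000),
    c(0.711, 0.990, 0.711, 0.991, 0.708, 0.433, 0.726, 0.667, 0.515, 0.912, 1.000),
    c(0.044, 0.000, 0.079, 0.000, 0.140, 0.246, 0.123, 0.167, 0.107, 0.033, 0.000)
  )
  dimnames(p) <- list(loci, names(pops))
  out <- data.frame(
    population = rep(names(pops), each = length(loci)),
    locus = rep(loci, times = length(pops)),
    p_ref = as.vector(p[, names(pops)]),
    n_typed = rep(unname(pops), each = length(loci)),
    stringsAsFactors = FALSE
  )
  structure(out,
            class = c("freq_table", "data.frame"),
            pop_sizes = pops, pop_types = types)
}

#' Build population specs for the synthetic generator from the study preset
#'
#' Converts the published frequency table into a list of [population_spec()]
#' objects, one per population, suitable for [generate_genotypes()]. With the
#' default arguments the generated data emulate the study design: 11
#' populations, 5 loci, 917 individuals, Hardy-Weinberg proportions within
#' populations.
#'
#' @inheritParams study_frequencies
#' @param F_inbreeding within-population fixation index used when drawing
#'   genotypes (single value recycled across populations).
#' @param missing_rate per-call missing-data probability.
#' @return A list of population specs.
#' @export
study_preset <- function(sizes = c("table", "methods"), F_inbreeding = 0,
                          missing_rate = 0) {
  ft <- study_frequencies(sizes)
  pops <- attr(ft, "pop_sizes")
  types <- attr(ft, "pop_types")
  loci <- study_loci()$name
  lapply(names(pops), function(pp) {
    f <- ft$p_ref[ft$population == pp][match(loci, ft$locus[ft$population == pp])]
    population_spec(code = pp, n = pops[[pp]],
                    freqs = stats::setNames(f, loci),
                    F_inbreeding = F_inbreeding,
                    missing_rate = missing_rate,
                    type = types[[pp]])
  })
}
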