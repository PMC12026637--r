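#' Read genotypes from TSV, GENEPOP or VCF
#'
#' @details
#' Supported dialects:
#' * **tsv** — header `sample_id<TAB>population<TAB>type<TAB><locus>...`;
#'   genotype cells are alt-allele dosages (`0`/`1`/`2`) or two-letter
#'   allele pairs (e.g. `"AG"`, requires locus definitions); missing is
#'   `NA`, `"./."` or empty. Unrecognised genotype strings become missing
#'   with a single warning giving the count.
#' * **genepop** — 4-digit allele coding, ref = `01`, alt = `02`, missing
#'   `0000`; title line, one locus name per line (or one comma-separated
#'   line), `Pop` separators. Sample ids written by [write_genotypes()] are
#'   `population:sample`; bare ids are assigned populations `POP1`, `POP2`,
#'   ... in block order.
#' * **vcf** — minimal VCF v4.2 via the vcfR package, GT field only;
#'   non-biallelic or non-SNP records are skipped with a warning. Requires
#'   `populations`, a named vector mapping sample id to population code.
#'
#' @param path file to read.
#' @param format one of `"tsv"`, `"genepop"`, `"vcf"`.
#' @param loci optional locus definitions (as [study_loci()]); needed to
#'   decode letter-pair TSV genotypes. Loci whose names match the study
#'   panel are decoded automatically.
#' @param populations named character vector sample -> population, required
#'   for VCF input.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv", "genepop", "vcf"),
                           loci = NULL, populations = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
         tsv = read_genotypes_tsv(path, loci),
         genepop = read_genotypes_genepop(path),
         vcf = read_genotypes_vcf(path, populations))
}

read_genotypes_tsv <- function(path, loci = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  need <- c("sample_id", "population", "type")
  if (ncol(tab) < 3L || !identical(names(tab)[1:3], need))
    stop("malformed TSV header at line 1: expected columns ",
         paste(need, collapse = ", "), call. = FALSE)
  locus_names <- names(tab)[-(1:3)]
  if (is.null(loci)) {
    panel <- study_loci()
    if (all(locus_names %in% panel$name))
      loci <- panel[match(locus_names, panel$name), ]
  }
  n_unknown <- 0L
  decode <- function(cell, ref, alt) {
    if (is.na(cell) || cell %in% c("NA", "", "./.")) return(NA_integer_)
    if (cell %in% c("0", "1", "2")) return(as.integer(cell))
    if (!is.na(ref) && nchar(cell) == 2L) {
      a <- substr(cell, 1, 1); b <- substr(cell, 2, 2)
      if (all(c(a, b) %in% c(ref, alt)))
        return(sum(c(a, b) == alt))
    }
    n_unknown <<- n_unknown + 1L
    NA_integer_
  }
  refs <- if (!is.null(loci)) loci$ref_allele else rep(NA_character_, length(locus_names))
  alts <- if (!is.null(loci)) loci$alt_allele else rep(NA_character_, length(locus_names))
  calls <- matrix(NA_integer_, nrow(tab), length(locus_names),
                  dimnames = list(tab$sample_id, locus_names))
  for (j in seq_along(locus_names))
    calls[, j] <- vapply(tab[[j + 3L]], decode, integer(1),
                         ref = refs[j], alt = alts[j], USE.NAMES = FALSE)
  if (n_unknown > 0L)
    warning(n_unknown, " unrecognised genotype string(s) set to missing",
            call. = FALSE)
  if (any(!nzchar(tab$population)))
    stop("validation error: sample(s) with no population: ",
         paste(tab$sample_id[!nzchar(tab$population)], collapse = ", "),
         call. = FALSE)
  genotype_matrix(calls, tab$population, tab$type, loci)
}

read_genotypes_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L)
    stop("malformed GENEPOP file: fewer than 3 lines", call. = FALSE)
  body <- lines[-1]
  pop_idx <- which(tolower(trimws(body)) == "pop")
  if (!length(pop_idx))
    stop("malformed GENEPOP file: no 'Pop' separator (line ",
         length(lines), " reached)", call. = FALSE)
  locus_lines <- body[seq_len(pop_idx[1] - 1L)]
  locus_names <- trimws(unlist(strsplit(locus_lines, ",")))
  locus_names <- locus_names[nzchar(locus_names)]
  if (!length(locus_names))
    stop("malformed GENEPOP file: no locus names before line ",
         pop_idx[1] + 1L, call. = FALSE)
  blocks <- split(seq_along(body)[-seq_len(pop_idx[1])],
                  findInterval(seq_along(body)[-seq_len(pop_idx[1])], pop_idx))
  samples <- character(); pops <- character(); rows <- list()
  n_unknown <- 0L
  block_no <- 0L
  for (blk in blocks) {
    block_no <- block_no + 1L
    for (i in blk) {
      ln <- trimws(body[i])
      if (!nzchar(ln)) next
      if (tolower(ln) == "pop") next
      parts <- strsplit(ln, ",")[[1]]
      if (length(parts) < 2L)
        stop("malformed GENEPOP individual line at file line ", i + 1L,
             call. = FALSE)
      id <- trimws(parts[1])
      if (grepl(":", id, fixed = TRUE)) {
        pp <- sub(":.*$", "", id); id <- sub("^[^:]*:", "", id)
      } else pp <- paste0("POP", block_no)
      codes <- strsplit(trimws(parts[2]), "[[:space:]]+")[[1]]
      if (length(codes) != length(locus_names))
        stop("malformed GENEPOP individual line at file line ", i + 1L,
             ": expected ", length(locus_names), " genotypes", call. = FALSE)
      dos <- vapply(codes, function(code) {
        if (nchar(code) != 4L) { n_unknown <<- n_unknown + 1L; return(NA_integer_) }
        a1 <- substr(code, 1, 2); a2 <- substr(code, 3, 4)
        if (a1 == "00" || a2 == "00") return(NA_integer_)
        if (!all(c(a1, a2) %in% c("01", "02"))) {
          n_unknown <<- n_unknown + 1L; return(NA_integer_)
        }
        sum(c(a1, a2) == "02")
      }, integer(1), USE.NAMES = FALSE)
      samples <- c(samples, id); pops <- c(pops, pp)
      rows[[length(rows) + 1L]] <- dos
    }
  }
  if (n_unknown > 0L)
    warning(n_unknown, " unrecognised genotype code(s) set to missing",
            call. = FALSE)
  calls <- do.call(rbind, rows)
  dimnames(calls) <- list(samples, locus_names)
  genotype_matrix(calls, pops)
}

read_genotypes_vcf <- function(path, populations) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF input requires the vcfR package", call. = FALSE)
  if (is.null(populations))
    stop("VCF input requires `populations`, a named sample -> population map",
         call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ok <- nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L &
    !grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(!ok))
    warning(sum(!ok), " non-biallelic-SNP record(s) skipped", call. = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")[ok, , drop = FALSE]
  dos <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) return(NA_integer_)
    sum(al == "1")
  })
  calls <- t(dos)
  locus_names <- ifelse(is.na(fix[ok, "ID"]) | fix[ok, "ID"] == ".",
                        paste0(fix[ok, "CHROM"], "_", fix[ok, "POS"]),
                        fix[ok, "ID"])
  colnames(calls) <- locus_names
  miss_pop <- setdiff(rownames(calls), names(populations))
  if (length(miss_pop))
    stop("validation error: sample(s) with no population: ",
         paste(miss_pop, collapse = ", "), call. = FALSE)
  loci <- data.frame(name = locus_names,
                     chromosome = fix[ok, "CHROM"],
                     position = as.integer(fix[ok, "POS"]),
                     ref_allele = fix[ok, "REF"],
                     alt_allele = fix[ok, "ALT"],
                     gene = NA_character_, region = NA_character_,
                     stringsAsFactors = FALSE)
  genotype_matrix(calls, unname(populations[rownames(calls)]), loci = loci)
}

#' Write genotypes to TSV or GENEPOP
#'
#' Writing then re-reading with [read_genotypes()] reproduces the genotype
#' matrix exactly (samples, populations, dosages, missingness) for both
#' formats.
#'
#' @param x a [genotype_matrix()].
#' @param path output file.
#' @param format `"tsv"` or `"genepop"`.
#' @param title title line for GENEPOP output.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(x, path, format = c("tsv", "genepop"),
                            title = "popdiff export") {
  stopifnot(inherits(x, "genotype_matrix"))
  format <- match.arg(format)
  if (format == "tsv") {
    cells <- ifelse(is.na(x$calls), "NA", as.character(x$calls))
    tab <- cbind(sample_id = rownames(x$calls), population = x$population,
                 type = x$type, cells)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(colnames(tab), collapse = "\t"), con)
    if (nrow(tab))
      writeLines(apply(tab, 1, paste, collapse = "\t"), con)
  } else {
    code_of <- c("0101", "0102", "0202")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(title, con)
    writeLines(colnames(x$calls), con)
    for (pp in unique(x$population)) {
      writeLines("Pop", con)
      idx <- which(x$population == pp)
      for (i in idx) {
        codes <- ifelse(is.na(x$calls[i, ]), "0000", code_of[x$calls[i, ] + 1L])
        writeLines(paste0(pp, ":", rownames(x$calls)[i], " , ",
                          paste(codes, collapse = " ")), con)
      }
    }
  }
  invisible(path)
}
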