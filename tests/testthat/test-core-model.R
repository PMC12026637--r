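test_that("TSV round trip is exact, including missing calls", {
  g <- generate_genotypes(study_preset(missing_rate = 0.05), seed = 11)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g, f, "tsv")
  g2 <- read_genotypes(f, "tsv")
  expect_identical(g2$calls, g$calls)
  expect_identical(g2$population, g$population)
  expect_identical(g2$type, g$type)
})

test_that("empty matrix writes a valid header-only TSV", {
  g <- genotype_matrix(matrix(integer(0), 0, 2,
                              dimnames = list(NULL, c("L1", "L2"))),
                       population = character(0))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g, f, "tsv")
  expect_identical(readLines(f),
                   "sample_id\tpopulation\ttype\tL1\tL2")
  expect_identical(dim(read_genotypes(f, "tsv")), c(0L, 2L))
})

test_that("TSV letter-pair genotypes decode against the locus panel", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste(c("sample_id", "population", "type", study_loci()$name[1:2]),
          collapse = "\t"),
    "s1\tITA\triver\tGG\tAG",
    "s2\tITA\triver\tGA\tGG",
    "s3\tEGY\triver\t./.\tAA"), f)
  g <- read_genotypes(f, "tsv")
  # LPL ref G / alt A; CSN1S1 ref A / alt G
  expect_identical(unname(g$calls[, 1]), c(0L, 1L, NA))
  expect_identical(unname(g$calls[, 2]), c(1L, 2L, 0L))
})

test_that("unknown TSV genotype strings become missing with a warning", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tpopulation\ttype\tL1",
               "s1\tA\tunknown\t0",
               "s2\tA\tunknown\t9"), f)
  expect_warning(g <- read_genotypes(f, "tsv"), "1 unrecognised")
  expect_identical(unname(g$calls[, 1]), c(0L, NA))
})

test_that("GENEPOP 4-digit codes map to dosages as hand-derived", {
  f <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("toy export", "L1", "L2", "Pop",
               "A:s1 , 0101 0102",
               "A:s2 , 0102 0202",
               "Pop",
               "B:s3 , 0202 0000"), f)
  g <- read_genotypes(f, "genepop")
  # 0101 -> 0, 0102 -> 1, 0202 -> 2, 0000 -> NA (hand-mapped)
  expect_identical(unname(g$calls),
                   rbind(c(0L, 1L), c(1L, 2L), c(2L, NA)))
  expect_identical(g$population, c("A", "A", "B"))
})

test_that("GENEPOP round trip reproduces a large synthetic matrix", {
  g <- generate_genotypes(study_preset(missing_rate = 0.02), seed = 3)
  f <- withr::local_tempfile(fileext = ".gen")
  write_genotypes(g, f, "genepop")
  g2 <- read_genotypes(f, "genepop")
  expect_identical(unname(g2$calls), unname(g$calls))
  expect_identical(colnames(g2$calls), colnames(g$calls))
  expect_identical(g2$population, g$population)
})

test_that("minimal VCF reader handles ./. and biallelic filtering", {
  skip_if_not_installed("vcfR")
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "3\t100\tsnp1\tG\tA\t.\tPASS\t.\tGT\t0/0\t0/1",
    "3\t200\tsnp2\tC\tA\t.\tPASS\t.\tGT\t./.\t1/1",
    "3\t300\tindel\tC\tCA\t.\tPASS\t.\tGT\t0/0\t0/0"), f)
  expect_warning(
    g <- read_genotypes(f, "vcf", populations = c(s1 = "A", s2 = "B")),
    "skipped")
  expect_identical(dim(g), c(2L, 2L))
  expect_identical(sum(is.na(g$calls)), 1L)
  expect_identical(unname(g$calls["s2", ]), c(1L, 2L))
})

test_that("pooling matches hand-weighted means and published pooled cells", {
  ft <- structure(data.frame(population = c("X", "Y"), locus = "L1",
                             p_ref = c(0.2, 0.8), n_typed = c(10L, 30L)),
                  class = c("freq_table", "data.frame"))
  expect_equal(pool_frequencies(ft, "by_n")$p_ref, 0.65)
  expect_equal(pool_frequencies(ft, "equal")$p_ref, 0.5)
  one <- ft[1, ]
  expect_equal(pool_frequencies(one, "by_n")$p_ref, 0.2)

  pooled <- pool_frequencies(study_frequencies(), "by_n")
  expect_equal(round(pooled$p_ref[pooled$locus == study_loci()$name[1]], 3),
               0.607)
  # pooled value always lies within the per-population range
  sf <- study_frequencies()
  for (loc in unique(sf$locus)) {
    p <- sf$p_ref[sf$locus == loc]
    expect_gte(pooled$p_ref[pooled$locus == loc], min(p))
    expect_lte(pooled$p_ref[pooled$locus == loc], max(p))
  }
  expect_error(pool_frequencies(ft[0, ]), "empty")
})

test_that("validation reports monomorphism, missingness and duplicates", {
  g <- generate_genotypes(study_preset(), seed = 5)
  rep_ <- validate_genotypes(g)
  # VNM is monomorphic at four of the five loci in the preset
  expect_identical(sum(rep_$monomorphic$population == "VNM"), 4L)
  expect_true(all(rep_$missingness == 0))
  expect_length(rep_$duplicated_samples, 0)

  calls <- rbind(c(0L, 1L), c(1L, 1L))
  rownames(calls) <- c("dup", "dup")
  g2 <- genotype_matrix(calls, population = c("A", "A"))
  expect_identical(validate_genotypes(g2)$duplicated_samples, "dup")

  # validation never mutates: frequencies identical before/after
  f1 <- allele_frequencies(g)
  invisible(validate_genotypes(g))
  expect_identical(allele_frequencies(g), f1)
})

test_that("genotype_matrix enforces its invariants", {
  expect_error(genotype_matrix(matrix(0L, 2, 1), population = "A"),
               "one entry per sample")
  expect_error(genotype_matrix(matrix(3L, 1, 1), population = "A"),
               "0, 1, 2 or NA")
  expect_error(genotype_matrix(matrix(0L, 1, 1), population = ""),
               "declared population")
  bad_loci <- study_loci()[1, ]; bad_loci$alt_allele <- bad_loci$ref_allele
  expect_error(genotype_matrix(matrix(0L, 1, 1), "A", loci = bad_loci),
               "must differ")
})
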