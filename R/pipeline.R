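#' Run the full diversity-and-differentiation pipeline
#'
#' Executes, in order: allele frequencies and Hardy-Weinberg tests,
#' per-population diversity (Ho, unbiased He, Fis), pooled MAF, pairwise
#' Weir-Cockerham theta with permutation p-values and Holm correction,
#' global theta and Nei G_ST, Nei standard distances (with locus-bootstrap
#' spread), genotype-level PCA with group ellipses, distance-matrix PCA
#' with k-means validity selection of K, agglomerative trees with bootstrap
#' support and a majority-rule consensus, and (when more than one group
#' label is present) the allele-heterogeneity chi-square by type. All
#' numeric outputs are written as TSV/JSON/Newick files under `out_dir`,
#' and a metadata JSON records seeds and estimator modes. A failing stage
#' aborts with an error naming the stage; outputs of earlier stages are
#' retained on disk.
#'
#' @param x a [genotype_matrix()].
#' @param out_dir output directory (created if needed).
#' @param B_perm permutations per population pair (0 skips the tests).
#' @param n_boot tree bootstrap replicates.
#' @param n_boot_dist locus-bootstrap replicates for distance uncertainty.
#' @param k_range candidate K values for k-means.
#' @param alpha Hardy-Weinberg significance level.
#' @param fis_mode `"ratio"` or `"wc"`, see [diversity_summary()].
#' @param gst_weights weighting for [nei_gst()].
#' @param pca_mode mode for [pca_distance_matrix()].
#' @param tree_methods linkage methods to build.
#' @param cap_factor ceiling factor for infinite distances.
#' @param seed master seed; every stochastic stage derives its own stream.
#' @return a `pipeline_bundle` list with the stage results and `files`.
#' @export
run_pipeline <- function(x, out_dir,
                         B_perm = 100, n_boot = 1000, n_boot_dist = 100,
                         k_range = 2:7, alpha = 0.05,
                         fis_mode = c("ratio", "wc"),
                         gst_weights = c("by_n", "equal"),
                         pca_mode = c("rows_as_features", "pcoa"),
                         tree_methods = c("upgma", "complete", "ward"),
                         cap_factor = 2, seed = 1) {
  stopifnot(inherits(x, "genotype_matrix"))
  fis_mode <- match.arg(fis_mode)
  gst_weights <- match.arg(gst_weights)
  pca_mode <- match.arg(pca_mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- list(files = character(0), seed = seed,
                 modes = list(fis = fis_mode, gst_weights = gst_weights,
                              pca = pca_mode))
  add_file <- function(f) bundle$files <<- c(bundle$files, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  tsv <- function(obj, name) {
    f <- file.path(out_dir, name)
    if (is.matrix(obj))
      utils::write.table(obj, f, sep = "\t", quote = FALSE, col.names = NA)
    else
      utils::write.table(obj, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    add_file(f)
    f
  }

  bundle$diversity <- stage("diversity", {
    ds <- diversity_summary(x, fis_mode = fis_mode)
    add_file(write_diversity_tables(ds, out_dir))
    ds
  })
  bundle$frequencies <- allele_frequencies(x)
  bundle$maf <- stage("maf", {
    mf <- minor_allele_frequency(bundle$frequencies)
    tsv(mf, "maf_pooled.tsv")
    mf
  })
  bundle$hwe <- count_hwe_deviations(bundle$diversity, alpha)

  bundle$fst <- stage("fst", {
    pw <- pairwise_fst(x, B = B_perm, seed = seed + 100)
    glob <- suppressWarnings(wc_theta(x))
    gst <- nei_gst(bundle$frequencies, weights = gst_weights)
    # publication-shaped table: theta below the diagonal, p above
    shaped <- pw$theta
    shaped[upper.tri(shaped)] <- pw$p_adj[upper.tri(pw$p_adj)]
    diag(shaped) <- NA
    tsv(round(shaped, 4), "pairwise_fst.tsv")
    tsv(glob$components, "fst_components.tsv")
    list(pairwise = pw, global_theta = glob, gst = gst)
  })

  bundle$distance <- stage("distance", {
    d <- suppressWarnings(cap_distances(nei_distance(bundle$frequencies),
                                        cap_factor))
    tsv(round(d, 6), "nei_distances.tsv")
    boot <- if (n_boot_dist > 0)
      nei_distance_bootstrap(bundle$frequencies, n_boot_dist,
                             seed = seed + 200) else NULL
    list(d = d, bootstrap = boot)
  })

  bundle$pca_genotypes <- stage("pca_genotypes", {
    pr <- pca_genotypes(x)
    tsv(round(pr$scores, 6), "pca_scores.tsv")
    tsv(round(pr$loadings, 6), "pca_loadings.tsv")
    tsv(data.frame(component = seq_along(pr$variance_explained),
                   fraction = pr$variance_explained), "pca_variance.tsv")
    f <- file.path(out_dir, "pca_ellipses.json")
    jsonlite::write_json(pr$group_ellipses, f, auto_unbox = TRUE,
                         digits = NA, force = TRUE)
    add_file(f)
    pr
  })

  bundle$clustering <- stage("clustering", {
    prd <- pca_distance_matrix(bundle$distance$d, mode = pca_mode)
    cv <- select_k(prd$scores, k_range = k_range, seed = seed + 300)
    tsv(cv$table, "cluster_validity.tsv")
    tsv(data.frame(population = rownames(prd$scores),
                   cluster = cv$assignments), "cluster_assignments.tsv")
    list(pca = prd, validity = cv)
  })

  bundle$trees <- stage("trees", {
    out <- lapply(tree_methods, function(m) {
      tr <- bootstrap_support(bundle$frequencies, n_boot = n_boot,
                              method = m, seed = seed + 400,
                              cap_factor = cap_factor)
      f <- file.path(out_dir, paste0("tree_", m, ".nwk"))
      writeLines(to_newick(tr), f); add_file(f)
      fc <- file.path(out_dir, paste0("tree_", m, "_consensus.nwk"))
      writeLines(to_newick(tr$consensus), fc); add_file(fc)
      tr
    })
    names(out) <- tree_methods
    out
  })

  if (length(unique(x$type)) > 1L)
    bundle$type_heterogeneity <- stage("type_heterogeneity", {
      het <- allele_heterogeneity_chi2(x, by = "type")
      tsv(het, "type_heterogeneity_chi2.tsv")
      het
    })

  meta <- list(package = "popdiff",
               version = as.character(utils::packageVersion("popdiff")),
               r_version = R.version.string,
               seed = seed,
               seeds = list(permutation = seed + 100, dist_boot = seed + 200,
                            kmeans = seed + 300, tree_boot = seed + 400),
               modes = bundle$modes,
               n_samples = nrow(x$calls), n_loci = ncol(x$calls),
               B_perm = B_perm, n_boot = n_boot, k_range = k_range,
               alpha = alpha)
  fmeta <- file.path(out_dir, "run_metadata.json")
  jsonlite::write_json(meta, fmeta, auto_unbox = TRUE, digits = NA)
  add_file(fmeta)
  class(bundle) <- "pipeline_bundle"
  bundle
}

#' One-page digest of a pipeline run
#'
#' @param bundle a `pipeline_bundle` from [run_pipeline()].
#' @return character vector of lines (also printed).
#' @export
report_summary <- function(bundle) {
  lines <- character(0)
  say <- function(...) lines <<- c(lines, sprintf(...))
  say("popdiff pipeline summary (seed %d)", bundle$seed)
  if (!is.null(bundle$fst)) {
    say("global Weir-Cockerham theta: %.4f", bundle$fst$global_theta$theta)
    say("global Nei G_ST (%s): %.4f", bundle$modes$gst_weights,
        bundle$fst$gst$gst)
    th <- bundle$fst$pairwise$theta
    off <- th[upper.tri(th)]
    prs <- which(upper.tri(th), arr.ind = TRUE)
    lo <- which.min(off); hi <- which.max(off)
    say("lowest pairwise theta: %.4f (%s-%s)", off[lo],
        rownames(th)[prs[lo, 1]], colnames(th)[prs[lo, 2]])
    say("highest pairwise theta: %.4f (%s-%s)", off[hi],
        rownames(th)[prs[hi, 1]], colnames(th)[prs[hi, 2]])
  } else say("differentiation: undefined (no polymorphic locus)")
  if (!is.null(bundle$maf) && any(is.finite(bundle$maf$maf))) {
    i <- which.min(bundle$maf$maf)
    say("lowest pooled MAF: %.3f (%s)", bundle$maf$maf[i],
        bundle$maf$locus[i])
  } else say("MAF: undefined")
  if (!is.null(bundle$hwe))
    say("HWE deviations: %d of %d tests (%.2f%%)", bundle$hwe$k,
        bundle$hwe$m, 100 * bundle$hwe$fraction)
  if (!is.null(bundle$clustering))
    say("chosen K: %d (silhouette %.3f, DBI %.3f)",
        bundle$clustering$validity$chosen_k,
        max(bundle$clustering$validity$table$silhouette),
        bundle$clustering$validity$table$dbi[
          which.max(bundle$clustering$validity$table$silhouette)])
  if (!is.null(bundle$pca_genotypes)) {
    ld <- bundle$pca_genotypes$loadings
    for (pc in seq_len(min(2, ncol(ld))))
      say("highest |loading| on PC%d: %s", pc,
          rownames(ld)[which.max(abs(ld[, pc]))])
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
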