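## Cross-species comparison of tissue expression profiles. The central
## statistic is the per-gene Spearman correlation between the focal and
## out-group tissue-proportion vectors; its significance is assessed with
## an ortholog-shuffle permutation null: re-pair focal genes with random
## out-group genes, recount how many exceed the correlation cutoff.

#' Spearman rank correlation
#'
#' Average ranks for ties; `NA` when either vector is constant (no ranking
#' is possible - e.g. a gene expressed too low in every tissue).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in `[-1, 1]`, or `NA`.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) return(NA_real_)
  suppressWarnings(stats::cor(x, y, method = "spearman"))
}

## rank rows (average ties); rows with NAs propagate NA
rank_rows <- function(m) {
  t(apply(m, 1, function(r)
    if (anyNA(r)) rep(NA_real_, length(r)) else rank(r)))
}

## gene x gene matrix of Spearman correlations between the rows of two
## proportion matrices (Pearson on row ranks == Spearman, average ties)
cross_spearman_matrix <- function(pf, po) {
  rf <- rank_rows(pf); ro <- rank_rows(po)
  suppressWarnings(stats::cor(t(rf), t(ro)))
}

#' Per-gene cross-species profile correlations
#'
#' Computes the Spearman correlation of tissue-proportion vectors for each
#' ortholog pair over the shared tissues, and flags genes with r strictly
#' greater than the cutoff (0.5) as having a correlated profile.
#'
#' @param focal,outgroup genes x tissues RPKM matrices (or
#'   [expression_matrix()] objects) with genes as rownames, tissues as
#'   colnames.
#' @param ortholog_map optional data frame with columns `focal`,
#'   `outgroup` (gene ids); defaults to matching rownames.
#' @param cutoff correlation cutoff (default 0.5, strict `>`).
#' @param transcribed_focal,transcribed_outgroup optional named logical
#'   vectors; genes must be transcribed in both species to enter.
#' @param proportions if `TRUE` (default) correlate tissue proportions,
#'   otherwise the matrices as given.
#' @return data frame with `focal`, `outgroup`, `r`, `correlated`.
#' @export
profile_correlations <- function(focal, outgroup, ortholog_map = NULL,
                                 cutoff = 0.5,
                                 transcribed_focal = NULL,
                                 transcribed_outgroup = NULL,
                                 proportions = TRUE) {
  mf <- as_rpkm_matrix(focal); mo <- as_rpkm_matrix(outgroup)
  tissues <- intersect(colnames(mf), colnames(mo))
  if (length(tissues) < 3) stop("need >= 3 shared tissues")
  if (is.null(ortholog_map)) {
    genes <- intersect(rownames(mf), rownames(mo))
    skipped <- setdiff(union(rownames(mf), rownames(mo)), genes)
    if (length(skipped))
      message(length(skipped), " gene(s) missing in one species, skipped")
    ortholog_map <- data.frame(focal = genes, outgroup = genes)
  }
  keep <- rep(TRUE, nrow(ortholog_map))
  if (!is.null(transcribed_focal))
    keep <- keep & transcribed_focal[ortholog_map$focal] %in% TRUE
  if (!is.null(transcribed_outgroup))
    keep <- keep & transcribed_outgroup[ortholog_map$outgroup] %in% TRUE
  ortholog_map <- ortholog_map[keep, , drop = FALSE]
  pf <- mf[ortholog_map$focal, tissues, drop = FALSE]
  po <- mo[ortholog_map$outgroup, tissues, drop = FALSE]
  if (proportions) {
    pf <- tissue_proportions(pf)
    po <- tissue_proportions(po)
  }
  r <- vapply(seq_len(nrow(pf)), function(i) {
    if (anyNA(pf[i, ]) || anyNA(po[i, ])) return(NA_real_)
    spearman(pf[i, ], po[i, ])
  }, numeric(1))
  data.frame(focal = ortholog_map$focal, outgroup = ortholog_map$outgroup,
             r = r, correlated = !is.na(r) & r > cutoff)
}

#' Ortholog-shuffle Monte-Carlo null
#'
#' Observed statistic: the number of ortholog pairs with profile
#' correlation strictly above `cutoff`. Each of `n_sim` simulations
#' permutes which out-group gene is paired with which focal gene
#' (uniform permutation; fixed points allowed - neglecting the ortholog
#' relationship does not forbid them) and recounts. The p-value is
#' `(1 + #\{null >= observed\}) / (1 + n_sim)`.
#'
#' @inheritParams profile_correlations
#' @param n_sim number of permutations (default 10000; < 100 warns).
#' @param seed optional integer seed.
#' @return object of class `null_result`: `observed_count`,
#'   `null_counts`, `p_value`, `n_sim`, `cutoff`, `seed`.
#' @export
ortholog_shuffle_null <- function(focal, outgroup, ortholog_map = NULL,
                                  cutoff = 0.5, n_sim = 10000, seed = NULL,
                                  proportions = TRUE) {
  if (n_sim < 100) warning("n_sim < 100: null distribution will be coarse")
  mf <- as_rpkm_matrix(focal); mo <- as_rpkm_matrix(outgroup)
  tissues <- intersect(colnames(mf), colnames(mo))
  if (length(tissues) < 3) stop("need >= 3 shared tissues")
  if (is.null(ortholog_map)) {
    genes <- intersect(rownames(mf), rownames(mo))
    ortholog_map <- data.frame(focal = genes, outgroup = genes)
  }
  n <- nrow(ortholog_map)
  if (n < 2) stop("need >= 2 genes")
  pf <- mf[ortholog_map$focal, tissues, drop = FALSE]
  po <- mo[ortholog_map$outgroup, tissues, drop = FALSE]
  if (proportions) {
    pf <- tissue_proportions(pf)
    po <- tissue_proportions(po)
  }
  ## all pairwise Spearman correlations at once; each permutation is then
  ## an indexing operation, exactly equivalent to per-pair spearman()
  C <- cross_spearman_matrix(pf, po)
  observed <- sum(diag(C) > cutoff, na.rm = TRUE)
  if (!is.null(seed)) set.seed(seed)
  null_counts <- vapply(seq_len(n_sim), function(i) {
    perm <- sample.int(n)
    sum(C[cbind(seq_len(n), perm)] > cutoff, na.rm = TRUE)
  }, numeric(1))
  p <- (1 + sum(null_counts >= observed)) / (1 + n_sim)
  structure(list(observed_count = observed, null_counts = null_counts,
                 p_value = p, n_sim = n_sim, cutoff = cutoff, seed = seed),
            class = "null_result")
}

#' @export
print.null_result <- function(x, ...) {
  cat(sprintf("<null_result> observed %d correlated pairs; p = %.4g (%d permutations)\n",
              x$observed_count, x$p_value, x$n_sim))
  invisible(x)
}

#' Hierarchical clustering of tissue-species expression columns
#'
#' Columns are `species.tissue` tissue-proportion vectors over the shared
#' gene set; complete-linkage agglomeration on Euclidean column distance
#' (or 1 - Pearson). If cross-species profiles are conserved, same-tissue
#' columns from different species cluster together.
#'
#' @param mats named list (by species) of genes x tissues proportion
#'   matrices sharing a gene set.
#' @param distance `"euclidean"` (default) or `"pearson"` (1 - r).
#' @param linkage linkage method for [stats::hclust()] (default
#'   `"complete"`).
#' @return an `hclust` object over `species.tissue` columns.
#' @export
cluster_tissues <- function(mats, distance = c("euclidean", "pearson"),
                            linkage = "complete") {
  distance <- match.arg(distance)
  if (inherits(mats, "expression_matrix") || is.matrix(mats))
    mats <- list(species = as_rpkm_matrix(mats))
  mats <- lapply(mats, as_rpkm_matrix)
  genes <- Reduce(intersect, lapply(mats, rownames))
  cols <- do.call(cbind, lapply(names(mats), function(sp) {
    m <- mats[[sp]][genes, , drop = FALSE]
    colnames(m) <- paste(sp, colnames(m), sep = ".")
    m
  }))
  if (ncol(cols) < 4) stop("need >= 4 tissue-species columns")
  cc <- stats::complete.cases(cols)
  if (!all(cc)) message(sum(!cc), " gene(s) with missing values dropped")
  cols <- cols[cc, , drop = FALSE]
  d <- if (distance == "euclidean") stats::dist(t(cols))
  else stats::as.dist(1 - suppressWarnings(stats::cor(cols)))
  stats::hclust(d, method = linkage)
}

#' Tissue-pair Spearman correlation matrix
#'
#' For every pair of tissue columns (within and across species) the
#' Spearman correlation across the shared gene set. Within-species
#' diagonal entries are 1; all-constant columns give `NA`.
#'
#' @param focal,outgroup genes x tissues matrices (proportions or RPKM)
#'   or [expression_matrix()] objects.
#' @return symmetric matrix over `species.tissue` columns.
#' @export
tissue_pair_matrix <- function(focal, outgroup) {
  mf <- as_rpkm_matrix(focal); mo <- as_rpkm_matrix(outgroup)
  genes <- intersect(rownames(mf), rownames(mo))
  if (length(genes) < 5) stop("need a shared gene set of >= 5")
  sp_f <- if (inherits(focal, "expression_matrix")) focal$species else "focal"
  sp_o <- if (inherits(outgroup, "expression_matrix")) outgroup$species
  else "outgroup"
  m <- cbind(mf[genes, , drop = FALSE], mo[genes, , drop = FALSE])
  colnames(m) <- c(paste(sp_f, colnames(mf), sep = "."),
                   paste(sp_o, colnames(mo), sep = "."))
  suppressWarnings(stats::cor(m, method = "spearman"))
}

#' ORF-expansion counter-test
#'
#' Under an ORF-expansion origin (a shorter ancestral ORF grew), genes
#' whose out-group ORF is relatively longer should be more strongly
#' correlated with the focal gene, and multi-exon genes more often
#' transcribed in the out-group. The test reports the two Spearman
#' coefficients and a one-sided Fisher exact p for the 2x2 table
#' (multi-exon vs single-exon) x (out-group transcribed vs not),
#' alternative: multi-exon genes more often transcribed.
#'
#' @param orf_length_ratio per-gene out-group/focal ORF length ratio.
#' @param relative_expression per-gene out-group/focal summed expression.
#' @param profile_r per-gene cross-species profile correlation.
#' @param exon_counts per-gene coding exon counts.
#' @param transcribed_flags per-gene logical, out-group transcribed.
#' @return list with `rho_length_vs_expression`, `rho_length_vs_profile_r`,
#'   `fisher_one_sided_p`, `degenerate` (flag for degenerate margins).
#' @export
orf_expansion_test <- function(orf_length_ratio, relative_expression,
                               profile_r, exon_counts, transcribed_flags) {
  n <- length(orf_length_ratio)
  stopifnot(n >= 5, length(relative_expression) == n,
            length(profile_r) == n, length(exon_counts) == n,
            length(transcribed_flags) == n)
  rho1 <- spearman(orf_length_ratio, relative_expression)
  rho2 <- spearman(orf_length_ratio, profile_r)
  multi <- factor(exon_counts > 1, levels = c(TRUE, FALSE))
  transcribed <- factor(transcribed_flags, levels = c(TRUE, FALSE))
  tab <- table(multi, transcribed)
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  p <- if (degenerate) 1 else
    stats::fisher.test(tab, alternative = "greater")$p.value
  list(rho_length_vs_expression = rho1, rho_length_vs_profile_r = rho2,
       fisher_one_sided_p = p, degenerate = degenerate)
}
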