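## End-to-end orchestration. A dataset bundle holds everything one run
## needs (tree, per-gene alignments, presence tables, expression matrices
## and backgrounds, junctions, optional homology/peptide/curation
## tables); run_pipeline() walks the identification funnel gene by gene,
## isolating per-gene failures with reason codes instead of aborting.

#' Default pipeline parameters
#'
#' Every threshold used in the identification and analysis, with its
#' conventional default, in one block: alignment reliability gates
#' (coverage 0.70, identity 0.50), ORF truncation threshold (0.70 of the
#' focal peptide; the `"strict"` preset uses 0.50), BLASTP E-value cutoff
#' (1e-6), transcription calling (RPKM 0.2, Monte-Carlo alpha 0.05,
#' focal-species inclusion RPKM 0.5), profile-correlation cutoff (0.5),
#' permutation count (10000), junction support minima and density-profile
#' shape.
#'
#' @param preset `"default"` or `"strict"` (truncation threshold 0.50).
#' @return named list of parameters.
#' @export
default_params <- function(preset = c("default", "strict")) {
  preset <- match.arg(preset)
  p <- list(
    min_coverage = 0.70, min_identity = 0.50,
    max_fraction_threshold = 0.70, orf_denominator = "aa",
    evalue_cutoff = 1e-6,
    rpkm_cutoff = 0.2, alpha = 0.05, focal_rpkm_filter = 0.5,
    correlation_cutoff = 0.5, n_sim = 10000,
    flank_fraction = 0.5, bins = 100, bidir_window = 1000,
    min_flank_reads = 1, min_span_reads = 1,
    seed = 1L)
  if (preset == "strict") p$max_fraction_threshold <- 0.50
  p
}

#' Simulate a complete study bundle
#'
#' Builds a ground-truthed dataset exercising every pipeline stage:
#' `n_genes` ORF histories with births split between the focal terminal
#' branch (Class I) and the focal-sister ancestral branch (Class II),
#' shared out-group disablers, two-species tissue expression with target
#' correlation `rho` and amplification `lambda`, an intergenic
#' background, and junction reads.
#'
#' @param n_genes number of genes.
#' @param tree rooted `phylo`; default a five-species primate tree.
#' @param class_fractions numeric `c(ClassI =, ClassII =)` mixing
#'   proportions (default half and half).
#' @param tissues tissue names (default the seven-tissue panel).
#' @param rho,lambda,dispersion passed to [simulate_expression()].
#' @param n_codons ORF length in codons.
#' @param seed integer seed for all sub-generators.
#' @return a dataset bundle for [run_pipeline()], with `$truth`.
#' @export
simulate_study <- function(n_genes, tree = NULL,
                           class_fractions = c(ClassI = 0.5, ClassII = 0.5),
                           tissues = c("adipose", "muscle", "cortex",
                                       "cerebellum", "heart", "liver",
                                       "testis"),
                           rho = 0.9, lambda = 2, dispersion = 0.1,
                           n_codons = 120, seed = 1L) {
  if (is.null(tree))
    tree <- ape::read.tree(
      text = "((((human,chimp),orangutan),rhesus),(mouse,dog));")
  focal <- "human"; sister <- "chimp"
  classes <- sample(rep(names(class_fractions),
                        round(n_genes * class_fractions / sum(class_fractions)))
                    [seq_len(n_genes)])
  classes[is.na(classes)] <- "ClassI"
  gene_ids <- sprintf("gene%03d", seq_len(n_genes))
  set.seed(substream_seed(seed, 41L))
  genes <- list()
  for (i in seq_len(n_genes)) {
    birth <- if (classes[i] == "ClassI") branch_id(focal) else
      branch_id(c(focal, sister))
    hist <- simulate_orf_history(tree, birth, n_codons,
                                 shared_disablers = "auto",
                                 focal = focal,
                                 seed = substream_seed(seed, 100L + i))
    locus_profile <- presence_profile(
      stats::setNames(rep("present", length(tree$tip.label)),
                      tree$tip.label), entity = "locus")
    genes[[gene_ids[i]]] <- list(history = hist,
                                 alignments = hist$alignments,
                                 locus_profile = locus_profile)
  }
  expr <- simulate_expression(n_genes, tissues, rho = rho, lambda = lambda,
                              dispersion = dispersion,
                              seed = substream_seed(seed, 42L))
  ## intergenic background: weakly covered random regions
  set.seed(substream_seed(seed, 43L))
  n_bg <- 500
  bg_regions <- data.frame(chrom = "chrU",
                           start = seq_len(n_bg) * 2000L,
                           end = seq_len(n_bg) * 2000L + 1000L)
  bg_lib <- 2e7
  bg_counts <- rpois(n_bg, 0.02 * 1 * bg_lib / 1e6)  # ~0.02 RPKM over 1 kb
  background <- intergenic_background(bg_regions, bg_counts, bg_lib,
                                      n = 2000,
                                      seed = substream_seed(seed, 44L))
  ## junctions: one per gene, canonical, simulated reads
  jt <- junction_records(chrom = gene_ids,
                         intron_start = 100L, intron_end = 200L,
                         strand = "+")
  jr <- simulate_junction_reads(jt, depth = 10, strand_error = 0.005,
                                seed = substream_seed(seed, 45L))
  list(tree = tree, focal = focal, sister = sister,
       genes = genes,
       expression = list(focal = expr$focal, outgroup = expr$outgroup),
       background = list(focal = background, outgroup = background),
       junctions = jr$junctions,
       truth = list(classes = stats::setNames(classes, gene_ids),
                    expression = expr$truth, seed = seed))
}

#' Validate a dataset bundle
#'
#' Checks structural integrity and cross-references (species against the
#' tree, gene ids across components, shared tissues). Failures are
#' enumerated, not silently dropped.
#'
#' @param dataset a bundle as produced by [simulate_study()] or
#'   [load_dataset()].
#' @return list with `errors` and `warnings` (character vectors); a run
#'   must not start when `errors` is non-empty.
#' @export
validate_dataset <- function(dataset) {
  errors <- character(0); warnings <- character(0)
  if (!inherits(dataset$tree, "phylo")) {
    errors <- c(errors, "missing or invalid species tree")
    return(list(errors = errors, warnings = warnings))
  }
  tips <- dataset$tree$tip.label
  if (!dataset$focal %in% tips)
    errors <- c(errors, paste("focal species not in tree:", dataset$focal))
  for (g in names(dataset$genes)) {
    gene <- dataset$genes[[g]]
    for (sp in names(gene$alignments)) {
      if (!sp %in% tips)
        errors <- c(errors, paste0(g, ": alignment species not in tree: ", sp))
      if (!inherits(gene$alignments[[sp]], "codon_alignment_pair"))
        errors <- c(errors, paste0(g, ": malformed alignment for ", sp))
    }
    if (!is.null(gene$locus_profile)) {
      bad <- setdiff(names(gene$locus_profile$states), tips)
      if (length(bad))
        errors <- c(errors, paste0(g, ": locus profile species not in tree: ",
                                   paste(bad, collapse = ",")))
    }
  }
  if (!is.null(dataset$expression)) {
    ef <- dataset$expression$focal; eo <- dataset$expression$outgroup
    shared <- intersect(colnames(ef$rpkm), colnames(eo$rpkm))
    dropped <- setdiff(union(colnames(ef$rpkm), colnames(eo$rpkm)), shared)
    if (length(dropped))
      warnings <- c(warnings, paste("tissue(s) present in one species only,",
                                    "dropped from shared set:",
                                    paste(dropped, collapse = ",")))
    if (length(shared) < 3)
      errors <- c(errors, "fewer than 3 shared tissues")
    miss <- setdiff(names(dataset$genes), rownames(ef$rpkm))
    if (length(miss))
      errors <- c(errors, paste("gene(s) missing from focal expression:",
                                paste(miss, collapse = ",")))
  }
  list(errors = errors, warnings = warnings)
}

#' Run the identification and comparison pipeline
#'
#' Stage order per gene: alignment reliability, disabler detection,
#' out-group ORF calls, ORF and locus dating, lineage classification,
#' paralog and peptide filters, shared-ancestral-disabler curation; then
#' study-wide: transcription calls against the intergenic background,
#' tissue proportions, per-gene profile correlations, the
#' ortholog-shuffle null, and junction support classification. A stage
#' failure reason-codes the gene and moves on.
#'
#' @param dataset a validated bundle ([simulate_study()],
#'   [load_dataset()]).
#' @param params parameter block from [default_params()].
#' @return list with `report` (per-gene data frame with every decision),
#'   `summary` (filter-funnel counts, class counts), `null`
#'   (`null_result` or `NULL`), `correlations`, `junction_status`.
#' @export
run_pipeline <- function(dataset, params = default_params()) {
  val <- validate_dataset(dataset)
  if (length(val$errors))
    stop("dataset validation failed:\n  ",
         paste(val$errors, collapse = "\n  "))
  for (w in val$warnings) message(w)
  tree <- dataset$tree
  genes <- names(dataset$genes)
  n <- length(genes)
  if (n == 0) {
    report <- data.frame(gene = character(0), orf_status = character(0),
                         class = character(0), final = logical(0))
    return(list(report = report,
                summary = list(funnel = c(input = 0L), n_final = 0L,
                               class_counts = table(factor(character(0),
                                 levels = c("ClassI", "ClassII"))),
                               null_p = NA_real_),
                null = NULL, correlations = NULL, junction_status = NULL))
  }

  rep_rows <- vector("list", n)
  for (i in seq_len(n)) {
    g <- genes[i]
    gene <- dataset$genes[[g]]
    row <- list(gene = g, reason = NA_character_)
    res <- try({
      calls <- lapply(gene$alignments, screen_outgroup,
                      min_coverage = params$min_coverage,
                      min_identity = params$min_identity,
                      max_fraction_threshold = params$max_fraction_threshold,
                      denominator = params$orf_denominator)
      states <- c(stats::setNames("present", dataset$focal),
                  vapply(calls, `[[`, character(1), "status"))
      orf_age <- assign_age(tree, presence_profile(states, "orf"))
      locus_age <- if (!is.null(gene$locus_profile))
        assign_age(tree, gene$locus_profile)
      else new_age_assignment(branch_id(tree$tip.label), "dated", 0L)
      cls <- classify_lineage(orf_age, locus_age, tree,
                              focal = dataset$focal, sister = dataset$sister)
      absent_calls <- Filter(function(cl) cl$status == "absent", calls)
      shared <- if (length(absent_calls) >= 2)
        shared_ancestral_disablers(absent_calls)
      else data.frame()
      par <- if (!is.null(gene$hits) || !is.null(gene$self_alignments))
        paralog_screen(gene$hits, gene$self_alignments,
                       evalue_cutoff = params$evalue_cutoff)
      else "pass"
      pep <- if (!is.null(gene$peptides) && !is.null(gene$translation))
        any(vapply(gene$peptides, peptide_evidence,
                   character(1), target_translation = gene$translation,
                   decoy_translations = gene$decoys %||% character(0)) ==
              "convincing")
      else NA
      curated <- gene$curation_accept %||% TRUE
      row <- list(
        gene = g,
        n_outgroups_absent = sum(vapply(calls, `[[`, character(1),
                                        "status") == "absent"),
        n_outgroups_ambiguous = sum(vapply(calls, `[[`, character(1),
                                           "status") == "ambiguous"),
        orf_status = orf_age$status,
        orf_branch = orf_age$branch,
        locus_branch = locus_age$branch,
        presence_support = orf_age$presence_support,
        class = as.character(cls),
        class_reason = attr(cls, "reason") %||% NA_character_,
        paralog = par,
        peptide_convincing = pep,
        shared_disabler = nrow(shared) > 0,
        curation_accept = isTRUE(curated),
        reason = NA_character_)
      row
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      row$reason <- paste("stage failure:",
                          trimws(attr(res, "condition")$message))
      row <- c(row, list(n_outgroups_absent = NA_integer_,
                         n_outgroups_ambiguous = NA_integer_,
                         orf_status = NA_character_, orf_branch = NA_character_,
                         locus_branch = NA_character_,
                         presence_support = NA_integer_,
                         class = NA_character_, class_reason = NA_character_,
                         paralog = NA_character_, peptide_convincing = NA,
                         shared_disabler = NA, curation_accept = NA))
      row <- row[!duplicated(names(row))]
    } else row <- res
    rep_rows[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rep_rows)

  ## expression stages
  correlations <- NULL; null <- NULL
  if (!is.null(dataset$expression) && n > 0) {
    ef <- dataset$expression$focal; eo <- dataset$expression$outgroup
    tf <- transcribed_genes(ef, dataset$background$focal, params)
    to <- transcribed_genes(eo, dataset$background$outgroup, params)
    report$transcribed_focal <- tf[report$gene]
    report$transcribed_outgroup <- to[report$gene]
    ## focal-species inclusion filter: RPKM > focal_rpkm_filter somewhere
    report$focal_expression_pass <-
      apply(ef$rpkm[report$gene, , drop = FALSE], 1,
            function(x) any(x > params$focal_rpkm_filter))
    correlations <- profile_correlations(
      ef, eo, cutoff = params$correlation_cutoff,
      transcribed_focal = tf, transcribed_outgroup = to)
    report$profile_r <- correlations$r[match(report$gene, correlations$focal)]
    report$correlated <- correlations$correlated[
      match(report$gene, correlations$focal)]
    if (nrow(correlations) >= 2)
      null <- ortholog_shuffle_null(
        ef, eo,
        ortholog_map = correlations[, c("focal", "outgroup")],
        cutoff = params$correlation_cutoff, n_sim = params$n_sim,
        seed = params$seed)
  }

  junction_status <- NULL
  if (!is.null(dataset$junctions))
    junction_status <- classify_junction(dataset$junctions,
                                         min_flank_reads = params$min_flank_reads,
                                         min_span_reads = params$min_span_reads)

  ## identification funnel (counts are of genes surviving all prior gates)
  ok <- rep(TRUE, n)
  funnel <- c(input = n)
  gate <- function(flag, name, prev, ok) {
    ok <- ok & (flag %in% TRUE)
    prev[name] <- sum(ok)
    list(funnel = prev, ok = ok)
  }
  st <- gate(report$orf_status == "dated", "dated", funnel, ok)
  st <- gate(report$class %in% c("ClassI", "ClassII"), "hominoid_class",
             st$funnel, st$ok)
  st <- gate(report$paralog == "pass", "paralog_pass", st$funnel, st$ok)
  if (!is.null(dataset$expression)) {
    st <- gate(report$focal_expression_pass, "focal_expression",
               st$funnel, st$ok)
  }
  st <- gate(report$shared_disabler, "shared_disabler", st$funnel, st$ok)
  st <- gate(report$curation_accept, "curated", st$funnel, st$ok)
  report$final <- st$ok

  summary <- list(
    funnel = st$funnel,
    class_counts = table(factor(report$class[st$ok],
                                levels = c("ClassI", "ClassII"))),
    n_final = sum(st$ok),
    null_p = if (!is.null(null)) null$p_value else NA_real_)
  list(report = report, summary = summary, null = null,
       correlations = correlations, junction_status = junction_status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## gene transcribed in >= 1 tissue; without an intergenic background the
## fixed RPKM cutoff alone is used
transcribed_genes <- function(em, background, params) {
  flags <- apply(em$rpkm, 1, function(x) {
    if (is.null(background)) any(x > params$rpkm_cutoff)
    else any(call_transcription(x, background, params$rpkm_cutoff,
                                params$alpha))
  })
  stats::setNames(flags, rownames(em$rpkm))
}

#' Load a dataset bundle from a JSON manifest
#'
#' The manifest is a JSON object with file paths: `tree` (Newick),
#' `alignments` (TSV: `gene`, `species`, `path` to gapped-FASTA pairs),
#' optional `locus_presence` (TSV: `gene`, `species`, `state`), optional
#' expression block (`counts_focal` / `counts_outgroup` TSVs with
#' `gene`, `tissue`, `count`; `library_sizes` TSV with `species`,
#' `tissue`, `size`; `region_lengths` TSV with `gene`, `length`;
#' `background_focal` / `background_outgroup` TSVs with `chrom`,
#' `start`, `end`, `count` plus `background_library_size`), optional
#' `junctions` TSV, and `focal` / `sister` species names. All referenced
#' files must exist; failures are collected into the validation error
#' list and the load refuses to return a bundle on any error.
#'
#' @param manifest path to a JSON manifest or an equivalent named list.
#' @return a dataset bundle (see [run_pipeline()]).
#' @export
load_dataset <- function(manifest) {
  m <- if (is.character(manifest)) jsonlite::read_json(manifest,
                                                       simplifyVector = TRUE)
  else manifest
  errors <- character(0)
  need <- function(path, what) {
    if (is.null(path)) return(NULL)
    if (!file.exists(path)) {
      errors <<- c(errors, paste0("missing file (", what, "): ", path))
      return(NULL)
    }
    path
  }
  tree <- NULL
  if (!is.null(need(m$tree, "tree"))) tree <- read_species_tree(m$tree)
  genes <- list()
  if (!is.null(need(m$alignments, "alignment index"))) {
    idx <- utils::read.delim(m$alignments, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(idx))) {
      p <- need(idx$path[i], paste("alignment", idx$gene[i]))
      if (is.null(p)) next
      aln <- read_alignment_pair(p)
      genes[[idx$gene[i]]]$alignments[[idx$species[i]]] <- aln
    }
  }
  if (!is.null(need(m$locus_presence, "locus presence"))) {
    lp <- read_presence_tsv(m$locus_presence, entity = "locus")
    for (g in names(lp)) {
      if (!g %in% names(genes))
        errors <- c(errors, paste("gene in presence table missing from",
                                  "alignments:", g))
      else genes[[g]]$locus_profile <- lp[[g]]
    }
  }
  expression <- NULL
  if (!is.null(m$counts_focal)) {
    expression <- tryCatch(
      load_expression_block(m, need), error = function(e) {
        errors <<- c(errors, paste("expression block:", conditionMessage(e)))
        NULL
      })
  }
  background <- NULL
  if (!is.null(m$background_focal)) {
    bgf <- utils::read.delim(m$background_focal, stringsAsFactors = FALSE)
    bgo <- if (!is.null(m$background_outgroup))
      utils::read.delim(m$background_outgroup, stringsAsFactors = FALSE)
    else bgf
    bsz <- m$background_library_size %||% 2e7
    background <- list(
      focal = intergenic_background(bgf, bgf$count, bsz,
                                    n = m$background_n %||% 10000,
                                    seed = m$seed %||% 1L),
      outgroup = intergenic_background(bgo, bgo$count, bsz,
                                       n = m$background_n %||% 10000,
                                       seed = m$seed %||% 1L))
  }
  junctions <- NULL
  if (!is.null(need(m$junctions, "junctions"))) {
    jd <- utils::read.delim(m$junctions, stringsAsFactors = FALSE)
    junctions <- junction_records(jd$chrom, jd$intron_start, jd$intron_end,
                                  jd$strand, jd$spanning_reads,
                                  jd$donor_flank_cov, jd$acceptor_flank_cov,
                                  jd$first2, jd$last2)
  }
  if (length(errors))
    stop("manifest validation failed:\n  ", paste(errors, collapse = "\n  "))
  list(tree = tree, focal = m$focal %||% "human",
       sister = m$sister %||% "chimp",
       genes = genes, expression = expression, background = background,
       junctions = junctions)
}

load_expression_block <- function(m, need) {
  read_counts <- function(path) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("gene", "tissue", "count") %in% names(d)))
    tab <- tapply(d$count, list(d$gene, d$tissue), sum, default = 0)
    as.matrix(tab)
  }
  cf <- read_counts(m$counts_focal)
  co <- read_counts(m$counts_outgroup)
  libs <- utils::read.delim(m$library_sizes, stringsAsFactors = FALSE)
  lens <- utils::read.delim(m$region_lengths, stringsAsFactors = FALSE)
  region_lengths <- stats::setNames(lens$length, lens$gene)
  mk <- function(counts, species) {
    lsz <- libs[libs$species == species, ]
    lib <- stats::setNames(lsz$size, lsz$tissue)
    rpkm <- compute_rpkm(
      counts,
      matrix(region_lengths[rownames(counts)], nrow(counts), ncol(counts)),
      matrix(lib[colnames(counts)], nrow(counts), ncol(counts), byrow = TRUE))
    expression_matrix(species, rpkm, lib, region_lengths, counts = counts)
  }
  list(focal = mk(cf, m$focal %||% "human"),
       outgroup = mk(co, m$outgroup_species %||% "rhesus"))
}
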