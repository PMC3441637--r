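## Ground-truthed synthetic data. The generators emulate the structure of
## the real study - an ORF born on one branch of a primate tree, out-group
## orthologs carrying shared ancestral disablers, and two-species
## multi-tissue expression with a tunable cross-species profile
## correlation and a focal-side amplification factor - so every
## downstream stage can be tested against known truth without any
## external download. One integer seed is threaded to all generators;
## sub-streams are derived deterministically from it.

SENSE_CODONS <- setdiff(
  apply(expand.grid(BASES, BASES, BASES), 1, paste, collapse = ""),
  STOP_CODONS)

## deterministic sub-stream seed, kept below 2^31
substream_seed <- function(seed, k) (as.integer(seed) + 1013L * k) %% 2147483647L

#' Simulate the history of an ORF on a species tree
#'
#' Generates an ancestral intact ORF (start codon, no internal stop,
#' terminal stop), gives every in-group species (leaves below
#' `birth_branch`) the intact ORF, and injects the specified disablers
#' into the out-group species at homologous codon positions - a premature
#' stop replaces the codon with the same stop triplet in every carrier
#' species (it is ancestral), a frameshift deletes the same bases.
#' Pairwise gapped alignments of the focal CDS against every out-group
#' are returned, together with the recorded truth.
#'
#' @param tree rooted `phylo` object with >= 3 leaves.
#' @param birth_branch branch id (see [tree_branches()]) on which the ORF
#'   is born.
#' @param n_codons ORF length in codons, >= 10 (including start and
#'   terminal stop).
#' @param shared_disablers `"auto"` (one shared premature stop at
#'   `floor(n_codons/3)` plus one shared 1-nt frameshift at
#'   `floor(2*n_codons/3)`, carried by every out-group), `"none"`, or a
#'   list of specs `list(species =, codon =, kind =, length =)` with kind
#'   `"premature_stop"` or `"frameshift_indel"`.
#' @param focal focal species; defaults to `"human"` when present in the
#'   in-group, else the first in-group leaf.
#' @param seed integer seed.
#' @return list with `tree`, `focal`, `ingroup`, `outgroups`,
#'   `sequences` (named ungapped character vector), `alignments` (named
#'   list of [codon_alignment_pair()] per non-focal species; in-group
#'   alignments are trivially intact) and `truth`
#'   (`birth_branch`, `disablers` data frame, `n_codons`, `seed`).
#' @export
simulate_orf_history <- function(tree, birth_branch, n_codons,
                                 shared_disablers = "auto",
                                 focal = NULL, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), length(tree$tip.label) >= 3,
            n_codons >= 10)
  if (!birth_branch %in% tree_branches(tree))
    stop("birth_branch not in tree: ", birth_branch)
  ingroup <- branch_leaves(birth_branch)
  outgroups <- setdiff(tree$tip.label, ingroup)
  if (is.null(focal))
    focal <- if ("human" %in% ingroup) "human" else ingroup[1]
  stopifnot(focal %in% ingroup)

  set.seed(substream_seed(seed, 1L))
  orf <- c("ATG", sample(SENSE_CODONS, n_codons - 2L, replace = TRUE), "TAA")
  focal_seq <- paste(orf, collapse = "")

  spec <- normalize_disabler_spec(shared_disablers, outgroups, n_codons)
  truth_dis <- do.call(rbind, lapply(spec, function(d)
    data.frame(species = d$species, focal_codon = d$codon, kind = d$kind,
               length = d$length, stringsAsFactors = FALSE)))
  if (is.null(truth_dis))
    truth_dis <- data.frame(species = character(0), focal_codon = integer(0),
                            kind = character(0), length = integer(0))

  ## per-species disabler edits; a shared stop uses one triplet for all
  set.seed(substream_seed(seed, 2L))
  stop_for <- lapply(spec, function(d)
    if (d$kind == "premature_stop") sample(STOP_CODONS, 1) else NA)

  sequences <- stats::setNames(rep(focal_seq, length(tree$tip.label)),
                               tree$tip.label)
  alignments <- list()
  for (sp in setdiff(ingroup, focal)) {
    alignments[[sp]] <- codon_alignment_pair(focal, sp, focal_seq, focal_seq)
  }
  for (sp in outgroups) {
    chars <- strsplit(focal_seq, "")[[1]]
    deleted <- rep(FALSE, length(chars))
    for (i in seq_along(spec)) {
      d <- spec[[i]]
      if (!sp %in% d$species) next
      pos <- (d$codon - 1L) * 3L + 1L
      if (d$kind == "premature_stop") {
        chars[pos:(pos + 2L)] <- strsplit(stop_for[[i]], "")[[1]]
      } else {
        deleted[pos:(pos + d$length - 1L)] <- TRUE
      }
    }
    out_gapped <- chars
    out_gapped[deleted] <- "-"
    sequences[sp] <- paste(chars[!deleted], collapse = "")
    alignments[[sp]] <- codon_alignment_pair(
      focal, sp, focal_seq, paste(out_gapped, collapse = ""))
  }
  for (sp in ingroup) sequences[sp] <- focal_seq

  list(tree = tree, focal = focal, ingroup = ingroup, outgroups = outgroups,
       sequences = sequences, alignments = alignments,
       truth = list(birth_branch = birth_branch, disablers = truth_dis,
                    n_codons = n_codons, seed = seed))
}

normalize_disabler_spec <- function(spec, outgroups, n_codons) {
  if (identical(spec, "none") || is.null(spec)) return(list())
  if (identical(spec, "auto")) {
    if (length(outgroups) == 0) return(list())
    return(list(
      list(species = outgroups, codon = max(2L, n_codons %/% 3L),
           kind = "premature_stop", length = NA_integer_),
      list(species = outgroups, codon = max(3L, (2L * n_codons) %/% 3L),
           kind = "frameshift_indel", length = 1L)))
  }
  lapply(spec, function(d) {
    stopifnot(all(d$species %in% outgroups))
    if (d$codon >= n_codons || d$codon < 1)
      stop("disabler position out of range: codon ", d$codon)
    d$length <- if (is.null(d$length)) {
      if (d$kind == "frameshift_indel") 1L else NA_integer_
    } else as.integer(d$length)
    if (d$kind == "frameshift_indel" && d$length %% 3L == 0L)
      stop("frameshift length must not be divisible by 3")
    d
  })
}

#' Simulate two-species multi-tissue expression with known truth
#'
#' Per gene, latent tissue profiles for the two species are Dirichlet
#' vectors coupled through a Gaussian copula so that their expected rank
#' correlation is approximately `rho`; the focal species' total
#' expression is `lambda` times the out-group's. Negative-binomial read
#' counts are drawn from the implied per-tissue means and converted to
#' RPKM with the stated library sizes, mirroring the real count-to-RPKM
#' path. `dispersion = 0` is the noise-free limit (counts equal their
#' expectations exactly).
#'
#' @param genes number of genes.
#' @param tissues character vector of >= 2 tissue names.
#' @param rho target cross-species profile rank correlation in `[0, 1]`.
#' @param lambda focal-over-out-group expression amplification (>= 1).
#' @param dispersion negative-binomial overdispersion (variance
#'   `mu + dispersion * mu^2`); 0 = deterministic counts.
#' @param library_sizes named per-tissue mapped-read counts (> 0),
#'   applied to both species, or `list(focal =, outgroup =)`.
#' @param region_lengths optional per-gene region lengths in bp; sampled
#'   from 500-3000 bp when missing.
#' @param concentration Dirichlet concentration of tissue profiles
#'   (default 0.8: moderately tissue-specific).
#' @param base_rpkm_meanlog,base_rpkm_sdlog log-normal parameters of the
#'   per-gene out-group total RPKM (defaults log(5) and 1).
#' @param seed integer seed.
#' @return list with `focal`, `outgroup` ([expression_matrix()] objects,
#'   species `"human"` and `"rhesus"`) and `truth` (latent proportions,
#'   totals, parameters).
#' @export
simulate_expression <- function(genes, tissues, rho, lambda,
                                dispersion = 0.1,
                                library_sizes = NULL,
                                region_lengths = NULL,
                                concentration = 0.8,
                                base_rpkm_meanlog = log(5),
                                base_rpkm_sdlog = 1,
                                seed = 1L) {
  stopifnot(length(tissues) >= 2, rho >= 0, rho <= 1, lambda >= 1,
            dispersion >= 0)
  nt <- length(tissues)
  if (is.null(library_sizes))
    library_sizes <- stats::setNames(rep(2e7, nt), tissues)
  libs <- if (is.list(library_sizes)) library_sizes else
    list(focal = library_sizes, outgroup = library_sizes)
  libs <- lapply(libs, function(l) {
    if (is.null(names(l))) names(l) <- tissues
    l
  })
  if (any(unlist(libs) <= 0)) stop("library sizes must be positive")
  gene_ids <- sprintf("gene%03d", seq_len(genes))

  set.seed(substream_seed(seed, 11L))
  if (is.null(region_lengths))
    region_lengths <- stats::setNames(
      sample(500:3000, genes, replace = TRUE), gene_ids)

  ## Gaussian copula correlation calibrated so coordinate-wise rank
  ## agreement approximates the target Spearman
  r_gauss <- if (rho >= 1) 1 else 2 * sin(pi * rho / 6)
  set.seed(substream_seed(seed, 12L))
  z_f <- matrix(rnorm(genes * nt), genes, nt)
  z_shared <- matrix(rnorm(genes * nt), genes, nt)
  z_o <- r_gauss * z_f + sqrt(1 - r_gauss^2) * z_shared
  gamma_q <- function(z) qgamma(pmin(pmax(pnorm(z), 1e-12), 1 - 1e-12),
                                shape = concentration, rate = 1)
  gf <- gamma_q(z_f); go <- gamma_q(z_o)
  prop_f <- gf / rowSums(gf)
  prop_o <- go / rowSums(go)

  set.seed(substream_seed(seed, 13L))
  total_o <- rlnorm(genes, base_rpkm_meanlog, base_rpkm_sdlog)
  total_f <- lambda * total_o

  draw <- function(props, totals, lib) {
    mu_rpkm <- props * totals
    mu_counts <- sweep(mu_rpkm, 1, region_lengths[gene_ids] / 1000, "*")
    mu_counts <- sweep(mu_counts, 2, lib[tissues] / 1e6, "*")
    counts <- if (dispersion == 0) mu_counts else
      matrix(rnbinom(length(mu_counts), mu = mu_counts,
                     size = 1 / dispersion),
             nrow(mu_counts), ncol(mu_counts))
    dimnames(counts) <- list(gene_ids, tissues)
    rpkm <- compute_rpkm(counts,
                         matrix(region_lengths[gene_ids], genes, nt),
                         matrix(lib[tissues], genes, nt, byrow = TRUE))
    list(counts = counts, rpkm = rpkm)
  }
  set.seed(substream_seed(seed, 14L))
  df <- draw(prop_f, total_f, libs$focal)
  set.seed(substream_seed(seed, 15L))
  do_ <- draw(prop_o, total_o, libs$outgroup)

  dimnames(prop_f) <- dimnames(prop_o) <- list(gene_ids, tissues)
  list(
    focal = expression_matrix("human", df$rpkm, libs$focal,
                              region_lengths, counts = df$counts),
    outgroup = expression_matrix("rhesus", do_$rpkm, libs$outgroup,
                                 region_lengths, counts = do_$counts),
    truth = list(rho = rho, lambda = lambda, dispersion = dispersion,
                 proportions_focal = prop_f, proportions_outgroup = prop_o,
                 total_rpkm_focal = stats::setNames(total_f, gene_ids),
                 total_rpkm_outgroup = stats::setNames(total_o, gene_ids),
                 seed = seed))
}

#' Simulate junction-spanning reads and flank coverage
#'
#' Each template junction receives `Poisson(depth)` spanning reads whose
#' strand labels are flipped independently with probability
#' `strand_error`; exonic flank read counts are Poisson with the same
#' mean.
#'
#' @param junctions junction template table ([junction_records()]);
#'   `spanning_reads` and flank columns are overwritten.
#' @param depth mean read depth (> 0).
#' @param strand_error per-read strand mislabeling rate in `[0, 1)`.
#' @param seed integer seed.
#' @return list with `junctions` (table with `spanning_reads`,
#'   `correct_strand_reads`, `mislabeled_reads`, flank coverages filled
#'   in) and `truth`.
#' @export
simulate_junction_reads <- function(junctions, depth, strand_error = 0,
                                    seed = 1L) {
  stopifnot(depth > 0, strand_error >= 0, strand_error < 1)
  n <- nrow(junctions)
  set.seed(substream_seed(seed, 21L))
  span <- rpois(n, depth)
  flipped <- rbinom(n, span, strand_error)
  junctions$spanning_reads <- span
  junctions$correct_strand_reads <- span - flipped
  junctions$mislabeled_reads <- flipped
  junctions$donor_flank_cov <- rpois(n, depth)
  junctions$acceptor_flank_cov <- rpois(n, depth)
  list(junctions = junctions,
       truth = list(depth = depth, strand_error = strand_error, seed = seed))
}

#' Simulate a neutrally evolved codon alignment
#'
#' Starts from a random sense-codon sequence and applies `n_subs` point
#' substitutions at uniform random positions with uniform random
#' alternative bases to a copy; substitutions that would create a stop
#' codon are rejected and redrawn, matching the estimator's elimination
#' of nonsense mutations. Under this neutral process the merged dN/dS is
#' approximately 1.
#'
#' @param n_codons alignment length in codons.
#' @param n_subs number of substitutions to apply.
#' @param seed integer seed.
#' @return character vector of two equal-length sequences
#'   (`ancestral`, `derived`).
#' @export
simulate_neutral_alignment <- function(n_codons, n_subs, seed = 1L) {
  set.seed(substream_seed(seed, 31L))
  anc <- paste(sample(SENSE_CODONS, n_codons, replace = TRUE), collapse = "")
  der <- strsplit(anc, "")[[1]]
  applied <- 0L
  while (applied < n_subs) {
    p <- sample.int(length(der), 1)
    b <- sample(setdiff(BASES, der[p]), 1)
    cod <- (p - 1L) %/% 3L
    trial <- der[(cod * 3L + 1L):(cod * 3L + 3L)]
    trial[(p - 1L) %% 3L + 1L] <- b
    if (paste(trial, collapse = "") %in% STOP_CODONS) next
    der[p] <- b
    applied <- applied + 1L
  }
  c(ancestral = anc, derived = paste(der, collapse = ""))
}
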