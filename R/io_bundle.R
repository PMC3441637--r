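## Writing a dataset bundle to plain-text files (Newick, gapped FASTA,
## TSV, JSON) and the manifest that load_dataset() reads back. This is
## the on-disk interchange format of the command-line interface.

#' Write a dataset bundle to a directory
#'
#' Serializes a bundle (e.g. from [simulate_study()]) as plain-text
#' files - Newick tree, gapped-FASTA alignment pairs with a TSV index,
#' presence/counts/junction TSVs, JSON manifest and truth - so that
#' `load_dataset(file.path(dir, "manifest.json"))` reconstructs it.
#'
#' @param dataset a bundle.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_bundle <- function(dataset, dir) {
  dir.create(file.path(dir, "alignments"), recursive = TRUE,
             showWarnings = FALSE)
  tsv <- function(d, name) {
    p <- file.path(dir, name)
    utils::write.table(d, p, sep = "\t", row.names = FALSE, quote = FALSE)
    p
  }
  m <- list(focal = dataset$focal, sister = dataset$sister)
  ape::write.tree(dataset$tree, file.path(dir, "tree.nwk"))
  m$tree <- file.path(dir, "tree.nwk")

  idx <- NULL; locus <- NULL
  for (g in names(dataset$genes)) {
    gene <- dataset$genes[[g]]
    for (sp in names(gene$alignments)) {
      p <- file.path(dir, "alignments", paste0(g, "_", sp, ".fa"))
      write_alignment_pair(gene$alignments[[sp]], p)
      idx <- rbind(idx, data.frame(gene = g, species = sp, path = p))
    }
    if (!is.null(gene$locus_profile))
      locus <- rbind(locus, data.frame(
        gene = g, species = names(gene$locus_profile$states),
        state = unname(gene$locus_profile$states)))
  }
  if (!is.null(idx)) m$alignments <- tsv(idx, "alignments.tsv")
  if (!is.null(locus)) m$locus_presence <- tsv(locus, "locus_presence.tsv")

  if (!is.null(dataset$expression)) {
    long <- function(em) {
      cn <- em$counts
      data.frame(gene = rep(rownames(cn), ncol(cn)),
                 tissue = rep(colnames(cn), each = nrow(cn)),
                 count = as.vector(cn))
    }
    ef <- dataset$expression$focal; eo <- dataset$expression$outgroup
    m$counts_focal <- tsv(long(ef), "counts_focal.tsv")
    m$counts_outgroup <- tsv(long(eo), "counts_outgroup.tsv")
    m$outgroup_species <- eo$species
    m$library_sizes <- tsv(rbind(
      data.frame(species = ef$species, tissue = names(ef$library_sizes),
                 size = unname(ef$library_sizes)),
      data.frame(species = eo$species, tissue = names(eo$library_sizes),
                 size = unname(eo$library_sizes))), "library_sizes.tsv")
    m$region_lengths <- tsv(
      data.frame(gene = names(ef$region_lengths),
                 length = unname(ef$region_lengths)), "region_lengths.tsv")
  }
  if (!is.null(dataset$junctions))
    m$junctions <- tsv(dataset$junctions, "junctions.tsv")
  if (!is.null(dataset$truth))
    jsonlite::write_json(dataset$truth["classes"],
                         file.path(dir, "truth.json"), auto_unbox = TRUE)
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(m, mf, auto_unbox = TRUE)
  invisible(mf)
}
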