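## Codon-indexed pairwise alignments of a focal CDS against one out-group
## ortholog. Sequences are equal-length gapped nucleotide strings; the
## focal reading frame is anchored at the alignment start, so focal codon k
## occupies the k-th triplet of focal non-gap columns.

#' Construct a codon alignment pair
#'
#' Coverage (fraction of focal CDS columns aligned to an out-group base)
#' and identity (fraction of matching bases over aligned columns) are
#' recomputed from the sequences.
#'
#' @param focal_id focal CDS identifier.
#' @param outgroup_species out-group species name.
#' @param focal_seq,outgroup_seq gapped nucleotide strings of equal length;
#'   gap character is `"-"`. The focal ungapped length must be a multiple
#'   of 3.
#' @return an object of class `codon_alignment_pair`.
#' @export
codon_alignment_pair <- function(focal_id, outgroup_species,
                                 focal_seq, outgroup_seq) {
  focal_seq <- toupper(focal_seq); outgroup_seq <- toupper(outgroup_seq)
  if (nchar(focal_seq) != nchar(outgroup_seq))
    stop("alignment sequences have unequal gapped lengths")
  f <- strsplit(focal_seq, "")[[1]]
  o <- strsplit(outgroup_seq, "")[[1]]
  if (any(f == "-" & o == "-"))
    stop("alignment contains all-gap columns")
  n_focal <- sum(f != "-")
  if (n_focal %% 3 != 0)
    stop("focal ungapped length not divisible by 3")
  aligned <- f != "-" & o != "-"
  coverage <- if (n_focal) sum(aligned) / n_focal else 0
  identity <- if (any(aligned)) mean(f[aligned] == o[aligned]) else 0
  structure(list(focal_id = focal_id, outgroup_species = outgroup_species,
                 focal_seq = focal_seq, outgroup_seq = outgroup_seq,
                 coverage = coverage, identity = identity,
                 n_codons = n_focal %/% 3L),
            class = "codon_alignment_pair")
}

#' @export
print.codon_alignment_pair <- function(x, ...) {
  cat(sprintf("<codon_alignment_pair> %s vs %s: %d codons, coverage %.2f, identity %.2f\n",
              x$focal_id, x$outgroup_species, x$n_codons,
              x$coverage, x$identity))
  invisible(x)
}

#' Write / read a gapped-FASTA alignment pair
#'
#' Two records per file: the focal CDS first, the out-group second. Record
#' names are `<focal_id>` and `<outgroup_species>`.
#'
#' @param aln a `codon_alignment_pair`.
#' @param path file path.
#' @return `read_alignment_pair` returns a `codon_alignment_pair`.
#' @export
write_alignment_pair <- function(aln, path) {
  ss <- Biostrings::BStringSet(c(aln$focal_seq, aln$outgroup_seq))
  names(ss) <- c(aln$focal_id, aln$outgroup_species)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' @rdname write_alignment_pair
#' @export
read_alignment_pair <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) != 2L)
    stop("alignment pair file must contain exactly 2 records: ", path)
  codon_alignment_pair(names(ss)[1], names(ss)[2],
                       as.character(ss[[1]]), as.character(ss[[2]]))
}
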