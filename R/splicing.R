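## Splice-junction support. A junction is an intron interval (0-based
## half-open) on an annotated strand. Support in a species requires read
## coverage on both exonic flanks plus either junction-spanning reads or
## - for strand-non-specific public data - covered flanks with a
## canonical GT-AG intron.

#' Build a junction record table
#'
#' @param chrom,intron_start,intron_end,strand intron coordinates
#'   (0-based half-open) and annotated strand.
#' @param spanning_reads junction-spanning read counts.
#' @param donor_flank_cov,acceptor_flank_cov read counts in the exonic
#'   windows flanking donor and acceptor.
#' @param first2,last2 the intron's first and last two bases on the
#'   annotated strand (e.g. `"GT"`, `"AG"`).
#' @return data frame of class `junction_table`.
#' @export
junction_records <- function(chrom, intron_start, intron_end, strand,
                             spanning_reads = 0L, donor_flank_cov = 0L,
                             acceptor_flank_cov = 0L,
                             first2 = "GT", last2 = "AG") {
  stopifnot(all(intron_end > intron_start), all(intron_start >= 0),
            all(spanning_reads >= 0), all(donor_flank_cov >= 0),
            all(acceptor_flank_cov >= 0), all(strand %in% c("+", "-")))
  d <- data.frame(chrom = chrom, intron_start = intron_start,
                  intron_end = intron_end, strand = strand,
                  spanning_reads = spanning_reads,
                  donor_flank_cov = donor_flank_cov,
                  acceptor_flank_cov = acceptor_flank_cov,
                  first2 = toupper(first2), last2 = toupper(last2),
                  stringsAsFactors = FALSE)
  class(d) <- c("junction_table", "data.frame")
  d
}

#' Classify junction support
#'
#' `insufficient_coverage` when either exonic flank has fewer than
#' `min_flank_reads` reads (the region cannot be assessed);
#' otherwise `supported` when spanning reads reach `min_span_reads` OR
#' both flanks are covered and the intron is canonical GT-AG;
#' otherwise `assessable_unsupported`.
#'
#' @param j a junction table (or single record) from [junction_records()].
#' @param min_flank_reads,min_span_reads support thresholds (default 1).
#' @return character vector of statuses.
#' @export
classify_junction <- function(j, min_flank_reads = 1, min_span_reads = 1) {
  flanks_ok <- j$donor_flank_cov >= min_flank_reads &
    j$acceptor_flank_cov >= min_flank_reads
  canonical <- j$first2 == "GT" & j$last2 == "AG"
  ifelse(!flanks_ok, "insufficient_coverage",
         ifelse(j$spanning_reads >= min_span_reads | canonical,
                "supported", "assessable_unsupported"))
}

#' Map a junction through a coordinate map
#'
#' The map is a table of collinear interval blocks (`src_chrom`,
#' `src_start`, `src_end`, `tgt_chrom`, `tgt_start`, `tgt_end`). Both
#' intron boundaries must fall inside blocks and map order-preservingly;
#' otherwise the junction is unmapped.
#'
#' @param j a single-row junction record.
#' @param coordinate_map block table as above.
#' @return list with `mapped` (logical), `junction` (mapped record or
#'   `NULL`) and `reason`.
#' @export
map_junction <- function(j, coordinate_map) {
  map_pos <- function(chrom, pos) {
    b <- coordinate_map[coordinate_map$src_chrom == chrom &
                          coordinate_map$src_start <= pos &
                          pos <= coordinate_map$src_end, , drop = FALSE]
    if (nrow(b) == 0) return(NULL)
    list(chrom = b$tgt_chrom[1], pos = b$tgt_start[1] + (pos - b$src_start[1]))
  }
  a <- map_pos(j$chrom, j$intron_start)
  b <- map_pos(j$chrom, j$intron_end)
  if (is.null(a) || is.null(b))
    return(list(mapped = FALSE, junction = NULL, reason = "boundary in map gap"))
  if (a$chrom != b$chrom)
    return(list(mapped = FALSE, junction = NULL, reason = "split across targets"))
  if (b$pos <= a$pos)
    return(list(mapped = FALSE, junction = NULL, reason = "inverted mapping"))
  out <- j
  out$chrom <- a$chrom
  out$intron_start <- a$pos
  out$intron_end <- b$pos
  list(mapped = TRUE, junction = out, reason = NA_character_)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Splice-site position-frequency matrices
#'
#' Summarizes donor and acceptor motifs over a junction set: per-position
#' base frequencies (A, C, G, T) in a window of 3 exonic + 6 intronic
#' bases around the donor and 6 intronic + 3 exonic around the acceptor,
#' read on the annotated strand (minus-strand junctions are
#' reverse-complemented). `N` bases are excluded from their column's
#' denominator. Canonical junctions put G=1, T=1 at donor +1, +2 and
#' A=1, G=1 at acceptor -2, -1.
#'
#' @param junctions junction table ([junction_records()]).
#' @param genome named character vector (or `DNAStringSet`) of chromosome
#'   sequences.
#' @param exonic,intronic window sizes (defaults 3 and 6).
#' @return list of two 4 x 9 matrices, `donor` and `acceptor`, with
#'   columns summing to 1 where defined.
#' @export
junction_motif_matrix <- function(junctions, genome, exonic = 3L,
                                  intronic = 6L) {
  stopifnot(nrow(junctions) >= 1)
  if (methods::is(genome, "XStringSet"))
    genome <- stats::setNames(as.character(genome), names(genome))
  w <- exonic + intronic
  donor_counts <- matrix(0, 4, w, dimnames = list(c("A", "C", "G", "T"), NULL))
  acceptor_counts <- donor_counts
  for (i in seq_len(nrow(junctions))) {
    jj <- junctions[i, ]
    g <- genome[[jj$chrom]]
    s <- jj$intron_start; e <- jj$intron_end       # 0-based half-open
    if (jj$strand == "+") {
      donor <- substr(g, s - exonic + 1L, s + intronic)
      acceptor <- substr(g, e - intronic + 1L, e + exonic)
    } else {
      donor <- revcomp(substr(g, e - intronic + 1L, e + exonic))
      acceptor <- substr(g, s - exonic + 1L, s + intronic)
      acceptor <- revcomp(acceptor)
    }
    stopifnot(nchar(donor) == w, nchar(acceptor) == w)
    for (p in seq_len(w)) {
      bd <- substr(donor, p, p); ba <- substr(acceptor, p, p)
      if (bd %in% rownames(donor_counts))
        donor_counts[bd, p] <- donor_counts[bd, p] + 1
      if (ba %in% rownames(acceptor_counts))
        acceptor_counts[ba, p] <- acceptor_counts[ba, p] + 1
    }
  }
  normalize <- function(m) sweep(m, 2, pmax(colSums(m), 1e-300), "/")
  pos_d <- c(paste0("-", rev(seq_len(exonic))), paste0("+", seq_len(intronic)))
  pos_a <- c(paste0("-", rev(seq_len(intronic))), paste0("+", seq_len(exonic)))
  donor <- normalize(donor_counts); colnames(donor) <- pos_d
  acceptor <- normalize(acceptor_counts); colnames(acceptor) <- pos_a
  list(donor = donor, acceptor = acceptor)
}
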