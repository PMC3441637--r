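## Expression quantification. RPKM (reads per kilobase of exon model per
## million mapped reads) is computed over *representative regions*: the
## exonic intervals of a gene that overlap no other annotated gene on
## either strand, so the signal is attributable, and (optionally) have a
## syntenic image in the other species, so the same region is quantified
## everywhere. Coordinates are 0-based half-open (BED native) throughout.

#' Select representative regions for a gene
#'
#' Subtracts the union of all other genes' intervals (strand-agnostic:
#' antisense overlap also disqualifies) from the gene's exonic intervals,
#' then intersects with the syntenic map if one is given. An empty result
#' flags the gene un-quantifiable.
#'
#' @param gene_model data frame of the gene's exon intervals with columns
#'   `chrom`, `start`, `end` (0-based half-open), e.g. from
#'   [bed12_exons()].
#' @param other_genes data frame of all other genes' intervals (`chrom`,
#'   `start`, `end`; strand ignored).
#' @param synteny_map optional data frame (`chrom`, `start`, `end`) of
#'   intervals with a syntenic image in the comparison species; exonic
#'   sub-intervals outside the map are dropped.
#' @param gene gene identifier for reporting.
#' @return object of class `representative_region`: list with `gene`,
#'   `intervals` (data frame), `total_length`, `quantifiable`.
#' @export
select_representative_regions <- function(gene_model, other_genes = NULL,
                                          synteny_map = NULL,
                                          gene = "gene") {
  check_bed(gene_model)
  res <- list()
  for (chr in unique(gene_model$chrom)) {
    g <- gene_model[gene_model$chrom == chr, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(g$start + 1L, g$end))
    if (!is.null(other_genes) && nrow(other_genes) > 0) {
      check_bed(other_genes)
      o <- other_genes[other_genes$chrom == chr, , drop = FALSE]
      if (nrow(o) > 0) {
        oir <- IRanges::reduce(IRanges::IRanges(o$start + 1L, o$end))
        ir <- IRanges::setdiff(ir, oir)
      }
    }
    if (!is.null(synteny_map)) {
      s <- synteny_map[synteny_map$chrom == chr, , drop = FALSE]
      sir <- if (nrow(s) > 0)
        IRanges::reduce(IRanges::IRanges(s$start + 1L, s$end))
      else IRanges::IRanges()
      ir <- IRanges::intersect(ir, sir)
    }
    if (length(ir) > 0)
      res[[chr]] <- data.frame(chrom = chr,
                               start = IRanges::start(ir) - 1L,
                               end = IRanges::end(ir))
  }
  intervals <- if (length(res)) do.call(rbind, res) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0))
  rownames(intervals) <- NULL
  total <- sum(intervals$end - intervals$start)
  structure(list(gene = gene, intervals = intervals,
                 total_length = total, quantifiable = total > 0),
            class = "representative_region")
}

check_bed <- function(d) {
  if (!all(c("chrom", "start", "end") %in% names(d)))
    stop("BED-like data frame needs chrom/start/end columns")
  bad <- which(d$end < d$start | d$start < 0)
  if (length(bad))
    stop("malformed BED row(s): ", paste(bad, collapse = ", "))
  invisible(d)
}

#' Expand a BED12 row into exon intervals
#'
#' @param row one-row data frame with BED12 columns (`chrom`, `start`,
#'   `end`, `name`, `score`, `strand`, `thickStart`, `thickEnd`,
#'   `itemRgb`, `blockCount`, `blockSizes`, `blockStarts`).
#' @return data frame of exon intervals (`chrom`, `start`, `end`).
#' @export
bed12_exons <- function(row) {
  sizes <- as.integer(strsplit(as.character(row$blockSizes), ",")[[1]])
  offs <- as.integer(strsplit(as.character(row$blockStarts), ",")[[1]])
  data.frame(chrom = row$chrom,
             start = row$start + offs,
             end = row$start + offs + sizes)
}

#' Reads-per-kilobase-per-million normalization
#'
#' `RPKM = count / (region_length/1000) / (library_size/1e6)`.
#'
#' @param count read count(s) in the region.
#' @param region_length region length in bp (> 0).
#' @param library_size mapped reads in the library (> 0).
#' @return numeric RPKM (vectorized).
#' @export
compute_rpkm <- function(count, region_length, library_size) {
  if (any(region_length <= 0)) stop("region_length must be positive")
  if (any(library_size <= 0)) stop("library_size must be positive")
  count / (region_length / 1000) / (library_size / 1e6)
}

#' Empirical intergenic transcription background
#'
#' Samples `n` intergenic regions (with replacement when fewer are
#' available), computes their RPKM, and returns the empirical
#' distribution with a finite-sample tail probability
#' `p(r) = (1 + #\{background >= r\}) / (1 + n)` - never exactly zero.
#'
#' @param intergenic_regions data frame with `chrom`, `start`, `end`.
#' @param counts read counts per region (same order).
#' @param library_size mapped reads.
#' @param n number of background draws (default 10000).
#' @param seed optional integer seed for the sampling.
#' @return object of class `intergenic_background` with elements `values`
#'   and `n`; evaluate tails with [background_p()].
#' @export
intergenic_background <- function(intergenic_regions, counts, library_size,
                                  n = 10000, seed = NULL) {
  check_bed(intergenic_regions)
  m <- nrow(intergenic_regions)
  if (m < 100) stop("need at least 100 intergenic regions")
  stopifnot(length(counts) == m)
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(m, n, replace = m < n)
  len <- intergenic_regions$end - intergenic_regions$start
  vals <- compute_rpkm(counts[idx], len[idx], library_size)
  structure(list(values = vals, n = n), class = "intergenic_background")
}

#' Monte-Carlo tail probability against the intergenic background
#' @param background an [intergenic_background()] object.
#' @param rpkm query RPKM value(s).
#' @return p-value(s) in (0, 1].
#' @export
background_p <- function(background, rpkm) {
  stopifnot(inherits(background, "intergenic_background"))
  vapply(rpkm, function(r)
    (1 + sum(background$values >= r)) / (1 + background$n), numeric(1))
}

#' Call convincing transcription
#'
#' A region is transcribed when its RPKM exceeds the fixed cutoff (0.2)
#' AND is significantly above the intergenic background (Monte-Carlo
#' p < alpha). A gene counts as transcribed in a species if any tissue
#' passes.
#'
#' @param rpkm RPKM value(s).
#' @param background an [intergenic_background()] object.
#' @param rpkm_cutoff fixed cutoff (default 0.2, strict `>`).
#' @param alpha Monte-Carlo significance level (default 0.05, strict `<`).
#' @return logical vector, `TRUE` = transcribed.
#' @export
call_transcription <- function(rpkm, background, rpkm_cutoff = 0.2,
                               alpha = 0.05) {
  rpkm > rpkm_cutoff & background_p(background, rpkm) < alpha
}

#' Tissue expression proportions
#'
#' Normalizes a gene's per-tissue RPKM by its summed RPKM in that species.
#' All-zero vectors are undefined and return `NA`s (such genes are
#' excluded from profile analyses).
#'
#' @param x numeric vector (one gene across >= 2 tissues) or a genes x
#'   tissues matrix (row-wise normalization).
#' @return proportions summing to 1 per gene, or `NA`s for all-zero input.
#' @export
tissue_proportions <- function(x) {
  if (is.matrix(x)) return(t(apply(x, 1, tissue_proportions)))
  stopifnot(length(x) >= 2)
  if (any(x < 0)) stop("negative RPKM")
  s <- sum(x)
  if (s == 0) return(rep(NA_real_, length(x)))
  x / s
}

#' Read-density profile across a transcript and its flanks
#'
#' Rescales the transcript to `bins` bins and each flank to `bins/2`,
#' sums per-base coverage within each bin and normalizes by the total over
#' the whole window, so the profile sums to 1. Uniform coverage gives a
#' flat profile at `1/(2*bins)` when the flanks are half the transcript
#' length.
#'
#' @param coverage numeric per-base coverage over
#'   `[upstream flank | transcript | downstream flank]`.
#' @param flank_length length in bases of each flank (conventionally 50%
#'   of the transcript length).
#' @param bins number of transcript bins (default 100; flanks get
#'   `bins/2` each).
#' @return named numeric vector of length `2*bins` summing to 1, or
#'   `NULL` (with a warning) when total coverage is zero.
#' @export
density_profile <- function(coverage, flank_length, bins = 100) {
  n <- length(coverage)
  tx_len <- n - 2L * flank_length
  stopifnot(tx_len > 0, bins %% 2 == 0)
  total <- sum(coverage)
  if (total == 0) {
    warning("zero total coverage; profile omitted")
    return(NULL)
  }
  up <- coverage[seq_len(flank_length)]
  tx <- coverage[(flank_length + 1L):(flank_length + tx_len)]
  dn <- coverage[(flank_length + tx_len + 1L):n]
  half <- bins %/% 2L
  prof <- c(bin_sums(up, half), bin_sums(tx, bins), bin_sums(dn, half)) / total
  names(prof) <- c(paste0("up", seq_len(half)), paste0("tx", seq_len(bins)),
                   paste0("down", seq_len(half)))
  prof
}

bin_sums <- function(v, k) {
  if (length(v) == 0) return(numeric(k))
  bin <- pmin(floor((seq_along(v) - 1) * k / length(v)) + 1L, k)
  as.numeric(tapply(v, factor(bin, levels = seq_len(k)), sum, default = 0))
}

#' Classify a gene's genomic transcriptional context
#'
#' Multi-label classification of how a new gene co-opts pre-existing
#' transcription: `same_strand_overlap` / `antisense_overlap` when its
#' span intersects another gene on the same / opposite strand, and `bi`
#' when a divergently oriented gene's TSS lies within `bidir_window` bp
#' upstream of the focal TSS (a shared bi-directional promoter).
#'
#' @param gene one-row data frame with `chrom`, `start`, `end`, `strand`.
#' @param annotations data frame of other genes (same columns).
#' @param bidir_window upstream window in bp (default 1000).
#' @return character vector of labels, or `"none"`.
#' @export
classify_context <- function(gene, annotations, bidir_window = 1000) {
  stopifnot(gene$strand %in% c("+", "-"))
  labs <- character(0)
  a <- annotations[annotations$chrom == gene$chrom, , drop = FALSE]
  if (nrow(a) > 0) {
    ovl <- a$start < gene$end & a$end > gene$start
    if (any(ovl & a$strand == gene$strand)) labs <- c(labs, "same_strand_overlap")
    if (any(ovl & a$strand != gene$strand)) labs <- c(labs, "antisense_overlap")
    focal_tss <- if (gene$strand == "+") gene$start else gene$end
    other_tss <- ifelse(a$strand == "+", a$start, a$end)
    divergent <- a$strand != gene$strand &
      (if (gene$strand == "+")
         other_tss < focal_tss & focal_tss - other_tss <= bidir_window
       else
         other_tss > focal_tss & other_tss - focal_tss <= bidir_window)
    if (any(divergent)) labs <- c(labs, "bi")
  }
  if (length(labs) == 0) "none" else labs
}

#' Library quality-control summary
#'
#' Strand-specific libraries should show > 100-fold more correctly
#' stranded than strand-mislabeled reads, and exonic read density > 100
#' times the intronic/intergenic density (mature polyadenylated RNA).
#' Ratios at or below 100 raise flags; zero denominators give `Inf`
#' without a flag.
#'
#' @param strand_counts data frame with `tissue`, `correct`, `mislabeled`.
#' @param region_class_densities data frame with `tissue`, `exon`,
#'   `intron`, `intergenic` mean densities.
#' @param per_position_mismatches numeric vector of mean mismatches per
#'   read position; its sum is the mean errors per read.
#' @return object of class `qc_report`.
#' @export
qc_summary <- function(strand_counts, region_class_densities,
                       per_position_mismatches = numeric(0)) {
  stopifnot(all(strand_counts$correct >= 0),
            all(strand_counts$mislabeled >= 0))
  strand_ratio <- ifelse(strand_counts$mislabeled == 0, Inf,
                         strand_counts$correct / strand_counts$mislabeled)
  exon_intron <- ifelse(region_class_densities$intron == 0, Inf,
                        region_class_densities$exon /
                          region_class_densities$intron)
  exon_intergenic <- ifelse(region_class_densities$intergenic == 0, Inf,
                            region_class_densities$exon /
                              region_class_densities$intergenic)
  flags <- character(0)
  if (any(is.finite(strand_ratio) & strand_ratio <= 100))
    flags <- c(flags, "strand_ratio")
  if (any(is.finite(exon_intron) & exon_intron <= 100))
    flags <- c(flags, "exon_intron_ratio")
  structure(list(
    strand_ratio = stats::setNames(strand_ratio, strand_counts$tissue),
    exon_intron_ratio = stats::setNames(exon_intron,
                                        region_class_densities$tissue),
    exon_intergenic_ratio = stats::setNames(exon_intergenic,
                                            region_class_densities$tissue),
    mean_errors_per_read = sum(per_position_mismatches),
    flags = flags), class = "qc_report")
}

#' Construct an expression matrix container
#'
#' @param species species name.
#' @param rpkm genes x tissues numeric matrix with dimnames.
#' @param library_sizes named per-tissue mapped-read counts.
#' @param region_lengths named per-gene representative-region lengths.
#' @param counts optional genes x tissues raw counts (RPKM must be
#'   recomputable from them).
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(species, rpkm, library_sizes, region_lengths,
                              counts = NULL) {
  stopifnot(is.matrix(rpkm), !is.null(rownames(rpkm)),
            !is.null(colnames(rpkm)), all(rpkm >= 0))
  stopifnot(all(colnames(rpkm) %in% names(library_sizes)),
            all(rownames(rpkm) %in% names(region_lengths)))
  structure(list(species = species, rpkm = rpkm,
                 library_sizes = library_sizes[colnames(rpkm)],
                 region_lengths = region_lengths[rownames(rpkm)],
                 counts = counts),
            class = "expression_matrix")
}

as_rpkm_matrix <- function(x) {
  if (inherits(x, "expression_matrix")) x$rpkm else as.matrix(x)
}
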