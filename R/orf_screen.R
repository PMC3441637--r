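## Out-group ORF screening: given a codon-based pairwise alignment of the
## focal CDS against an orthologous out-group sequence, decide whether the
## out-group still encodes the ORF. An "ORF disabler" is a premature stop
## codon or a frame-disrupting (length not divisible by 3) indel read in
## the focal frame; an ORF is called absent only if it is disabled AND the
## maximum continuous disabler-free peptide is shorter than a fraction
## (default 70%) of the focal peptide.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Assess alignment reliability
#'
#' Only reliable alignments (coverage >= 70% and identity >= 50%, both
#' inclusive) support presence/absence inference; anything less is
#' ambiguous - rapidly-evolving or partially assembled loci cannot tell an
#' absent ORF from a misaligned one.
#'
#' @param aln a [codon_alignment_pair()].
#' @param min_coverage,min_identity inclusive thresholds.
#' @return `"reliable"` or `"ambiguous"`.
#' @export
assess_reliability <- function(aln, min_coverage = 0.70, min_identity = 0.50) {
  stopifnot(inherits(aln, "codon_alignment_pair"))
  if (aln$coverage >= min_coverage && aln$identity >= min_identity)
    "reliable" else "ambiguous"
}

#' Detect ORF disablers in an out-group sequence
#'
#' The out-group sequence is scanned in the focal reading frame. An
#' in-frame stop (TAA/TAG/TGA) at a focal codon before the terminal stop
#' is a `premature_stop`. A maximal gap run in either sequence whose
#' length is not divisible by 3 is a `frameshift_indel`, positioned at the
#' focal codon containing its first column. Disablers mark positions; the
#' frame is re-anchored to the focal frame after each indel, so a single
#' frameshift does not cascade into spurious downstream stops.
#'
#' @param aln a [codon_alignment_pair()] (assumed reliable).
#' @return data frame with columns `kind`, `focal_codon`, `detail`,
#'   sorted by `focal_codon`.
#' @export
detect_disablers <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment_pair"))
  f <- strsplit(aln$focal_seq, "")[[1]]
  o <- strsplit(aln$outgroup_seq, "")[[1]]
  n_col <- length(f)
  focal_pos <- cumsum(f != "-")            # focal ungapped position per column
  codon_of_col <- ifelse(f != "-", (focal_pos - 1L) %/% 3L + 1L, NA_integer_)
  n_codons <- aln$n_codons

  kind <- character(0); codon <- integer(0); detail <- character(0)

  ## frameshift indels: maximal gap runs in either sequence
  for (seq_chars in list(f, o)) {
    r <- rle(seq_chars == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      len <- r$lengths[i]
      if (len %% 3L == 0L) next
      first_col <- starts[i]
      ## codon containing the first column: for insertions (focal gap) the
      ## first focal base at/after the run anchors the codon
      cd <- codon_of_col[first_col]
      if (is.na(cd)) {
        later <- codon_of_col[first_col:n_col]
        cd <- if (any(!is.na(later))) later[!is.na(later)][1] else n_codons
      }
      kind <- c(kind, "frameshift_indel")
      codon <- c(codon, cd)
      detail <- c(detail, as.character(len))
    }
  }

  ## premature stops: out-group bases at the focal codon's columns
  for (k in seq_len(max(n_codons - 1L, 0L))) {
    cols <- which(!is.na(codon_of_col) & codon_of_col == k)
    trip <- o[cols]
    if (length(trip) == 3L && !any(trip == "-") &&
        paste(trip, collapse = "") %in% STOP_CODONS) {
      kind <- c(kind, "premature_stop")
      codon <- c(codon, k)
      detail <- c(detail, paste(trip, collapse = ""))
    }
  }

  out <- data.frame(kind = kind, focal_codon = codon, detail = detail,
                    stringsAsFactors = FALSE)
  out[order(out$focal_codon, out$kind), , drop = FALSE]
}

#' Call out-group ORF status from disablers
#'
#' `max_peptide_fraction` is the longest run of focal codons free of any
#' disabler divided by the focal peptide length (codon count minus the
#' terminal stop; set `denominator = "codons"` to divide by the full codon
#' count instead). The ORF is `absent` only when at least one disabler
#' exists and the fraction falls below `max_fraction_threshold`; a
#' disabled but barely-truncated ORF stays `present`. Threshold 0.50
#' reproduces the stricter gene list.
#'
#' @param aln a [codon_alignment_pair()].
#' @param disablers result of [detect_disablers()]; computed if missing.
#' @param max_fraction_threshold truncation threshold (default 0.70).
#' @param denominator `"aa"` (peptide length, default) or `"codons"`.
#' @return an object of class `orf_call`: list with `species`, `status`,
#'   `max_peptide_fraction`, `disablers`.
#' @export
call_orf_status <- function(aln, disablers = NULL,
                            max_fraction_threshold = 0.70,
                            denominator = c("aa", "codons")) {
  stopifnot(inherits(aln, "codon_alignment_pair"))
  denominator <- match.arg(denominator)
  if (is.null(disablers)) disablers <- detect_disablers(aln)
  n_codons <- aln$n_codons
  n_aa <- n_codons - 1L
  denom <- if (denominator == "aa") n_aa else n_codons
  if (nrow(disablers) == 0L) {
    frac <- 1
  } else {
    hit <- sort(unique(pmin(pmax(disablers$focal_codon, 1L), n_aa)))
    runs <- diff(c(0L, hit, n_aa + 1L)) - 1L
    frac <- max(runs) / denom
  }
  status <- if (nrow(disablers) > 0L && frac < max_fraction_threshold)
    "absent" else "present"
  structure(list(species = aln$outgroup_species, status = status,
                 max_peptide_fraction = frac, disablers = disablers),
            class = "orf_call")
}

#' Screen one out-group: reliability, disablers, status
#'
#' Convenience wrapper: an ambiguous alignment yields status `"ambiguous"`
#' with no disabler scan.
#'
#' @inheritParams call_orf_status
#' @inheritParams assess_reliability
#' @return an `orf_call`.
#' @export
screen_outgroup <- function(aln, min_coverage = 0.70, min_identity = 0.50,
                            max_fraction_threshold = 0.70,
                            denominator = "aa") {
  if (assess_reliability(aln, min_coverage, min_identity) == "ambiguous") {
    return(structure(list(species = aln$outgroup_species,
                          status = "ambiguous",
                          max_peptide_fraction = NA_real_,
                          disablers = detect_disablers(aln)[0, ]),
                     class = "orf_call"))
  }
  call_orf_status(aln, max_fraction_threshold = max_fraction_threshold,
                  denominator = denominator)
}

#' Shared ancestral disablers across out-groups
#'
#' A disabler shared (same kind, same focal codon) by two or more
#' out-group species was most plausibly present in their common ancestor,
#' so the ORF was never intact there: the gene is being born in the
#' in-group, not dying in the out-groups. Genes without any shared
#' disabler stay "birth-vs-loss unresolved".
#'
#' @param calls list of `orf_call` objects (one per out-group).
#' @return data frame with `focal_codon`, `kind`, `species` (list column),
#'   `n_species`; zero rows when nothing is shared.
#' @export
shared_ancestral_disablers <- function(calls) {
  stopifnot(length(calls) >= 2L)
  tab <- do.call(rbind, lapply(calls, function(cl) {
    d <- cl$disablers
    if (nrow(d) == 0L) return(NULL)
    d$species <- cl$species
    d
  }))
  empty <- data.frame(focal_codon = integer(0), kind = character(0),
                      n_species = integer(0))
  empty$species <- list()
  if (is.null(tab) || nrow(tab) == 0L) return(empty)
  key <- paste(tab$kind, tab$focal_codon)
  out <- do.call(rbind, lapply(split(tab, key), function(g) {
    sp <- sort(unique(g$species))
    if (length(sp) < 2L) return(NULL)
    r <- data.frame(focal_codon = g$focal_codon[1], kind = g$kind[1],
                    n_species = length(sp))
    r$species <- list(sp)
    r
  }))
  if (is.null(out)) return(empty)
  out <- out[order(out$focal_codon), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Paralog screen against the focal proteome
#'
#' A de novo gene must not descend from a mother gene: it fails if any
#' non-self homology hit has E-value at or below `evalue_cutoff`, or -
#' because short proteins inflate E-values - if any supplied pairwise
#' alignment against another protein has coverage >= 70% and identity
#' >= 50%.
#'
#' @param hit_table data frame of non-self homology hits in 12-column
#'   tabular format (at minimum a numeric `evalue` column; standard column
#'   order assumed when unnamed). Malformed rows are skipped with a
#'   warning.
#' @param self_alignments optional data frame with columns `partner`,
#'   `coverage`, `identity` (pairwise alignments against other proteins).
#' @param evalue_cutoff,min_coverage,min_identity thresholds.
#' @return `"pass"`, or `"fail"` with a `reason` attribute
#'   (`"evalue"` or `"align-well"`).
#' @export
paralog_screen <- function(hit_table, self_alignments = NULL,
                           evalue_cutoff = 1e-6,
                           min_coverage = 0.70, min_identity = 0.50) {
  blast_cols <- c("qid", "sid", "pident", "length", "mismatch", "gapopen",
                  "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (!is.null(hit_table) && nrow(hit_table) > 0) {
    if (!"evalue" %in% names(hit_table) && ncol(hit_table) == 12L)
      names(hit_table) <- blast_cols
    ev <- suppressWarnings(as.numeric(hit_table$evalue))
    if (anyNA(ev)) {
      warning(sum(is.na(ev)), " malformed hit row(s) skipped")
      ev <- ev[!is.na(ev)]
    }
    if (any(ev <= evalue_cutoff)) {
      out <- "fail"; attr(out, "reason") <- "evalue"
      return(out)
    }
  }
  if (!is.null(self_alignments) && nrow(self_alignments) > 0) {
    well <- self_alignments$coverage >= min_coverage &
      self_alignments$identity >= min_identity
    if (any(well, na.rm = TRUE)) {
      out <- "fail"; attr(out, "reason") <- "align-well"
      return(out)
    }
  }
  "pass"
}

## minimum Hamming distance between `pep` and any equal-length window of
## `target`; Inf when target is shorter than pep
min_window_mismatches <- function(pep, target) {
  k <- nchar(pep); n <- nchar(target)
  if (n < k) return(Inf)
  p <- strsplit(pep, "")[[1]]
  t <- strsplit(target, "")[[1]]
  best <- Inf
  for (i in seq_len(n - k + 1L)) {
    mm <- sum(p != t[i:(i + k - 1L)])
    if (mm < best) best <- mm
    if (best == 0L) break
  }
  best
}

#' Peptide-evidence test for translation
#'
#' A mass-spectrometry peptide is convincing evidence that a CDS is
#' translated only if it matches the CDS translation exactly and its best
#' match anywhere else in the proteome (if any) carries at least two
#' mismatches, so the spectrum cannot be explained by another gene.
#'
#' @param peptide amino-acid string, length >= 6.
#' @param target_translation translation of the candidate CDS.
#' @param decoy_translations character vector of all other protein
#'   translations in the genome.
#' @return `"convincing"` or `"rejected"`.
#' @export
peptide_evidence <- function(peptide, target_translation,
                             decoy_translations = character(0)) {
  stopifnot(nchar(peptide) >= 6L)
  if (!grepl(peptide, target_translation, fixed = TRUE)) return("rejected")
  if (length(decoy_translations) == 0L) return("convincing")
  best <- min(vapply(decoy_translations,
                     function(d) min_window_mismatches(peptide, d),
                     numeric(1)))
  if (best >= 2) "convincing" else "rejected"
}
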