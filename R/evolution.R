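## Pooled Nei-Gojobori (1986) dN/dS on concatenated codon alignments.
## Sites: at each codon position the fraction of the possible nucleotide
## changes that are synonymous, with nonsense (stop-producing) changes
## eliminated from the tally as in the classical method. Differences
## between a codon pair: averaged over all orderings of the differing
## positions with equal weight, excluding pathways that pass through a
## stop codon (falling back to all pathways when every one does).
## Proportions are Jukes-Cantor corrected and the counts are pooled over
## the whole concatenation before the ratio is formed ("merged" dN/dS),
## as classical sliding-window tools do.

BASES <- c("A", "C", "G", "T")

codon_aa <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

is_stop <- function(codon) codon %in% STOP_CODONS

## synonymous site count of one codon (0..3); each position contributes
## the fraction of its non-nonsense changes that are synonymous
syn_sites_codon <- function(codon) {
  aa <- codon_aa(codon)
  s <- 0
  for (pos in 1:3) {
    n_syn <- 0L; n_ok <- 0L
    for (b in setdiff(BASES, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (is_stop(mut)) next
      n_ok <- n_ok + 1L
      if (codon_aa(mut) == aa) n_syn <- n_syn + 1L
    }
    if (n_ok > 0) s <- s + n_syn / n_ok
  }
  s
}

## permutations of 1..n (n <= 3)
perms <- function(n) {
  if (n == 1) return(list(1L))
  if (n == 2) return(list(c(1L, 2L), c(2L, 1L)))
  list(c(1L,2L,3L), c(1L,3L,2L), c(2L,1L,3L),
       c(2L,3L,1L), c(3L,1L,2L), c(3L,2L,1L))
}

## synonymous / nonsynonymous differences between two codons, averaged
## over equally weighted mutational pathways; pathways through stop
## codons are excluded when any stop-free pathway exists
pathway_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(pos)
  if (nd == 0) return(c(sd = 0, nd = 0))
  paths <- perms(nd)
  tally <- function(order_idx, allow_stops) {
    cur <- c1; sd <- 0; nsd <- 0
    for (p in pos[order_idx]) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (!allow_stops && is_stop(nxt) && nxt != c2) return(NULL)
      if (!is_stop(cur) && !is_stop(nxt) &&
          codon_aa(cur) == codon_aa(nxt)) sd <- sd + 1 else nsd <- nsd + 1
      cur <- nxt
    }
    c(sd, nsd)
  }
  res <- Filter(Negate(is.null), lapply(paths, tally, allow_stops = FALSE))
  if (length(res) == 0)
    res <- lapply(paths, tally, allow_stops = TRUE)
  m <- Reduce(`+`, res) / length(res)
  c(sd = m[1], nd = m[2])
}

## memoized per-codon sites and per-pair differences
.ng_cache <- new.env(parent = emptyenv())

ng_sites <- function(codon) {
  key <- paste0("S_", codon)
  if (is.null(.ng_cache[[key]])) .ng_cache[[key]] <- syn_sites_codon(codon)
  .ng_cache[[key]]
}

ng_diffs <- function(c1, c2) {
  key <- paste0("D_", c1, c2)
  if (is.null(.ng_cache[[key]])) .ng_cache[[key]] <- pathway_diffs(c1, c2)
  .ng_cache[[key]]
}

## aligned triplet columns in the reference frame; gap-containing
## triplets are skipped pairwise downstream
split_codons <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  substring(seq, seq(1, n, 3), pmin(seq(3, n + 2, 3), n))
}

#' Merged (pooled) Nei-Gojobori dN/dS over concatenated alignments
#'
#' Counts synonymous/nonsynonymous sites and differences for every codon
#' pair across all blocks, pools them, applies the Jukes-Cantor multiple-
#' hit correction to the pooled proportions, and reports dN/dS. Codon
#' pairs containing gaps, ambiguity codes or a stop in either sequence
#' are excluded pairwise. Sites are averaged between the two sequences.
#'
#' @param aln_set a list of alignment blocks; each block a character
#'   vector of >= 2 equal-length in-frame sequences (the first two are
#'   used), or a single block as a character vector.
#' @return list with `dN`, `dS`, `ratio` (`NA` when `dS` is 0 or
#'   undefined), the pooled counts `S`, `N`, `Sd`, `Nd`, the raw
#'   proportions `pS`, `pN` and `codons_used`.
#' @export
merged_dnds <- function(aln_set) {
  if (is.character(aln_set)) aln_set <- list(aln_set)
  S <- N <- Sd <- Nd <- 0
  used <- 0L
  for (block in aln_set) {
    stopifnot(length(block) >= 2)
    a <- block[[1]]; b <- block[[2]]
    if (nchar(a) != nchar(b)) stop("block sequences of unequal length")
    if (nchar(a) %% 3 != 0)
      stop("block length not divisible by 3")
    ca <- split_codons(a); cb <- split_codons(b)
    n <- min(length(ca), length(cb))
    for (i in seq_len(n)) {
      c1 <- ca[i]; c2 <- cb[i]
      if (nchar(c1) != 3 || nchar(c2) != 3) next
      if (grepl("[^ACGT]", c1) || grepl("[^ACGT]", c2)) next
      if (is_stop(c1) || is_stop(c2)) next
      s1 <- ng_sites(c1); s2 <- ng_sites(c2)
      S <- S + (s1 + s2) / 2
      N <- N + 3 - (s1 + s2) / 2
      d <- ng_diffs(c1, c2)
      Sd <- Sd + d[["sd"]]
      Nd <- Nd + d[["nd"]]
      used <- used + 1L
    }
  }
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  dS <- jc(pS); dN <- jc(pN)
  ratio <- if (!is.na(dS) && dS > 0 && !is.na(dN)) dN / dS else NA_real_
  list(dN = dN, dS = dS, ratio = ratio, S = S, N = N, Sd = Sd, Nd = Nd,
       pS = pS, pN = pN, codons_used = used)
}

#' Read codon alignment blocks from FASTA files
#'
#' Each file holds one block: >= 2 aligned in-frame sequences.
#'
#' @param paths FASTA file paths.
#' @return a list of character-vector blocks for [merged_dnds()].
#' @export
read_codon_blocks <- function(paths) {
  lapply(paths, function(p) {
    ss <- Biostrings::readBStringSet(p)
    stats::setNames(as.character(ss), names(ss))
  })
}
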