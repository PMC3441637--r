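mk_aln <- function(focal, outgroup, species = "rhesus") {
  codon_alignment_pair("focal", species, focal, outgroup)
}

test_that("coverage and identity are recomputed from the sequences", {
  # 4 codons; out-group misses one codon (in-frame gap) and mismatches 2 bases
  aln <- mk_aln("ATGAAACCCTAA", "ATG---CCGTAT")
  expect_equal(aln$coverage, 9 / 12)
  expect_equal(aln$identity, 7 / 9)
  expect_error(mk_aln("ATGAAA", "ATG"), "unequal")
  expect_error(codon_alignment_pair("f", "o", "ATGA", "ATGC"),
               "divisible by 3")
})

test_that("assess_reliability uses inclusive thresholds", {
  aln <- mk_aln("ATGAAACCCTAA", "ATGAAACCCTAA")
  aln$coverage <- 0.75; aln$identity <- 0.60
  expect_equal(assess_reliability(aln), "reliable")
  aln$coverage <- 0.69; aln$identity <- 0.90
  expect_equal(assess_reliability(aln), "ambiguous")
  aln$coverage <- 0.70; aln$identity <- 0.50
  expect_equal(assess_reliability(aln), "reliable")
})

test_that("detect_disablers finds stops and frameshifts at focal codons", {
  d <- detect_disablers(mk_aln("ATGAAATGGTAA", "ATGTAATGGTAA"))
  expect_equal(d$kind, "premature_stop")
  expect_equal(d$focal_codon, 2L)
  expect_equal(d$detail, "TAA")

  # 1-nt deletion inside codon 2
  d2 <- detect_disablers(mk_aln("ATGAAATGGTAA", "ATGA-ATGGTAA"))
  expect_equal(d2$kind, "frameshift_indel")
  expect_equal(d2$focal_codon, 2L)
  expect_equal(d2$detail, "1")

  # identical sequences
  expect_equal(nrow(detect_disablers(mk_aln("ATGAAATGGTAA", "ATGAAATGGTAA"))),
               0L)

  # terminal stop is not premature
  expect_equal(nrow(detect_disablers(mk_aln("ATGAAATGGTAA", "ATGAAATGGTAA"))),
               0L)
})

test_that("in-frame indels are not disablers", {
  # 60-codon focal; out-group with one 3-nt in-frame deletion only
  set.seed(7)
  codons <- c("ATG", sample(setdiff(names(Biostrings::GENETIC_CODE),
                                    c("TAA", "TAG", "TGA")), 58,
                            replace = TRUE), "TAA")
  focal <- paste(codons, collapse = "")
  out <- strsplit(focal, "")[[1]]
  out[31:33] <- "-"                       # deletes codon 11 exactly
  aln <- mk_aln(focal, paste(out, collapse = ""))
  expect_equal(nrow(detect_disablers(aln)), 0L)
  # cross-check: the gapless out-group still translates without stops
  og <- gsub("-", "", aln$outgroup_seq)
  aas <- strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(og))), "")[[1]]
  expect_false("*" %in% head(aas, -1))
})

test_that("disabler positions shift exactly under a prepended in-frame block", {
  base_f <- "ATGAAATGGTAA"; base_o <- "ATGTAATGGTAA"
  d0 <- detect_disablers(mk_aln(base_f, base_o))
  for (n_extra in 1:3) {
    block <- paste(rep("GGG", n_extra), collapse = "")
    d <- detect_disablers(mk_aln(paste0(block, base_f),
                                 paste0(block, base_o)))
    expect_equal(d$focal_codon, d0$focal_codon + n_extra)
  }
})

test_that("call_orf_status implements the truncation rule", {
  # helper: alignment with a stop at a given codon of an n-codon ORF
  stop_at <- function(n, k) {
    codons <- c("ATG", rep("GGA", n - 2), "TAA")
    focal <- paste(codons, collapse = "")
    out <- codons; out[k] <- "TAA"
    mk_aln(focal, paste(out, collapse = ""))
  }
  a50 <- stop_at(100, 50)
  c50 <- call_orf_status(a50)
  expect_equal(c50$max_peptide_fraction, 49 / 99)
  expect_equal(c50$status, "absent")

  a85 <- stop_at(100, 85)
  c85 <- call_orf_status(a85)
  expect_equal(c85$max_peptide_fraction, 84 / 99)
  expect_equal(c85$status, "present")

  clean <- call_orf_status(stop_at(100, 50), disablers =
                             detect_disablers(mk_aln("ATGTAA", "ATGTAA")))
  expect_equal(clean$max_peptide_fraction, 1)
  expect_equal(clean$status, "present")

  # stricter threshold
  expect_equal(call_orf_status(a50, max_fraction_threshold = 0.50)$status,
               "absent")                      # 0.495 < 0.50
  a52 <- stop_at(100, 53)                     # longest run 52/99 = 0.525
  expect_equal(call_orf_status(a52, max_fraction_threshold = 0.50)$status,
               "present")
})

test_that("raising the truncation threshold never flips absent to present", {
  set.seed(11)
  tr <- tree3()
  for (i in 1:20) {
    h <- simulate_orf_history(tr, "human", 60, seed = i)
    for (aln in h$alignments[h$outgroups]) {
      prev <- "present"
      for (thr in c(0.3, 0.5, 0.7, 0.9)) {
        st <- call_orf_status(aln, max_fraction_threshold = thr)$status
        if (prev == "absent") expect_equal(st, "absent")
        prev <- st
      }
    }
  }
})

test_that("shared_ancestral_disablers requires same kind at same codon in >= 2 species", {
  call_with <- function(species, kind, codon) {
    structure(list(species = species, status = "absent",
                   max_peptide_fraction = 0.3,
                   disablers = data.frame(kind = kind, focal_codon = codon,
                                          detail = "x")),
              class = "orf_call")
  }
  sh <- shared_ancestral_disablers(list(
    call_with("chimp", "premature_stop", 37L),
    call_with("rhesus", "premature_stop", 37L)))
  expect_equal(nrow(sh), 1L)
  expect_equal(sh$focal_codon, 37L)
  expect_equal(sh$species[[1]], c("chimp", "rhesus"))

  none <- shared_ancestral_disablers(list(
    call_with("chimp", "premature_stop", 37L),
    call_with("rhesus", "frameshift_indel", 37L)))
  expect_equal(nrow(none), 0L)
})

test_that("paralog_screen applies the E-value and align-well gates", {
  hit <- function(e) data.frame(qid = "g", sid = "other", pident = 40,
                                length = 50, mismatch = 30, gapopen = 0,
                                qstart = 1, qend = 50, sstart = 1, send = 50,
                                evalue = e, bitscore = 60)
  r <- paralog_screen(hit(1e-7))
  expect_equal(as.character(r), "fail")
  expect_equal(attr(r, "reason"), "evalue")

  r2 <- paralog_screen(hit(1e-5),
                       self_alignments = data.frame(partner = "p",
                                                    coverage = 0.75,
                                                    identity = 0.55))
  expect_equal(attr(r2, "reason"), "align-well")

  expect_equal(as.character(paralog_screen(hit(1e-5))), "pass")
  expect_equal(as.character(paralog_screen(hit(0)[0, ])), "pass")
  bad <- hit(1e-5); bad$evalue <- "oops"
  expect_warning(res <- paralog_screen(bad), "malformed")
  expect_equal(as.character(res), "pass")
})

test_that("peptide_evidence demands an exact match and a distant runner-up", {
  target <- "MKLVADERTQWPLIS"
  expect_equal(peptide_evidence("ADERTQ", target,
                                c("WWADEKTMWW")), "convincing")    # 2 mm
  expect_equal(peptide_evidence("ADERTQ", target,
                                c("WWADEKTQWW")), "rejected")      # 1 mm
  expect_equal(peptide_evidence("ADERTQ", target, character(0)),
               "convincing")
  expect_equal(peptide_evidence("AAAAAA", target), "rejected")
  expect_error(peptide_evidence("AD", target))
})
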