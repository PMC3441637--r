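Package: orfbirth
Title: Phylogenetic Dating and Comparative Transcriptomics of De Novo
    Gene Origination
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study the birth of protein-coding genes from
    previously non-coding, already-transcribed loci. Implements Dollo
    (single-gain, zero-loss) parsimony dating of loci and open reading
    frames on a species tree; detection of ORF disablers (premature stop
    codons and frame-disrupting indels) in codon-based pairwise
    alignments against out-group species, with reliability, truncation,
    paralog and peptide-evidence filters and a shared-ancestral-disabler
    test that discriminates gene birth from gene loss; RPKM
    quantification over representative exonic regions with an intergenic
    Monte-Carlo background; cross-species tissue-expression profile
    correlation with an ortholog-shuffle permutation null, complete
    linkage clustering and tissue-pair correlation matrices; splice
    junction support classification and splice-site motif summaries;
    pooled Nei-Gojobori dN/dS on concatenated codon alignments; and a
    ground-truthed synthetic data generator so the whole pipeline is
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
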