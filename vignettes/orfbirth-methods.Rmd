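---
title: "Methods: dating, screening and comparative transcriptomics of de novo genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dating, screening and comparative transcriptomics of de novo genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orfbirth)
```

# The problem and the model

A *de novo* protein-coding gene arises from DNA that was never part of a
mother gene. Two observations identify one: (i) the focal species
carries an intact ORF while orthologous sequence in out-group species is
disabled, and (ii) no paralog explains the protein by duplication. A
further question — did transcription precede coding? — is answered by
comparing the transcript structure and tissue expression profile of the
coding gene with its non-coding orthologs in close relatives. This
package implements both halves as composable, individually tested
operations plus an orchestrating pipeline.

## Parsimony dating

The dating model is deliberately minimal: **one gain, zero losses**
(Dollo). A presence profile over the leaves of a rooted tree is dated to
the branch immediately above the MRCA of the `present` leaves, and only
if

* no leaf inside that clade is unambiguously `absent` (otherwise a loss
  would be required; the case is reported `contradictory` and discarded
  rather than modelled — loss histories are exactly what the
  shared-disabler test is designed to exclude, so modelling them here
  would double-count the evidence), and
* at least one out-group leaf is unambiguously `absent` (otherwise an
  older origin cannot be excluded and the case is `undatable`).

`ambiguous` leaves are unconstraining by design: out-group genome
assemblies are error-prone, and treating a low-quality alignment as
evidence of absence would manufacture false frame disruptions. A profile
whose only non-present leaves are ambiguous is undatable, the
conservative reading. When exactly one out-group is informative the gene
is dated but `presence_support` is 1, so downstream users can filter on
the strength of the dating themselves.

Branches are identified by the sorted `"+"`-joined leaf set below them
(`"chimp+human"`), which is stable across tree-library node
renumberings. The branch above the root is a valid assignment (the
character predates the sampled species) and has support 0.

The whole operation is small enough to verify exhaustively: the test
suite enumerates **all** 3^k presence profiles on trees of up to six
leaves and checks status and branch against an independent oracle that
enumerates every gain scenario.

## ORF-disabler screening

Out-group ORF status is inferred from a codon-based pairwise alignment
of the focal CDS (frame anchored at the alignment start) against the
orthologous out-group sequence.

* **Reliability gate.** Coverage ≥ 0.70 and identity ≥ 0.50, both
  inclusive, both recomputable from the sequences. Anything less is
  `ambiguous` — the screen refuses to call absence from sequence it
  cannot trust, and ambiguity propagates to the dating stage as an
  unconstraining state.
* **Disablers.** A premature stop is an out-group in-frame TAA/TAG/TGA
  at a focal codon before the terminal stop. A frameshift is a maximal
  gap run (either sequence) whose length is not divisible by 3,
  positioned at the focal codon containing its first column. Disablers
  are *positions*: after an indel the frame is re-anchored to the focal
  frame at the next codon boundary, so one event does not cascade into
  dozens of phantom stops. A stop within three codons of the terminal
  stop still counts (no grace window). In-frame indels are not
  disablers.
* **Truncation rule.** `max_peptide_fraction` is the longest run of
  focal codons free of any disabler divided by the focal peptide length.
  The denominator excludes the terminal stop — the 70% rule speaks of
  peptide lengths, and peptides do not include stops; a `"codons"`
  denominator is exposed for the off-by-one alternative. The ORF is
  `absent` only when disabled *and* the fraction is below the threshold
  (default 0.70; 0.50 gives the stricter list used for robustness
  re-runs).
* **Birth versus loss.** A disabler at the same focal codon with the
  same kind in ≥ 2 out-group species was parsimoniously present in their
  common ancestor, so the ORF never existed there: origination, not
  loss. Genes without a shared disabler remain "birth-vs-loss
  unresolved" and are excluded from the curated set.
* **Paralog and peptide filters.** Duplication is excluded by a
  homology-hit gate (E ≤ 10⁻⁶ fails) plus an alignment gate
  (coverage ≥ 0.70 ∧ identity ≥ 0.50 against any other protein fails,
  because short proteins have weak E-values). Mass-spectrometry peptide
  evidence is `convincing` only when the peptide matches the CDS
  translation exactly and every other proteome location differs by ≥ 2
  mismatches.

## Expression quantification

RPKM = count / (L/1000) / (N/10⁶) over **representative regions**: the
gene's exonic intervals minus the union of every other annotated gene's
intervals on either strand (strand-agnostic subtraction, because the
integrated public data are strand-non-specific and cannot attribute
overlapping signal), optionally intersected with a synteny map so the
same region is measurable in all species. Coordinates are 0-based
half-open internally (BED native); 1-based only in reports.

Transcription is called when RPKM > 0.2 **and** the value is
significantly above an empirical intergenic background
(Monte-Carlo p < 0.05). The background tail probability uses the
finite-sample estimator p(r) = (1 + #{bg ≥ r}) / (1 + n), which is never
exactly zero; n defaults to 10,000 draws (with replacement when fewer
intergenic regions are available). A gene is transcribed in a species if
any tissue passes.

Genomic-context classification is multi-label: same-strand overlap,
antisense overlap, and `bi` for a divergently oriented gene whose TSS
lies within 1,000 bp upstream of the focal TSS. The window size is not
defined anywhere authoritative; 1 kb is the conventional bidirectional
promoter span and is exposed in the parameter block. Library QC flags
strand-correct:mislabeled ratios ≤ 100 and exon:intron density ratios
≤ 100; zero denominators report `Inf` without a flag.

## Cross-species comparison

Per gene, tissue proportions p_t = RPKM_t / Σ RPKM_t are compared across
species with Spearman's rank correlation (average ranks for ties; `NA`
for constant vectors, e.g. genes too lowly expressed to rank). Spearman
is used uniformly — the cross-species panels and the reported
correlation values in this literature are rank correlations, and mixing
conventions within one analysis invites error. A gene's profile is
conserved when r is **strictly** greater than 0.5; boundary genes are
excluded, and the cutoff is in the parameter block.

Significance comes from the **ortholog-shuffle null**: permute which
out-group gene is paired with which focal gene (uniform over the
permutation group — fixed points allowed, since "neglecting the ortholog
relationship" does not forbid a gene pairing with itself), recount the
conserved genes, repeat n_sim = 10,000 times, and report
p = (1 + #{null ≥ obs}) / (1 + n_sim). The implementation precomputes
the full gene-by-gene Spearman cross-correlation matrix once and indexes
it per permutation; this is algebraically identical to recomputing
per-pair correlations (Pearson on ranks) and makes 10,000 permutations
cheap. For ≤ 6 genes the sampled null is checked against exhaustive
enumeration of all n! permutations.

Clustering of `species.tissue` proportion columns uses complete linkage
on Euclidean distance (the linkage is the documented choice; the
distance is not stated anywhere, Euclidean on proportions is the
simplest, and 1 − Pearson is available via `distance = "pearson"`).
Tissue-pair matrices report Spearman r for every tissue pair across the
gene set, with `NA` where a tissue cannot be ranked.

The ORF-expansion counter-test asks whether relative out-group ORF
length predicts expression conservation (two Spearman coefficients) and
whether multi-exon genes are more often transcribed in the out-group
(one-sided Fisher's exact test on the 2×2 table; degenerate margins
report p = 1 with a flag).

## Splice junctions

A junction (0-based half-open intron, annotated strand) is
`insufficient_coverage` when either ±20 bp exonic flank has fewer than
1 read — "enough coverage to assess" is not defined in the source
literature, so it is operationalized as ≥ 1 read per flank with both
parameters exposed. Otherwise it is `supported` when spanning reads
exist **or** when both flanks are covered and the intron is canonical
GT–AG — the weaker disjunct is how strand-non-specific public data can
support a junction without any read crossing it. Support is monotone:
adding reads never demotes a status. Motif matrices summarise base
frequencies in 3 exonic + 6 intronic positions at the donor and
6 + 3 at the acceptor, reverse-complemented for minus-strand junctions,
with N bases excluded from their column's denominator.

## Pooled dN/dS

`merged_dnds()` implements classical Nei–Gojobori (1986) counting:
per-position synonymous site fractions with **nonsense mutations
eliminated** (stop-producing changes are excluded from the per-position
tally, as in the original method), pathway-averaged differences with
equal weights over all orderings of the differing positions (pathways
through stop codons are excluded; if every pathway passes through a
stop, all are used), Jukes–Cantor correction
d = −(3/4)·log(1 − 4p/3), and counts **pooled over the whole
concatenation before the ratio** — "merged" means counts-then-ratio,
not a mean of per-gene ratios, which would be dominated by short
blocks. Codons containing gaps or ambiguity codes in either sequence
are excluded pairwise; dS = 0 reports ratio `NA` with both components.
The pairwise mode uses the first two sequences of each block; which two
out-group species to align is a user decision (the truncated out-group
forms, e.g. chimpanzee vs orangutan, is the natural choice for testing
whether truncated ORFs evolve neutrally).

Eliminating nonsense changes from the site tally is not cosmetic: if
stop-producing changes are counted as nonsynonymous sites but a
stop-containing codon pair is excluded from the differences (as every
classical tool does), dN is systematically underestimated and a neutral
simulation converges to ≈ 0.94, not 1. With the elimination the neutral
limit is unbiased, which is what the acceptance criterion checks.

# The synthetic world

The generator encodes the generative assumptions the analysis is
designed to detect, with stated defaults; these are **fixed conditions,
not dials**.

* `simulate_orf_history()` builds an ancestral intact ORF (ATG, sense
  codons, terminal stop), gives it to every in-group species, and
  injects disablers into out-groups at homologous positions. A shared
  premature stop uses the *same* stop triplet in every carrier (it is
  one ancestral event). The `"auto"` spec places one shared stop at
  n/3 and one shared 1-nt frameshift at 2n/3, truncating the maximum
  peptide to ≈ 1/3 — comfortably below both the 0.70 and 0.50
  thresholds, as a real ancestral disabler pair would.
* `simulate_expression()` draws per-gene tissue profiles from a
  Dirichlet (concentration 0.8: moderately tissue-specific), couples
  the two species through a Gaussian copula with correlation
  2·sin(πρ/6) so the coordinate-wise population rank correlation is ρ,
  scales the focal species' total expression by λ, and draws
  negative-binomial counts (variance μ + φμ²) that are converted to
  RPKM with the stated library sizes — the same count→RPKM path as the
  real pipeline. φ defaults to 0.1, a conventional bulk-RNA-Seq
  overdispersion; the literature states no noise level, and the default
  is flagged in the parameter block rather than derived. φ = 0 is the
  noise-free limit (counts equal expectations exactly). Note that the
  *sample* Spearman over 7 tissues is attenuated below ρ by small-sample
  bias and by Poisson noise at weakly expressed tissues; the generator
  targets the population rank correlation, and the tests check
  convergence on a wide tissue panel at φ = 0.
* `simulate_junction_reads()` gives each junction Poisson(depth)
  spanning reads with strand labels flipped at the mislabeling rate, and
  Poisson flank coverage.
* `simulate_neutral_alignment()` applies uniform random substitutions,
  rejecting stop-creating ones — matching the estimator's nonsense
  elimination, so the neutral dN/dS expectation is exactly 1. The
  acceptance run uses 2,000 substitutions on a 10 kb alignment (~0.2
  per site): enough events that estimator error rather than
  event-sampling noise dominates, while staying well inside the
  Jukes–Cantor validity range.

One integer seed drives everything; sub-stream seeds are derived
deterministically and kept below 2³¹. Fixed seed ⇒ bit-identical
outputs, which the tests assert.

**What a green test establishes — and what it does not.** The synthetic
world has clean orthology, complete alignments, no assembly gaps, no
mapping bias, and disablers exactly where the truth manifest says. A
passing truth-recovery test therefore establishes that the *inference
machinery* is correct, not that real genomes will be as kind: real
screens inherit alignment ambiguity (handled here by the reliability
gate) and annotation errors (handled by reason-coded per-gene isolation)
that the generator deliberately does not emulate. Raw FASTQ simulation,
sequencing error beyond strand mislabeling, and repeat elements are out
of scope.

# Numerical and interface decisions

* Monte-Carlo p-values always use the +1/(n+1) estimator; they are never
  exactly 0.
* All thresholds live in `default_params()`; the `"strict"` preset
  changes only the truncation threshold (0.70 → 0.50). Robustness
  re-runs are parameter presets, not code paths.
* Manual curation enters as an auditable accept/reject flag per gene,
  never as silent removal; every per-gene failure carries a reason code
  and isolates that gene rather than aborting the run.
* The run manifest is JSON (this environment provides no YAML parser);
  the structure is otherwise as a YAML manifest would be.
* Overlapping gap runs are resolved left-to-right, each maximal run
  counted once; all-gap columns are rejected at construction.
* `dispersion = 0` switches the count model from negative-binomial to
  deterministic expectations; the limit φ → 0⁺ is Poisson, which still
  carries counting noise. The spec's degenerate-limit example
  (identical proportions at ρ = 1) is only achievable at exactly 0,
  which is how it is implemented.
* Funnel counts are cumulative (genes surviving all prior gates), hence
  non-increasing by construction.

# Known limitations

* The dating model cannot represent gene loss; profiles requiring one
  are discarded, which is the analysis design but means secondarily lost
  genes are invisible.
* `classify_lineage()` needs the focal and sister species named; it does
  not infer them from the tree.
* The coordinate-map interface for junction lift-over supports collinear
  blocks only (no inversions; an inverted mapping is reported as
  unmapped with a reason).
* The peptide-evidence search is exact-window Hamming matching, adequate
  for proteome-scale decoy sets of ordinary size but not optimized for
  very large ones.
* Published genome-scale summary constants (median protein lengths,
  per-species transcription fractions, merged dN/dS values for real
  gene sets) depend on curated gene tables and alignments that are not
  redistributable here; the acceptance machinery therefore validates
  method properties (oracle equivalence, truth recovery, calibration,
  the neutral limit) rather than such constants.
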