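---
title: "Identifying natural antisense transcripts: models, thresholds and design choices"
author: "natseek"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying natural antisense transcripts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(natseek)
```

## The problem

A natural antisense transcript (NAT) is an RNA transcribed from the strand
opposite a protein-coding gene, its sense transcript (ST). A *cis*-NAT arises
at the same genomic locus as its ST, so the overlap is perfectly reverse
complementary; a *trans*-NAT arises at a remote locus and is only partially
complementary. Given a genome, stranded gene models (GFF3) and stranded
assembled transcripts (GTF), `natseek` produces a catalog of cis- and
trans-NATs and the downstream statistics used to characterize them:
configuration and relationship typing, stage-presence partitioning,
expression correlation, and functional-category enrichment. Read mapping and
transcript assembly are upstream of this package, and the external
similarity/coding-potential searches (protein database, coding-potential
scoring, housekeeping-ncRNA and small-RNA databases) are consumed as
two-column TSV evidence tables rather than executed.

## Containers and coordinates

The package is organized around Bioconductor containers: transcript models
are a named `GRangesList` of exons inside a `TranscriptSet` (with a
`predicted_gene` / `assembled` origin per model), units are a `GRanges` with
member lists, sequences are `DNAStringSet`, and result catalogs are `DFrame`
subclasses. Coordinates follow the GRanges convention (1-based, closed);
GFF3/GTF conversion happens entirely inside `rtracklayer`, which removes the
usual off-by-one risks at the format boundary. Within spliced sequences,
offsets are 1-based and read 5'→3' on each transcript's own strand.
Unstranded (`.`) features are rejected at input — every downstream rule is
strand-specific, so guessing a strand would poison the catalog.
The nucleotide alphabet is uppercase ACGTN and `N` never base-pairs: an `N`
column counts as a mismatch in both the complementarity search and the
duplex alignment.

## Transcript units

Genes and transcripts on the same scaffold and strand merge into a
*transcript unit* when their spans share at least one base, transitively.
Two choices matter here:

* **Spans, not exon chains.** A transcript overlapping only the intron of a
  gene still marks the same locus, so clustering uses the transcript span
  (first to last exon). Exon-aware overlap is easy to express on the same
  containers but is deliberately not the default.
* **Abutting is not overlapping.** `[1, 100]` and `[101, 200]` share no base
  and stay separate (`reduce(min.gapwidth = 0)`); a 1-bp overlap merges.
  No minimum-overlap threshold is imposed beyond that single shared base.

Unit ids are assigned in (scaffold, start, strand) order, so a given input
always yields the same ids.

## cis-NAT admission and configuration

A (gene, opposite-strand unit) pair is admitted when the overlap is at least
10 % of the length of *either* side. The wording "either" is read as the
weaker condition (at least one side); the stricter both-sides reading is one
switch away (`overlap_rule = "both"`), and the pipeline reports show that
`both` catalogs are always subsets of `any` catalogs. Units that contain a
predicted gene are ST-side loci and never NAT candidates; admission is
decided at unit level, after which pairs are expanded to the unit's member
transcripts, which are what the filter cascade, the expression analyses and
the final catalog operate on.

Configuration typing checks containment first (`S_contains_N`, then
`N_contains_S`; two identical spans are called `S_contains_N`), then lets the
overlapped end of the ST decide: its 5' end means *divergent* (head-to-head),
its 3' end *convergent* (tail-to-tail). For two partially overlapping
intervals exactly one ST end is covered, so the four classes are exhaustive
and mutually exclusive, and the call is invariant under mirroring the locus.

## trans-NAT detection

The published procedure delimits complementary regions with BLASTN and
verifies duplex formation with a thermodynamic folding server. Both external
tools are replaced by deterministic, testable equivalents that preserve the
printed decision rules:

* **Complementarity search** (`findComplementaryRegions`): exact 12-mer seeds
  of one sequence against the reverse complement of the other, grouped by
  diagonal; maximal exact runs ≥ 12 nt form cores, which extend across
  *single* mismatches while the region identity stays ≥ 0.8 (configurable;
  the floor is not stated by the published procedure and 0.8 is chosen
  permissive). Regions are gap-free by construction, matching the
  "continuous complementary region" wording; whether the original BLASTN hits
  tolerated gaps is unstated, and the gap-free reading is implemented.
* **Duplex annealing** (`annealDuplex`): a local alignment (match +1,
  mismatch −1, gap opening −2, gap extension −0.5 via
  `Biostrings::pairwiseAlignment`) of the seed region's ±150-nt
  neighborhoods. The annealed region is the maximal-scoring block; a *bubble*
  is a maximal interior run of non-paired columns (terminal overhangs are not
  bubbles); the pair passes when the block overlaps the seed region on both
  sequences and no bubble exceeds 10 % of the block length, bubbles included.
  Free energy is out of scope — the folding step is used only to delimit the
  annealed region and measure bubbles, which the alignment reproduces.

A pair must be *remote*: different transcript units and zero genomic span
overlap (strand ignored). No minimum genomic distance is imposed — the
published description gives none — but the overlap test makes cis loci
ineligible by construction. The three criteria are then: region longer than
100 nt; region longer than 50 % of at least one of the two sequences (same
"either" reading and switch as above); and the bubble rule. Raising the
length threshold never adds pairs and raising the bubble cap never removes
them, which the suite checks as monotonicity properties.

## The five-step non-coding cascade

Boundary semantics are exact, tested, and worth stating because the source
wording is contradictory in two places:

| step | keep iff | boundary |
|------|----------|----------|
| length | length > 200 nt | exactly 200 fails |
| ORF | longest ORF ≤ 100 aa | exactly 100 passes |
| protein hit | no hit with e ≤ 1e-3 | a hit at exactly 1e-3 removes |
| coding potential | score < 0 | exactly 0 fails |
| ncRNA hit | no hit with e ≤ 1e-10 | a hit at exactly 1e-10 removes |

The methods description removes ORFs "of more than 100 amino acids" while the
results text says "< 100 aa"; the methods reading (≤ 100 keeps) is
implemented. For coding potential the two wordings ("scores > 0 removed"
vs "score < 0" keeps) disagree at exactly zero; the stricter keep-requires-
negative reading is implemented. Hits at exactly an e-value cutoff disqualify
(tie behavior is unstated; "e ≤ cutoff disqualifies" is documented here).
Evaluation stops at the first failing step, so each record's trail shows
`NA` for steps never reached, and the funnel report counts survivors per
step, per kind and combined.

ORF scanning is 3-frame on the transcript's own strand — coding potential is
read 5'→3' — with ATG-only starts and the standard genetic code
(`both_strands = TRUE` gives a 6-frame scan). A missing evidence table makes
its step pass vacuously with a warning; `strict = TRUE` turns that into an
error for production runs.

## Expression statistics

RPKM uses the standard scaling `1e9 * count / (library_size * length)`; the
presence cutoff "RPKM value of 2" is read inclusively (≥ 2). The Venn
partition is defined for exactly three stages (mycelia, primordia, fruiting
bodies in the motivating study); its seven exclusive regions always sum to
the number of transcripts expressed anywhere.

Profile normalization follows the two published conventions: `log2(x + 1)`
then division by the profile mean (cross-technology comparisons) or by the
maximum (relative stage profiles). The log base and pseudocount are not
stated in the source; base 2 with +1 is the transcriptomics default and only
rescales profiles, leaving correlation signs untouched.

Correlation significance uses `t = r / sqrt((1 - r^2) / (N - 2))` with
`N − 2` degrees of freedom and a *directional* p-value (one tail in the
direction of the observed r), so r = 0 gives p = 0.5; a two-sided option is
available and cross-checked against `cor.test`. Whether the published
correlations used N = 3 stage means or N = 9 replicate points is not
recoverable from the text, so N is always an explicit property of the data
passed in, never assumed. Perfect correlations are reported as `t = ±Inf`,
`p = 0` rather than NaN, and zero-variance profiles are an explicit error
(or `NA` rows in the batch interface `correlatePairs`).

## Enrichment

For each functional category the upper-tail hypergeometric probability
P(X ≥ x) is computed by log-space summation of `lchoose` terms
(tails below 1e-300 stay finite; the suite checks agreement with exact
rational enumeration at small populations and with the library tail
elsewhere). The tail is inclusive: "observing more STs" is read as the
standard ≥ x tail, with the exclusive tail one flag away. The number of
draws N defaults to *all* STs, annotated or not, matching the printed
definition of N; FDR correction (Benjamini–Hochberg, via `p.adjust`) runs
over all tested categories, and the "at least 4 mapped STs" rule is applied
afterwards as a reporting filter — the published order of those two steps is
unstated, and correcting first is the conservative choice. Which FDR
procedure the source used is also unstated; BH is implemented.

## Synthetic study conditions

`generateFixture()` emits a three-scaffold genome (uniform ACGT, GC 0.5 by
default, with a GC knob so planted classes stay comparable) with every
pipeline stage's truth planted:

* all four cis configurations with NATs (250–700 nt) shorter than their STs
  (800–1500 nt), so overlap fractions are larger on the NAT side, as
  observed in real catalogs;
* the multiplex motifs — one ST with two embedded NATs (1:n), one NAT
  bridging two genes (n:1), and two overlapping genes with two NATs crossing
  both (n:n);
* remote trans pairs as a 200-nt reverse-complement of a gene window embedded
  in a 260-nt transcript on another scaffold (region 200 > 100 nt; coverage
  77 % > 50 %; clean duplex);
* one decoy per criterion, each violating exactly that criterion by a stated
  margin: 5 % overlap (vs 10 %), 150 nt length (vs > 200), a planted 150-aa
  ORF (vs ≤ 100), protein e-value 1e-5 (vs 1e-3), coding score +1.5 (vs
  < 0), housekeeping 1e-12 and small-RNA 1e-15 (vs 1e-10), a 90-nt
  complement (vs > 100), a 120-nt/20 % coverage complement (vs > 50 %), and
  a split complement whose duplex carries a 40-column bubble in a 280-column
  block (14.3 % vs ≤ 10 %). The bubble decoy cannot put the bubble inside
  the seed region — a gap would split the "continuous" region below the
  length threshold — so it pairs a clean 160-nt region (53 % of the
  transcript) with a 40-nt insert and an 80-nt continuation that the local
  alignment bridges;
* a three-stage RPKM matrix cycling the final NATs through all seven Venn
  regions, with planted positive/negative ST–NAT profile pairs (monotone
  profiles with 5 % lognormal jitter, comfortably above the presence cutoff);
* an annotation map whose first category is deliberately over-drawn from the
  STs-with-NATs.

Every planted transcript sequence is rejection-sampled until it carries no
ORF over 100 aa, so the ORF filter is exercised *only* by its decoy. All
randomness flows from one integer seed and the bundle is byte-identical
across runs. Trans complements are embedded in spliced transcript sequence
(not intron sequence) because the trans module operates on spliced
sequences.

What the generator does *not* emulate: read-level noise and coverage gaps
(transcripts are exact intervals), GC heterogeneity along scaffolds,
paralogy beyond the planted n:n block, and expression noise beyond lognormal
jitter. Passing the planted-truth suite therefore demonstrates that the
decision rules are implemented exactly, not that the pipeline is robust to
assembler fragmentation or quantification error — on real data those enter
through the inputs.

## Problem sizes and budgets

The default ("full") fixture holds ~60 genes and ~45 transcripts over three
scaffolds (~100 kb), sized so a complete generate-and-run cycle takes well
under a minute and the whole validation suite (brute-force oracle
equivalences up to 1000 intervals, a 1000-draw null calibration of the
enrichment test, 1000-pair correlation recovery) runs in a few minutes on
one CPU. The "smoke" preset halves the planted counts for interactive use.
The enrichment calibration checks the empirical rate of p < 0.05 under a
random null against the *exact* achieved level of the discrete inclusive
tail (slightly below the nominal 0.05), rather than against 0.05 itself —
the honest comparison for a discrete test.

## Known limitations

* Overlap and clustering are span-based; exon-chain overlap is not the
  default anywhere.
* The complementarity search bridges only single mismatches between exact
  runs; two adjacent mismatches end a region even when the identity floor
  would tolerate them. This is deliberate — the seed definition is a
  *continuous* complementary region — but it makes the 0.8 identity floor
  conservative.
* The duplex model is score-based, not thermodynamic: it reproduces
  region/bubble geometry, not melting energies.
* Enrichment treats annotations as given; no ontology-graph propagation.
* The three-stage Venn partition does not generalize to other stage counts
  by design (an error, not a silent reinterpretation).
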