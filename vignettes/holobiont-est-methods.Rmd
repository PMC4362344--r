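---
title: "Methods: holobiont EST partitioning and c-type lectin domain mining"
author: "HolobiontEST package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: holobiont EST partitioning and c-type lectin domain mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HolobiontEST)
```

## The problem

An EST (expressed sequence tag) survey of an uncultured planktonic
holobiont — a rhizarian host cell together with its photosymbiotic algae
and associated bacteria — produces a mixed bag of assembled unigenes:
host transcripts, symbiont transcripts, bacterial messages, ribosomal
RNA from everything in and around the cell, and bystander organisms.
HolobiontEST implements the standard desk-scale analysis of such a
survey: cleaning, rRNA/mRNA partitioning, taxonomic accounting,
cross-sample protein-level clustering, GC profiling, and — the bespoke
part — detection, deduplication and phylogenetic placement of c-type
lectin domains (CTLDs), carbohydrate-binding domains implicated in
host/symbiont recognition in several marine photosymbioses.

Every stage is driven by, and verified against, a synthetic holobiont
EST generator with complete per-read and per-domain ground truth, so the
whole pipeline is testable without any sequencing archive.

## Cleaning

`lengthFilter()` removes unigenes shorter than 200 bp (a sequence of
exactly 200 bp is kept). `trimPolyA()` strips poly-A tails — and their
reverse-strand appearance, leading poly-T heads — using an anchored
rule: a terminal run of at least `min_run` (default 10) nt qualifies
when it begins and ends with the run base and contains at most one
other base per 10 nt of run. The anchor prevents the mismatch budget
from consuming the transcript base adjacent to the tail, and the rule is
applied to a fixed point, which makes trimming idempotent. The exact
heuristic used by classical EST cleaning tools is not published; this
parameterisation is our own and is documented here rather than inferred.

## rRNA/mRNA partition

A unigene is called ribosomal when at least one of its similarity hits
(i) carries one of 13 ribosomal keywords in its subject description
(5.8S, 16S, 18S, 23S, 26S, 28S, ITS, rRNA, rDNA, ribosomal DNA,
ribosomal RNA, LSU, SSU), (ii) has identity strictly above 80%, and
(iii) an alignment length strictly above 100 bp. Everything else —
including unigenes with no hits — is treated as putative mRNA.

The keyword matcher is a design decision of this package: `ITS`, `LSU`
and `SSU` match case-sensitively as whole tokens (delimited by
non-alphanumerics) so that "its" or "sites" never fire; the other
phrases match as literal, case-insensitive substrings. Descriptions
like "60S ribosomal protein L3" do not match because bare "ribosomal"
is not in the list. Thresholds are strict (`>`) following the wording
of the rule; inclusive variants are available via
`partitionRule(strict = FALSE)`.

## Built-in similarity search

External BLAST searches are replaced by a built-in aligner suitable for
desk-scale reference sets. `smithWaterman()` is an affine-gap local
aligner (a gap of length $L$ costs $g_o + L\,g_e$); defaults are
match/mismatch $+2/-3$ with gaps $5/2$ for nucleotides and BLOSUM62
with gaps $10/1$ for proteins. In translated ("tblastn-like") mode the
six reading frames of each query are split at stop codons into ORF
segments of at least 20 aa before searching, so alignments never cross
a stop; the frame is recorded in the hit. E-values are not computed —
pipeline decisions use identity, length and raw score thresholds, and
the desk-scale reference sets do not support meaningful Karlin–Altschul
statistics.

Two conventions make downstream results well defined:

* **Deterministic identity.** Global-alignment identity (used by
  clustering and domain dedup) is defined as the *lexicographic
  optimum*: among all score-optimal alignments, the one with the most
  identical columns. This makes the reported match count a function of
  the sequences alone, with no traceback-tie ambiguity, and lets an
  independent brute-force oracle reproduce it exactly.
* **Deterministic ties.** Equal-scoring hits are ordered by subject
  identifier, so search output is invariant under reference ordering.

The kernels are compiled (Rcpp); a score-only linear-memory pass gates
the full traceback alignment, which is only computed for pairs reaching
the score threshold.

## Taxonomic assignment

`lcaAssign()` performs lowest-common-ancestor binning in the style of
classic metagenomic binning tools: hits scoring at least `min_score`
(default 50 protein / 40 nucleotide) vote if they lie within
`top_percent` (default 10%) of the best bitscore, and the unigene is
assigned to the LCA of the voting taxa. A unigene with no hits is
reported as "No hits"; one whose hits all fall below the score floor as
"Not assigned". These parameter values are declared defaults — the
binning tool the analysis emulates does not publish a single canonical
setting — and are configurable.

Count tables (`buildTaxonCountTable()`) report per-(sample, fraction)
unigene counts with reserved "No hits"/"Not assigned"/"Total" rows.
Percentage formatting follows the presentation convention of published
taxonomic tables: values of at least 1% round to the nearest integer
(half away from zero), smaller values to one decimal; raw floats remain
available (`formatted = FALSE`).

## Cross-sample clustering

`clusterSixFrames()` translates every mRNA unigene in all six frames
and clusters the frame peptides greedily with CD-HIT semantics:
sequences are visited by decreasing length (ties by identifier) and
join the first cluster whose representative aligns at $\ge$ 50%
identity, the identity denominator being the shorter sequence. Because
the analysis counts *unigenes*, frame-level clusters are then collapsed
to unigene level: clusters sharing any unigene are merged (connected
components), so each unigene lies in exactly one cluster. Venn-style
subset counts (`vennCounts()`) assign each cluster to the exact set of
samples present in it. There is no k-mer prefilter by default
(exactness over speed); `kmer_filter = 5` enables one for larger
inputs, and the pipeline driver uses it.

## CTLD mining

The operational domain definition (`ctldGrammar()`) is: four conserved
cysteines whose consecutive spacings lie in [5, 60], [20, 90] and
[5, 40] residues; a WIGL-like 4-mer (W, then I/L/V, then G, then
I/L/V/F) strictly between the first and third cysteine; and a
sugar-binding motif position between the second and fourth cysteine.
The cysteine spacings are not published anywhere as exact numbers; the
defaults were chosen once to admit compact CTLD architectures while
rejecting random cysteine scatter, and all synthetic-data tests plant
domains compatible with them, so results do not hinge on the exact
bounds. When a window holds more than four cysteines the scanner
accepts the lexicographically first 4-subset satisfying all constraints
(leftmost-compact), for determinism. A window may not contain a stop
codon. Scanning continues after each accepted window, so multi-domain
transcripts are split into their domains.

`classifySugar()` searches the inter-cysteine-2/4 region for EPN
(glucose/mannose binding), then LND (galactose binding). Otherwise the
3-mer occupying the *reference motif column* is reported with class
"variant": the domain is globally aligned to a packaged synthetic
anchor CTLD whose EPN position is known, and the anchor's motif columns
are mapped through the alignment. This anchored localization is a
declared decision; it presumes the domain is homologous enough to the
anchor for the alignment to be meaningful, which holds for
grammar-positive domains seeded by the reference search.

`dedupeDomains()` collapses near-duplicates greedily at 97% identity
(longest member kept). The threshold is a declared default: published
reductions of redundant domain sets do not state their collapse
criterion.

## Phylogeny

`progressiveAlign()` is a deterministic progressive aligner: pairwise
global identities give distances, average-linkage clustering fixes the
merge order, and profiles are merged by profile–profile dynamic
programming under BLOSUM62. `curateBlocks()` reduces classic
alignment-curation behaviour to three parameters (maximum per-column
gap fraction, default 0; minimum modal-residue fraction, default 0.5;
minimum block length, default 10 columns). Distances are p-distances
over shared ungapped columns, optionally Poisson-corrected
($-\ln(1-p)$). `njTree()` is standard neighbor joining (via ape), which
provably recovers the generating topology from any additive matrix;
negative branch lengths are clamped to zero and flagged. Maximum
likelihood inference is deliberately out of scope: the phylogenetic
claims the pipeline verifies are topological (per-sample domains form
clades), and NJ on curated distances supports exactly that. Branch
support, when wanted, comes from a seeded nonparametric bootstrap
(`njBootstrap()`, default 100 column resamples) rather than approximate
likelihood-ratio tests.

## The synthetic generator

`simulateHolobiont()` emulates the statistical structure the analysis
assumes, with complete ground truth:

* **Read lengths**: truncated normal, mean 350, sd 90, min 150, max
  1200 bp — the scale of a 454 EST survey (per-sample averages in such
  surveys run ≈ 337–369 bp), with a deliberate tail below the 200 bp
  filter so cleaning is exercised.
* **rRNA reads** (fraction `rrna_fraction`, default 5%): mutated
  windows of packaged *synthetic* rRNA references whose description
  lines carry the ribosomal keywords and a taxon label.
* **mRNA reads**: mutated windows of per-(sample, taxon) reference
  genes generated at the taxon's GC target (defaults: host 0.46,
  photosymbiont 0.55, bacterium 0.40, bystander 0.50); eukaryotic
  transcripts receive a 10–30 nt poly-A tail and every read has random
  strand orientation. Default mutation rate 0.02 substitutions/site.
* **Shared orthologs**: optional full-length transcript families
  present in every sample, for cross-sample clustering tests.
* **Planted CTLDs**: each of `n_planted_ctld` transcripts founds a
  distinct domain family; `n_redundant_copies` near-copies (exactly one
  amino-acid substitution, i.e. within-family identity ≥ 0.97) are
  planted on multi-domain transcripts and extra single-domain
  transcripts. Families derive from a per-sample base template
  (35% of free positions redrawn from the packaged anchor) by redrawing
  25% of free positions again — chosen once so that within-family
  identity exceeds the dedup threshold, between-family identity stays
  below 0.8, and within-sample domains are mutually closer than
  cross-sample domains (the clade property). Flanks, linkers and
  negative-control transcripts contain no cysteine or tryptophan
  codons, so planted coordinates are recovered exactly and negatives
  cannot satisfy the grammar.
* **Determinism**: one RNG stream per (seed, sample), so adding a
  sample never perturbs another; fixed seeds give byte-identical
  output files. Reverse translation uses a fixed codon table.

Truth coordinates for planted domains refer to the six-frame
translation of the *trimmed* read — the sequence the pipeline actually
translates; tails are constructed so trimming is exact.

What the generator does *not* emulate: 454 homopolymer errors, chimeric
reads, quality scores, assembly artefacts, and realistic codon usage or
secondary structure. Passing tests therefore demonstrate the
correctness of the pipeline's logic and arithmetic on data with the
assumed structure, not robustness to every artefact of real 454
libraries.

## Problem sizes and numerical choices

The test-suite and acceptance runs use simulations of 30–60 background
reads per sample (plus planted transcripts), 3 reference genes per
(sample, taxon) of 900 bp, and domain families of 101 aa. These sizes
were chosen as the smallest at which every property under test is
non-trivially exercised — partition and LCA see every taxon, clustering
sees shared and private families, and the NJ tree has enough leaves per
sample for clade checks. The larger law-of-large-numbers checks (GC
recovery, 4000 reads) run once.

Other numerical conventions: score comparisons in the DP kernels use an
absolute tolerance of 1e-9 (all inputs are integer-valued, so scores
are exact); the identity denominator is always the shorter sequence;
hit and cluster ties break lexicographically; `percentOfTotal` rounds
half away from zero. Degenerate inputs are defined behaviour: an empty
mRNA fraction skips clustering, CTLD and phylogeny stages gracefully;
fewer than three unique domains skips the tree; an alignment with no
surviving curated columns warns and returns an empty alignment.

## Known limitations

* The built-in search is exhaustive (no heuristic seeding) and suits
  reference sets of tens of sequences, not nr/nt-scale databases.
* LCA accuracy depends on reference coverage; with single-taxon
  references and mutation rates ≤ 0.05 assignment is essentially
  perfect, which real surveys of undersampled lineages are not.
* The anchored sugar-motif localization reports a 3-mer only as
  accurately as the domain aligns to the anchor.
* GO/KEGG annotation, SILVA screening and assembly are out of scope.
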