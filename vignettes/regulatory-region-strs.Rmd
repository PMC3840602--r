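---
title: "Short tandem repeats in TSS regulatory regions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Short tandem repeats in TSS regulatory regions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Short tandem repeats (STRs, microsatellites) are tandemly repeated DNA
motifs with a unit length ("period") of 1–9 bp. They mutate by expansion
and contraction orders of magnitude faster than surrounding sequence, and
when they sit in the regulatory region around a transcription start site
(TSS) they can change chromatin structure, nucleosome positioning and
transcription-factor access — and hence gene expression. This package
builds a gene-by-gene catalogue of high-purity STRs in the window 2 kb
upstream to 1 kb downstream of each canonical TSS, profiles their density
and composition relative to the TSS, and asks which functional gene sets
are over-represented among STR-carrying genes.

## Repeat model and reporting thresholds

A repeat tract is summarised by its genomic span (0-based half-open),
period, copy number, consensus motif, purity (percent of tract positions
matching the best tiling of the consensus, no indels), base composition,
entropy and an alignment score. The score model is per-base: each
consensus-matching base contributes `match_weight` (default 2) and each
mismatch deducts `mismatch_penalty` (default 7, the Tandem Repeat Finder
convention). A repeat is reportable when its score reaches `min_score`
(default 50), so the shortest reportable pure tract is
`ceiling(50 / 2) = 25` bp. Catalogue membership additionally requires
period ≤ 9 and purity ≥ 90%.

Two rounding conventions coexist in the tabular output, both matching the
upstream table dialect: base-composition percentages are truncated to
integers (so A+C+G+T sums to 97–100), while purity and copy number round
half-up (purity to the nearest integer, copy number to one decimal).
Entropy is stored at full precision.

## Detection

The built-in detector is substitution-only. For each period p it computes
the autocorrelation indicator `m[i] = (s[i] == s[i-p])`; an exact match
run of at least `seed_len` (default `max(12, 2p)`) opens a candidate,
which absorbs neighbouring runs while no mismatch run exceeds `max_gap`
(default p) and is then trimmed at both ends to the span maximising
`2·matches − 7·mismatches` (the first period of a span counts as
matching). Consensus motifs come from a per-column majority vote with
alphabetical tie-breaks; non-primitive consensus calls (e.g. "ACAC") are
collapsed to their primitive period before overlap resolution, which
keeps the higher score, then the smaller period, then the leftmost record
among calls sharing at least half of the shorter span. `N` bases break
matches and never count toward composition.

Because the detector is indel-free, its optimal span is exactly
computable: the test suite checks every reported score against a
brute-force enumeration of all spans. Records with score < 50 or purity
below the detector floor (80%, deliberately below the catalogue filter so
the purity filter is observable downstream) are dropped. Repeats with
indels (`perIndel > 0`) can enter the pipeline only through ingestion of
a precomputed repeats table.

## TSS-relative annotation

Gene models are genePred-like (0-based half-open). Haplotype and
unplaced contigs are excluded by the underscore naming convention. One
transcript per locus is kept: an explicit canonical list wins when
supplied, otherwise the longest genomic span with a lexicographic
identifier tie-break — deterministic and order-invariant. Loci are
grouped by gene symbol, a documented proxy for curated locus identifiers.

The regulatory window is strand-aware: `[txStart−2000, txStart+1000)` on
the plus strand, `[txEnd−1000, txEnd+2000)` on the minus strand, clamped
at chromosome edges rather than dropped. TxPos, the TSS-relative start of
a repeat in transcript orientation, is `srStart − txStart` (plus) or
`txEnd − srEnd` (minus); negative values are upstream.

Two membership rules are used and never mixed: catalogue rows require
*full containment* of the repeat in the window, while compartment subsets
(upstream [−2000, −1], proximal promoter [−250, +250], core promoter
[−60, +40], exon/intron/5′-UTR) use *any overlap* of at least 1 bp. The
5′-UTR is exon-aware: exonic bases strictly between the TSS and the CDS
start in transcript orientation.

## Profiling

Each catalogue row adds one count to every TxPos position it covers, so
the summed profile conserves total repeat bases; density divides by the
number of regions profiled (raw counts are retained as well, since a
per-region or raw normalisation are both defensible). Profiles are
decomposed by period and split by whether the region overlaps a CpG
island. Composition and copy-number profiles take the unweighted mean of
the covering rows' repeat-level percentages; uncovered positions are
missing, not zero, to avoid dragging composition curves toward zero.

Curves are smoothed by LOWESS (tricube-weighted local linear regression,
span 0.1 of the grid by default). Robustness iterations are available but
default to 0: coverage profiles are spiky by nature, and robust
reweighting treats genuine peaks as outliers — on the default synthetic
fixture three robust iterations deflate the density mean by roughly a
fifth, whereas the plain fit preserves it to well under 1%. Smoothed
values at the two boundary windows are one-sided and slightly biased;
tests therefore assert exactness of linear trends away from the grid
edges.

## Gene sets and over-representation

Four comparison sets are built. The catalogue set contains unique loci
with at least one table row. The exonic set contains genes with at least
one repeat overlapping an exon, with *no* purity filter. The intronic
high-density set ranks genes by kb of intron per high-purity intronic
repeat (total intron width / number of qualifying repeats; smaller =
denser) and keeps the highest-density quartile — values at or below the
25th percentile by linear interpolation, boundary ties included. Finally,
ten random gene samples of the catalogue-set size are drawn without
replacement from the intronic pool, reproducibly from a seed.

Over-representation of a term is tested with the hypergeometric upper
tail `P(X ≥ k)` and fold enrichment `(k/n)/(K/N)`; p-values are adjusted
per term collection with the Benjamini–Hochberg step-up, written out
explicitly and cross-checked against `stats::p.adjust` in the tests. For
the random samples, a term is reported only when significant
(FDR < 0.05) in at least 6 of the 10 samples. The background defaults to
all canonical genes on primary contigs and is configurable, since any
external tool's background universe is not reproducible here; no
minimum-count filter is applied.

## The synthetic study system

`simulate_genome()` produces a genome with known truth so every stage is
testable without downloads: i.i.d. background sequence at a configurable
GC fraction (default 0.4), 100 genes by default on both strands of two
0.8 Mb chromosomes, each with 2–5 exons and (90% of the time) a CDS, and
CpG islands written over half of the TSS windows. Repeats are planted per
a configurable specification; the default emulates the structure reported
for human promoters: AT-rich dinucleotides spread over the upstream
region, GC-rich trinucleotides concentrated near the TSS of CpG-island
genes (truncated normal, sd 150 bp), a genome-wide mixed-period
background dominated by mono- and dinucleotides, and a small group of
sub-25 bp tracts that the score filter must drop.

Planting is substitution-only, matching the detector's model, so truth
`perIndel` is always 0. Substitutions are placed at distinct interior
positions until the realised purity is within ±2 points of target, and
two further guards keep truth unambiguous: substitutions are kept clear
of tract ends and mutually spaced so that the score-optimal span is
exactly the planted span, and impure tracts intended to be detectable are
lengthened until their substitution load still clears the minimum score
with margin. The second guard is forced by arithmetic: at weights 2/7 a
tract at purity 96 must be ≥ 34 bp before it can score 50 at all, and
purity below ~89% can never accumulate a positive score regardless of
length. Tract flanks are locally adjusted so background sequence cannot
extend the optimal span — without this, roughly a quarter of planted
tracts would gain a one-base extension by chance. Planted tracts keep
100 bp clearance from each other and from exon boundaries; chance
background repeats are left in place, so recovery tests measure recall on
truth positions rather than global precision.

What the simulation does *not* emulate: CpG dinucleotide chains and
isochore structure, indel-containing repeats, overlapping transcript
isoforms, and realistic promoter sequence composition. Passing recovery
tests therefore demonstrate the pipeline arithmetic and filters, not
detector performance on real genomes, where indels and compositional
heterogeneity matter.

An optional term specification attaches random gene sets as annotation
terms and biases window-repeat placement toward the first term's genes
with a configurable sampling weight, which lets the over-representation
stage be power-checked against a known enriched term.

## Problem sizes and determinism

The default study fixture is seed 1, 100 genes, ~520 planted repeats on
1.6 Mb — chosen so a full simulate–detect–build–profile cycle and the
enrichment power check (100 replicates of a fold-3 planted term over a
1000-gene background) complete comfortably on a single core. Every
stochastic step (simulation, sampling, random gene sets) is reproducible
from explicit seeds, and the pipeline restores the caller's RNG state.

## Known limitations

* The detector has no indel model; TRF-style probabilistic detection and
  wraparound alignment are out of scope, and indel-bearing records are
  supported only via table ingestion.
* Locus grouping by gene symbol can merge distinct loci sharing a symbol
  in poorly curated annotations.
* Identifier columns beyond the RefSeq id and symbol are pass-through
  from an optional mapping file; no cross-database joining is attempted.
* The enrichment stage assumes the user-supplied term map's gene
  identifiers match the gene table's symbols.
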