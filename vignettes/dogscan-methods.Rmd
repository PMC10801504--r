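---
title: "Detecting downstream-of-gene readthrough transcripts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting downstream-of-gene readthrough transcripts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dogscan)
```

## The problem

Under several kinds of cellular stress — osmotic shock, heat shock, viral
infection, and pharmacological inhibition of RNA polymerase II transcription
(e.g. by the TFIIH inhibitors triptolide and THZ1) — termination at the
polyadenylation site fails for a subset of genes and polymerase keeps
elongating for kilobases past the annotated 3' end.  The resulting
chromatin-associated long noncoding RNAs are called downstream-of-gene (DoG)
transcripts.  In RNA-seq coverage a DoG appears as a contiguous block of
signal continuing past a gene's transcription end site (TES).

dogscan detects these regions from per-base coverage, validates them with
RNAP II ChIP-seq promoter peaks, quantifies them between two conditions, and
compares DoG sets across conditions or cell lines.

## DoG discovery

For each annotated gene the caller walks consecutive, non-overlapping
windows of `window_bp` (default 500 bp) starting at the TES and moving in
the gene's 3' direction.  A window keeps the extension alive when its FPKM —
`(summed depth / read length)` normalised by window length and library size
— is at least `min_fpkm` (default 0.2).  The first failing window terminates
the extension (`max_gap_windows` can relax this; the default of 0 is the
simplest rule consistent with windowed readthrough scanners in this field).
A DoG is reported when the extended region reaches `min_length_bp` (default
4000, *inclusive*: studies that count DoGs "between 4000 and 5000 nt" imply
that 4000 itself is attainable).  The reported `mean_fpkm` is the FPKM of
the whole emitted region; the per-window threshold governs extension only.

Because the last passing window is included in full, DoG lengths are
multiples of the window size unless a downstream gene truncates them.

### Blocking by downstream genes

Coverage downstream of a gene stops being interpretable as readthrough once
it reaches another gene's transcription start: from there on, signal may
simply be that gene's own transcription.  Extension therefore cannot cross
the *TSS-side boundary* of any other gene — its start for a `+` gene, its
end for a `-` gene — and the window that would cross it is evaluated as a
partial window up to the boundary (so truncated DoGs need not be window
multiples).  In unstranded mode (the default; the motivating datasets are
single-end and non-stranded) genes on either strand block; in stranded mode
only same-strand genes do.

A consequence worth spelling out: an *opposite-strand* gene's TSS-side
boundary is its far edge, so a called DoG can legitimately run across that
gene's body.  This is exactly the false-positive mode of non-stranded data —
antisense downstream transcription masquerading as readthrough — and it is
the job of the ChIP-seq filters, not the caller, to remove it.

Extension is also capped at the recorded coverage extent of the chromosome:
beyond the last covered base there is no evidence either way, and the cap
keeps the scan finite even at `min_fpkm = 0`.

### Eligibility

With `expressed_only = TRUE` a gene is scanned only when its gene-body FPKM
reaches `min_fpkm`.  Readthrough is only meaningful for transcriptionally
active genes; no separate expression cutoff is introduced, the discovery
threshold is reused.

## ChIP-seq filters

Promoter-proximally paused RNAP II produces a ChIP-seq peak 20–120 nt past
the TSS of most active genes.  Two filters exploit this:

* **Downstream interference.** A DoG is discarded iff its region overlaps
  (≥ 1 bp) a gene other than its parent *and* contains (≥ 1 bp) an RNAP II
  peak — the conjunctive reading: the signal is then better explained by an
  active downstream gene.  A stricter `peak_only` mode discards on any
  interior peak; both variants are preserved because the published
  descriptions of this filter differ in whether the covered gene is
  required.
* **Promoter peak.** A DoG is kept iff a peak overlaps
  `[tss − w, tss + w)` of its parent, `w = promoter_window_bp` (default
  500 bp).  The pausing signal itself sits within ~120 nt; the ±500 bp
  default tolerates peak-caller summit spread.

Overlap semantics are ≥ 1 bp everywhere — no fractional-overlap thresholds,
since none are established for this use.  Both filters are per-DoG
predicates independent of the rest of the set, hence contractive,
idempotent, and order-independent; the test suite asserts all three.

## Differential expression

Region counts are estimated as summed per-base depth divided by read length,
rounded.  Normalisation is median-of-ratios (the standard size-factor
construction; the unit tests cross-check it against
`DESeq2::estimateSizeFactorsForMatrix` to 1e-12), with a library-size
fallback when no region is nonzero in all samples.

The test is a negative-binomial Wald test defined by this package (exact
replication of external DE tools is a non-goal):

* `log2fc = log2((mean treated + c) / (mean control + c))` on normalised
  counts, pseudocount `c = 1` keeping estimates finite;
* per-region dispersion by method of moments on *within-condition*
  residuals (`var = mu + alpha mu^2` per condition, averaged), truncated at
  zero, then moderated toward the across-region mean dispersion and floored
  at 0.01;
* Wald statistic `log2fc / SE` with the SE delta-propagated from the NB
  variance of each condition mean; two-sided normal tail.

Two numerical choices deserve justification.  First, dispersion must be
estimated within conditions: a cross-condition moment estimate folds the
treatment effect itself into the variance, making the test severely
conservative under the null and powerless at real effects.  Second, with two
replicates per condition a raw per-region estimate has one degree of freedom
per condition; using it directly makes the Wald test anticonservative.
Full moderation toward the common dispersion (the default, `moderation = 1`)
calibrates the test on a planted NB null — the suite and the acceptance
script both compute the type-I error and assert/report it against the
[0.03, 0.08] band — at the cost of
assuming dispersions are exchangeable across regions, reasonable for the
homogeneous region sets produced here.  Note the accuracy of any per-run
fold-change estimate is bounded by sampling noise
(`sd ≈ sqrt(2·alpha / n_rep) / ln 2`, about 0.32 at dispersion 0.05 with two
replicates); the calibration suite therefore checks that the *mean*
recovered log2FC over repeated simulations sits on the planted value, and
that significance is essentially always reached at a planted 4-fold change.

Significance defaults to raw `p ≤ 0.05` (inclusive), matching how DoG
counts at a p-value cutoff are conventionally reported; Benjamini–Hochberg
adjustment is available as an option.

## Comparison and correlation

DoG set identity is by gene identifier, not by interval: merged annotations
differ in exact 3' ends far more than in gene membership, and published DoG
set comparisons are id-based.  `merge_replicates()` unions per-gene calls,
keeping the farthest downstream end.  `gene_dog_correlation()` joins
gene-body and DoG differential results by parent gene, keeps pairs with
`p ≤ 0.05` on both sides, computes the Pearson product-moment correlation
(two-sided t-distributed p-value, via `cor.test`), and classifies each gene
by gene-body log2FC with inclusive boundaries at ±1.2 — the threshold and
inclusivity used in the figure legends this analysis style comes from.
Class percentages are reported to one decimal, so they sum to 100 ± 0.2.

## The synthetic-data generator

Real DoG studies start from GEO-deposited BAMs; the generator replaces them
with fully self-contained datasets whose truth is known before any caller
runs.  It emulates:

* genes of 2–6 kb with log-uniform expression of 1–20 FPKM on a single
  linear chromosome, gaps of 6–12 kb (enlarged automatically so planted DoG
  spans never collide);
* planted readthrough extensions of 4–10 kb (rounded to the 500-bp window
  resolution so planted and called lengths are directly comparable), at
  coverage `dog_to_gene_coverage_ratio` (default 0.5) of the parent gene
  body;
* two conditions × two replicates, with the control condition given fewer
  readthrough genes than the treated one and a configurable shared
  fraction — the structure seen when comparing drug-treated and vehicle
  conditions;
* expected depth = FPKM × (read length/1000) × (library size/10^6), with
  per-base Poisson noise per replicate and a log-normal per-replicate depth
  scaling (σ = 0.05 by default) that produces negative-binomial
  overdispersion at the count level — noise at coverage level is kept
  Poisson because that is sufficient to exercise the caller, while
  replicate scaling is what the NB test actually has to absorb;
* promoter peaks (300 bp, centred on the TSS) for a configurable fraction
  of expressed genes;
* interfering downstream genes: for a fraction of treated readthrough
  genes, an opposite-strand gene with its own expression and promoter peak
  is placed at the distal end of the planted DoG span.  The parent's call
  then covers it (see the blocking rule above) and must be removed by
  Filter 1.  The truth table also records the interfering gene's *own*
  apparent call — unstranded coverage runs from its TSS back across the
  parent — and whether Filter 1 will remove it (it does iff the parent has
  a promoter peak inside that span).  With zero noise these expectations
  are exact, and the filter tests assert set equality against them.

All randomness flows from a single seed (`with_local_seed` restores the
caller's RNG state), so a fixed seed gives byte-identical output files.

What the generator does *not* emulate: splicing, fragment-length structure,
mappability variation, multi-chromosome genomes, GC bias, or annotation
error.  Passing tests on this data therefore demonstrate algorithmic
correctness — boundary-exact calling, exact filter semantics, calibrated
testing — not robustness to every artefact of real libraries.

## Problem sizes and degenerate inputs

The shipped test suite and the acceptance script use 8–100-gene genomes
(0.1–2 Mb), 200 randomized caller-versus-oracle instances, null calibrations
of 1000–5000 regions and 200-run effect recoveries: sizes chosen so the full
pipeline graph is exercised end-to-end in minutes on one CPU while leaving
every statistical check well-powered.

Degenerate inputs are defined rather than left to chance: empty annotation
or coverage gives empty (not failing) results; a gene with no downstream
space yields no DoG; an empty peak set discards every DoG in the promoter
filter (with a warning) since promoter evidence is then vacuous; fewer than
three significant gene/DoG pairs makes the correlation an error rather than
a meaningless number; bedGraph intervals that overlap, negative depths, and
malformed GTF rows are rejected loudly with positions.

## Known limitations

* FPKM-based window thresholds inherit FPKM's library-size sensitivity;
  comparisons of raw DoG counts across datasets of very different depth are
  confounded (deeper sequencing finds more DoGs), as the studies this
  replicates also note.
* The Wald test with full dispersion moderation assumes exchangeable
  dispersions; strongly heterogeneous regions would call for per-region
  shrinkage instead.
* Unstranded mode cannot attribute antisense signal; the ChIP-seq filters
  mitigate but cannot fully resolve this.
* Gene-level annotation spans (unions over transcripts) are used throughout;
  transcript-level 3' end choice is out of scope.
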