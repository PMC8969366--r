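---
title: "Benchmarking gene-annotation choice in RNA-seq quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking gene-annotation choice in RNA-seq quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annobench)
library(dplyr)
```

## The problem

Gene-level RNA-seq quantification counts mapped fragments (read pairs) to
genes, and a gene can only be counted if an annotation defines its exons.
Ensembl and RefSeq annotations disagree substantially: tens of thousands of
genes are unique to one database, and even shared genes differ in their
exon-union ("effective") lengths, sometimes by more than an order of
magnitude. Those disagreements propagate into counts, CPM/FPKM values and
every downstream analysis. `annobench` implements a benchmark for measuring
that propagation: it quantifies annotation discrepancy directly, counts
fragments under each annotation with identical (featureCounts-style)
semantics, normalizes the resulting matrices identically, and then scores
quantification accuracy against two kinds of ground truth — the titration
design of SEQC-style mixture samples and external measurements (RT-PCR-like
and microarray-like truth tables).

## The mixture design and the titration statistic

The benchmark's built-in truth follows the SEQC design: two reference RNA
samples A and B, and two mixtures C and D prepared at 3:1 and 1:3 ratios of
A to B. Sixteen libraries (four replicates per sample) are quantified. On
the linear scale, a gene with concentration $a$ in A and $b$ in B must have
concentration $0.75a + 0.25b$ in C and $0.25a + 0.75b$ in D, so its
expression must be ordered $A \ge C \ge D \ge B$ (or the reverse), and the
expected C-vs-D log2 fold change given the A-vs-B log2 fold change $x$ is

$$E(x) \;=\; \log_2\!\frac{3\cdot 2^{x}+1}{2^{x}+3},$$

an odd, increasing curve with asymptotes $\pm\log_2 3$. `assess_titration()`
computes per-gene observed fold changes from replicate-mean log2 expression,
compares them against $E(x)$, and summarizes agreement as a mean squared
error together with the fraction of genes whose expression is monotonically
ordered. A smaller MSE means the quantification preserved the physical
mixing truth better. Fold changes are differences of replicate-averaged
log2 expression (averaging on the log scale, the same scale on which the
values are reported); linear-scale averaging can be obtained by passing a
linear-scale matrix, but the standard pipeline works in log space
throughout.

## Counting semantics

`count_library()` reproduces featureCounts-style gene-level assignment: a
fragment is assigned to a gene if any of its aligned blocks overlaps any
exon of the gene by at least one base, unstranded; fragments overlapping
exons of two or more genes are "ambiguous" and counted to nothing;
fragments overlapping no exon are "no feature". Multi-mapping fragments are
resolved *before* assignment: if exactly one candidate location lies in a
gene's exon it is chosen; if several do, the first in canonical order among
them; if none does, the first in canonical order overall. Because the
aligner's internal index order is unavailable, canonical order is defined
deterministically as: chromosome order of the annotation file, then start
coordinate, then input order. Multi-mappers are also classified
(`multi_gene` / `within_one_gene` / `no_exon`) for reporting, since only
the `multi_gene` class can create assignment ambiguity.

Ambiguous fragments are never counted (featureCounts' default). Library
sizes used downstream default to the per-library *assigned* totals (the
count-matrix column sums); the total *input* fragment count is available as
an alternative denominator via `library_sizes(x, type = "input")`, and both
denominators appear in the assignment-statistics report.

## Normalization

Counts are converted with the voom transform
$\log_2\!\big((c + 0.5)/(L\,f + 1)\times 10^6\big)$, where $L$ is the
library size and $f$ a normalization factor. The prior count of 0.5 avoids
log of zero; the +1 library-size offset matches voom exactly (verified
against `limma::voom` in the tests). Three normalization modes are
supported, mirroring common practice: plain library size ($f = 1$), TMM
(factors from `edgeR::calcNormFactors`, i.e. the published trimmed mean of
M-values with upper-quartile reference selection, 30%/5% trimming and
inverse-variance weights), and quantile (applied by
`limma::normalizeQuantiles` to the log2CPM matrix, with ties receiving the
mean of the rank means they span — the same behaviour voom's
`normalize.method = "quantile"` produces). log2FPKM is obtained by
subtracting $\log_2(\text{effective length}/1000)$.

The expression filter retains a gene iff its CPM (prior 0, raw library
sizes, computed before any normalization) is at least 0.5 in at least 4
libraries; both bounds are inclusive. Normalization factors deliberately do
not enter the filter.

## What the synthetic generator emulates

Real SEQC libraries and genome-scale annotations are too large (and
unlicensed) to ship; `generate_bundle()` creates a desk-scale bundle with
the statistical structure every stage assumes. Its defaults are fixed study
conditions, not tuning knobs:

* **Design**: 4 samples x 4 replicates, C and D as 3:1 / 1:3 mixtures;
  depth 2 x 10^6 fragments per library over 2000 genes per annotation
  (about 1000 fragments per gene, comparable to ~20M fragments over ~25k
  expressed genes in SEQC libraries).
* **Expression**: baseline log2 abundance ~ Normal(0, 2) across genes and
  A-vs-B log2 fold changes ~ Normal(0, 2) — the brain-reference vs
  universal-reference contrast is of this magnitude. Total abundance is
  equalized between A and B, matching the titration assumption that mixing
  acts on comparable mRNA pools. Ten percent of genes are "silent"
  (annotated but essentially untranscribed, ~13 log2 units below baseline)
  so the 0.5 CPM filter is a live step.
* **Noise**: counts are negative binomial with Var = mu + phi mu^2,
  phi = 0.01 by default (technical-replicate scale). Draws are
  quantile-coupled — one uniform per (gene, library), transformed through
  the NB quantile function — so sweeps over phi at a fixed seed are
  comparable pair by pair. phi = 0 degenerates to rounded expectations
  rather than Poisson, which makes exact-recovery tests possible. At
  phi = 0 every library is produced at *exactly* the configured depth: one
  designated high-abundance sink gene (a fixed 8:1 A:B ratio, ~3% of the
  library) absorbs the integer-rounding residual of each column. Without
  this, column sums differ by a few counts in 10^6, which is enough to
  flip the non-strict monotonicity ordering for genes whose A and B
  abundances tie, and exact monotonicity recovery would be an accident of
  rounding rather than a property.
* **Annotations**: 2–3 annotations drawn over a shared gene universe with
  configurable all-shared / pairwise-shared / unique fractions; shared
  genes receive per-annotation exon-length divergence factors
  2^Normal(0, 0.25) (capped at ±2 log2); a configured fraction of gene
  pairs is placed with identical starts so their first exons overlap,
  creating genuine assignment ambiguity. Identifier maps (pairwise and to
  a shared symbol namespace) are exact ground truth.
* **Truth tables**: an RT-PCR-like table (unique gene rows, stored on the
  linear scale and log2-transformed on read) and a microarray-like table
  with 1–3 probes per gene. Truth values are the generator's true
  expression on the per-kilobase (FPKM-like) scale — normalized by each
  gene's baseline exonic length — plus Gaussian log2 noise (sigma = 0.25
  by default). The best probe of each microarray gene measures the truth
  exactly and extra probes are attenuated, so representative-probe
  selection (highest mean across samples, lexicographic tie-break) is
  exercised and sigma = 0 recovery is exact.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: mappability structure (multi-mapper candidates
are placed in intergenic deserts, not homologous exons), fragment-level GC
or length biases, mRNA-fraction differences between reference samples that
distort real titration, annotation errors that correlate with sequence
features, and probe cross-hybridization. The benchmark validates the
*machinery*; conclusions about real annotations require real libraries.

## Numerical choices and degenerate inputs

* Coordinates are GTF 1-based inclusive on disk and 0-based half-open
  internally; all outputs use the internal convention except written GTFs.
* `collapse_exons()` merges book-ended exons ([a,b) + [b,c) becomes
  [a,c)): effective length is unchanged and the representation becomes
  canonical.
* Strand is stored but ignored in all overlap and length computations
  (SEQC-style libraries are unstranded).
* Transcriptome size is the per-gene sum of effective lengths; bases shared
  by overlapping genes count once per gene. A genomic-union variant would
  be smaller; the per-gene sum is what "sum of effective gene lengths"
  denotes here.
* Three-way Venn membership requires the three pairwise one-to-one matches
  to agree transitively; non-transitive triples are demoted to a pairwise
  region and counted in the report, since identifier maps in the wild are
  not guaranteed to compose.
* Quantile-normalization ties use the mean of spanned rank means
  (`ties = TRUE`), boxplot statistics use type-7 (linear interpolation)
  quantiles, and Pearson correlations require at least 3 matched genes and
  report `NA` with a warning under zero variance.
* Empty inputs degrade explicitly: an empty GTF yields an empty annotation
  with a warning; an empty fragment stream yields a zero count column with
  zeroed tallies.

## Problem sizes

The test suite and the acceptance script run the full pipeline at the
default 2000-gene, 16-library scale (the dispersion sweep re-generates
counts three times), with module-level property checks on smaller random
toys (up to 10^3 fragments by 10^2 genes against the brute-force counting
oracle, 20 replicates). These sizes keep every brute-force oracle exact and
the whole suite comfortably fast while preserving the study's structure;
they are stated here so results can be reproduced at the same scale.

## Session info

```{r}
sessionInfo()
```
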