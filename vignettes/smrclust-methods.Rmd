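---
title: "Annotation-free small RNA cluster calling with smrclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotation-free small RNA cluster calling with smrclust}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smrclust)
```

## The problem

Reference-based small RNA quantification counts reads only where an
annotation says a gene is. Small RNA libraries — particularly from
extracellular vesicles — contain abundant, reproducible read accumulations
outside annotated features. `smrclust` inverts the workflow: it defines
expressed loci from the data (gap-based read clustering), characterizes
them, and treats annotation as a label applied afterwards, so unannotated
loci survive into the count matrix on equal footing.

## Pipeline and model

The stages are: adapter trimming → external alignment (bowtie-class,
reporting all sites) → multimap rescue → cluster calling → metrics →
annotation → quantification. The package implements everything except the
alignment itself, which it consumes as SAM/BAM.

### Trimming

`trim_read()` reproduces the preparation of SMARTer-style small RNA
libraries: an unconditional 3-base 5' head trim (template-switching triad),
removal of the leftover 3' poly-A (oligo-dT) adapter `AAAAAAAAAA` and
everything 3' of it, and a 15 nt minimum length. Adapter matching follows
standard 3'-adapter trimmer semantics at defaults: candidate occurrences may
be internal or partially overlap the read's 3' end; an occurrence of overlap
$L$ with $m$ mismatches is valid when $m \le \lfloor 0.1\,L \rfloor$ and
$L \ge 3$; among valid occurrences the one with the most matching bases wins
(ties: fewer mismatches, then leftmost, which trims more). `N` never
matches. The best-match rule matters: with a homopolymer adapter,
leftmost-valid matching would accept a 9/10 occurrence starting one base
before a perfect occurrence and eat one genuine base. A consequence users
should expect: a genomic A-run immediately 5' of the adapter is
indistinguishable from adapter and is trimmed with it.

### Multimap rescue

Reads reported at more than `max_sites` (default 15, the cap used at
alignment) are discarded. A retained multi-mapped read is split across its
sites proportionally to the mean unique-read depth over each site footprint,
with a uniform $1/k$ fallback when no site has unique support. This is a
single informed pass, not an EM: no iteration, no feedback of rescued weight
into the reference distribution, which keeps the result deterministic and
order-independent. The mean over the footprint (rather than a point depth)
is robust to 1 bp jitter in small RNA read stacks; `rescue_window` can widen
the averaging window. Weights per read sum to 1 exactly, so total read mass
is conserved.

### Cluster calling

Sorted weighted reads are clustered by single-linkage gap closure: a read
joins the open cluster when the gap between the cluster's running maximum
end and the read start is `< min_gap` (default 75 bp, the typical trimmed
read length); overlapping and book-ended reads always join. Clusters with
summed weight `< min_reads` (default 100, the threshold for a positive
detection of RNA amplification) are dropped — never re-assigned. This
construction is equivalent to sliding a 75 bp window over read positions,
and guarantees every reported pair of clusters is separated by at least
`min_gap`. Thresholding on *weighted* counts is the default (rescued
multimappers count fractionally); `count_mode = "reads"` counts sites once
for comparison. Cluster lengths are reported, never clipped.

Two multi-sample modes exist. The default pools all samples' reads to define
one shared locus set — one "average" de novo landscape with a single count
matrix. `per_sample = TRUE` calls per sample and unions overlapping
intervals; pooled-mode clusters always cover the merged per-sample set, but
the two differ when a locus is sub-threshold in every sample yet
supra-threshold jointly. Clustering is unstranded by default — nothing in
the locus definition refers to strand, and small RNA stacks from
strand-sensitive kits are usually strand-pure anyway — with `stranded =
TRUE` available.

### Metrics

*Complexity* is the Shannon entropy of the weighted read **start**
distribution normalized by $\ln(\text{span})$:
$C = -\sum_b p_b \ln p_b / \ln L \in [0, 1]$. Start positions (not per-base
depth) are used deliberately: a single read stack then scores exactly 0 and
length-1 reads tiling every base score exactly 1, pinning both endpoints of
the definition; depth-based entropy cannot score a single read as 0. The
base of the logarithm cancels. Spans of 1 bp are defined as 0.

*Peak* statistics are depth-based: the peak is the base of maximal weighted
depth (leftmost on ties); peak coverage sums the weights of reads covering
that base; peak fraction divides by the cluster total, so a cluster whose
every read covers the modal base scores exactly 1.

The *consensus* is computed over the peak-supporting reads only (the peak is
the reproducible core of a locus; the cluster tails may be heterogeneous),
column-wise weighted majority with ties broken A < C < G < T and
zero-coverage columns emitted as `N`. Alignments are assumed ungapped, the
regime produced by short-read aligners in mismatch-only mode on 15–75 nt
reads.

All metrics are invariant under uniform rescaling of member weights.

### Annotation and quantification

A cluster is `annotated` on any ≥ 1 bp overlap with a gene feature — the
most permissive rule, chosen because no overlap fraction is part of the
locus definition; `overlap_fraction` is reported so users can re-threshold.
The biotype comes from the largest-overlap gene, with exact ties resolved by
a fixed priority favoring small RNA classes (miRNA > snoRNA > snRNA > rRNA >
tRNA > lincRNA > protein_coding > pseudogenes > other): miRNA genes commonly
nest inside host genes, and in a small RNA assay the small RNA label is the
informative one. Introns are derived as gene minus exons.

Quantification assigns each read to the cluster of greatest overlap (ties:
leftmost), never fractionally — counts stay interpretable and column sums
never exceed library sizes. CPM uses total retained weighted reads as the
library size; log2-CPM uses the voom-style offset
$\log_2\!\big((c + 0.5)/(N + 1) \cdot 10^6\big)$ with the pseudo-count
recorded in the output. The expression filter keeps a locus when at least
one sample (within one phenotype group, when groups are given) exceeds
CPM 10. TMM normalization and differential expression are deliberately not
reimplemented: the exported counts + library sizes are the exact layout
edgeR/limma-voom ingest.

## The simulator, and what passing tests do and do not show

`sim_config()`/`simulate_genome()`/`simulate_reads()` generate a uniform
random genome (GC 0.5), plant clusters with three shapes — `point` (all
reads share a start: complexity 0, peak fraction 1 by construction),
`uniform` (deterministic even tiling: complexity analytically
$\ln S/\ln L$ for $S$ distinct starts over span $L$), `gaussian`
(diffuse, $\sigma$ default 10 bp) — duplicate footprints verbatim at decoy
loci to create genuine multi-mapping with correct `NH` tags, and scatter
isolated background reads. Defaults mirror the assay regime: 22 nt reads
(miRNA-like, configurable 15–75), cluster read counts freely configurable
across the 1–10,000 range observed in practice, per-sample library-size
multipliers, substitution error rate 0 by default.

The simulator writes final alignment records directly; no aligner runs in
the test loop (an optional FASTQ emission exercises the trimming stage).
Consequently the tests validate the method's logic under its own model of
the data: clean footprints, exact `NH` tags, no soft-clipping, no ligation
or sequence-composition bias, strand-pure loci. Recovery of planted truth
(precision = recall = 1 for well-separated supra-threshold clusters;
complexity within ±0.02 of the planted analytic value) demonstrates
correctness of the implementation, not performance on real libraries, where
adapter chemistry, repeat structure and aligner behavior add noise the
simulator does not model.

Problem sizes used throughout the suite — a 2 × 100 kb genome, 3–4 planted
clusters of 150–2000 reads, two samples, 100-instance randomized oracle
comparisons of ≤ 500 reads — are desk-scale choices that exercise every code
path while keeping the whole suite under two minutes.

## Numerical and degenerate-case choices

* Gap arithmetic is integer; "gap" is the count of bases strictly between
  footprints, so book-ended reads (gap 0) always join and the minimal
  separating gap equals `min_gap` exactly.
* Complexity of a 1 bp span or single distinct start is 0 by definition
  (no entropy, no normalizer).
* Peak ties break leftmost; consensus base ties break A < C < G < T; read
  assignment ties break to the leftmost cluster — all fixed, making every
  output byte-deterministic for identical inputs.
* Rescue weights: sites of a multimapped read with zero unique depth receive
  weight 0 when any sibling site has support (the read mass goes where the
  evidence is), and $1/k$ only when no site has support.
* Wilcoxon comparisons on constant pooled values return p = 1 with a
  `degenerate` flag rather than an error; Spearman correlations of constant
  profiles return `NA` with a flag.
* Malformed FASTQ records and malformed GTF lines are skipped with counted
  warnings; CIGARs containing reference-skip or padding operators are
  skipped likewise (spliced alignments are out of scope for small RNA).
* `max_sites` defaults to 15, matching the alignment cap of the intended
  upstream aligner invocation; a stricter cap of 10 is sometimes used for
  gene-level quantification and is available as a parameter.

## Known limitations

* No sub-cluster peak deconvolution: a bimodal locus closer than `min_gap`
  is one cluster (of intermediate complexity), by design.
* Rescue is unique-read-informed only; loci with *no* unique anchors
  anywhere (perfect repeat families) are split uniformly, which can dilute a
  genuinely single-origin signal.
* The annotation step labels, it does not resolve: a cluster overlapping
  two genes gets one biotype (largest overlap), with the full overlap table
  available for finer work.
* Microbiome/contaminant filtering is an upstream concern: the package
  accepts pre-filtered alignments and documents the hook, it does not filter.
* Consensus assumes ungapped alignments; indel-containing records contribute
  match columns only.
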