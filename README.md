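# smrclust

Annotation-free discovery and quantification of small RNA read clusters
(smRCs) from aligned small RNA-seq data.

Most small RNA-seq pipelines quantify reads against a reference annotation,
so transcriptional signal arising outside annotated features — a substantial
fraction of the output of cells and especially of extracellular vesicles —
is silently discarded. `smrclust` takes the opposite, data-driven route: it
calls read accumulation loci directly from the alignments, characterizes
them, and only afterwards asks whether each locus happens to overlap a known
gene. It is aimed at transcriptomics researchers working with small RNA
libraries (cells, tissue, biofluids, extracellular vesicles) who want a
count matrix over *all* expressed loci, annotated or not, ready for
limma/edgeR/DESeq2-style downstream statistics.

## Method

Reads are adapter-trimmed (5' head trim, 3' homopolymer adapter, minimum
length 15 nt) and aligned externally; the package consumes the resulting
SAM/BAM, keeping up to 15 alignment sites per read. Multi-mapped reads are
redistributed in a single pass: a read reported at sites *i = 1..k* receives
weight

    w_i = u_i / Σ_j u_j        (uniform 1/k when all u_j = 0)

where *u_i* is the mean uniquely-mapping read depth over site *i*'s
footprint. Weighted reads are then clustered along each chromosome:
a read joins the open cluster while the gap to the cluster's running maximum
end is < 75 bp; clusters with summed weight < 100 reads are dropped. Each
surviving cluster (a "small read cluster", smRC, also called a UGR —
un-annotated genomic region — when it escapes annotation) is characterized
by:

* **complexity** — Shannon entropy of the weighted read-start distribution
  normalized by ln(cluster span): 0 for a single read stack, 1 for uniform
  tiling;
* **peak coverage / fraction** — weighted reads covering the maximal-depth
  base, absolute and as a fraction of the cluster total;
* **consensus** — weighted per-column majority sequence over the
  peak-supporting reads.

Clusters are labeled with the biotype of the largest-overlap gene from a
GTF gene model (`unannotated` otherwise), and every sample is quantified
against the unified cluster set by greatest-overlap read assignment,
yielding a counts TSV plus library sizes for CPM/RPKM normalization, a
CPM > 10 expression filter, rank-based group comparisons (Wilcoxon,
Benjamini–Hochberg) and Spearman profile correlations.

A seeded simulator plants clusters of known shape (point stacks, uniform
tiling, gaussian), duplicated decoy loci for genuine multi-mapping, and
sub-threshold background reads, and emits coordinate-sorted SAM plus a truth
table, so the whole pipeline is testable without any external data.

## Worked example

```r
library(smrclust)

clusters <- data.frame(
  chrom = c("chr1", "chr1", "chr2"),
  start = c(10001L, 30001L, 20001L),
  end   = c(10400L, 30400L, 20400L),
  n_reads = c(500L, 500L, 200L),
  shape = c("point", "uniform", "gaussian"),
  multimap_copies = c(1L, 1L, 2L))
cfg <- sim_config(7, clusters = clusters, samples = c(s1 = 1, s2 = 2),
                  background_reads = 30L)
g   <- simulate_genome(cfg)
sim <- simulate_reads(cfg, g, out_dir = "sim")

res <- run_pipeline(sim$sam_paths, out_dir = "run1")
res$clusters[, c("ugr_id", "weighted_count", "complexity", "peak_fraction")]
```

```
      seqnames      ranges strand |           ugr_id weighted_count complexity peak_fraction
  [1]     chr1 10001-10022      * | chr1:10001-10022           1500   0.000000     1.0000000
  [2]     chr1 30001-30400      * | chr1:30001-30400           1500   0.987363     0.0733333
  [3]     chr2 20085-20241      * | chr2:20085-20241            601   0.736394     0.7138103
```

The point-shaped stack scores complexity 0 with every read in its peak; the
uniformly tiled locus approaches complexity 1 with a flat profile; the
gaussian locus sits in between. The duplicated chr2 locus is recovered at
its true position with its full weighted count (601 ≈ 200 + 2 × 200): the
decoy copies receive no unique coverage, so rescue concentrates the
multi-mapped weight at the anchored locus. `res$counts` is the
cluster-by-sample matrix (`s1` 500/500/200, `s2` 1000/1000/401) with library
sizes attached.

A thin command-line front end is installed at
`system.file("scripts", "smrclust", package = "smrclust")` with subcommands
`trim`, `call`, `run`, `simulate`.

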