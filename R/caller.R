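#' Call small RNA read clusters (smRCs)
#'
#' Gap-based single-linkage clustering of weighted reads. A read joins the
#' open cluster when the gap between the cluster's running maximum end and the
#' read's start is smaller than \code{min_gap}; overlapping or book-ended
#' reads always join. Clusters whose summed read weight falls below
#' \code{min_reads} are discarded. The defaults (75 bp minimum inter-cluster
#' distance, 100 reads) reflect the typical trimmed small RNA read length and
#' the minimum coverage at which an accumulation locus is treated as a
#' positive detection of RNA amplification.
#'
#' This sliding construction is equivalent to a moving window of width
#' \code{min_gap} passed over read positions: any two surviving clusters on
#' the same chromosome (and strand, in stranded mode) are separated by at
#' least \code{min_gap} bp.
#'
#' @param reads \code{GRanges} of weighted reads (a \code{weight} column;
#'   missing weights default to 1). Need not be pre-sorted.
#' @param min_gap Minimum distance in bp between distinct clusters
#'   (default 75).
#' @param min_reads Minimum weighted read count per reported cluster
#'   (default 100).
#' @param stranded Cluster each strand independently (default \code{FALSE}).
#' @param count_mode \code{"weighted"} (default) thresholds on summed weights;
#'   \code{"reads"} counts each retained read site once.
#'
#' @return \code{GRanges} of clusters, coordinate-sorted, with metadata
#'   columns \code{ugr_id} (\code{chrom:start-end}, 1-based inclusive),
#'   \code{weighted_count}, \code{n_reads}. Strand is \code{*} unless
#'   \code{stranded}.
#' @export
call_clusters <- function(reads, min_gap = 75L, min_reads = 100,
                          stranded = FALSE, count_mode = c("weighted", "reads")) {
  stopifnot(min_gap >= 1L, min_reads >= 1)
  count_mode <- match.arg(count_mode)
  if (length(reads) == 0L) return(empty_clusters())
  if (is.null(reads$weight)) reads$weight <- rep(1, length(reads))
  if (!stranded) GenomicRanges::strand(reads) <- "*"
  reads <- GenomicRanges::sort(reads, ignore.strand = !stranded)

  key <- if (stranded) {
    paste(GenomicRanges::seqnames(reads), GenomicRanges::strand(reads))
  } else {
    as.character(GenomicRanges::seqnames(reads))
  }
  pieces <- lapply(split(seq_along(reads), key), function(idx) {
    cluster_one_group(reads[idx], min_gap, min_reads, count_mode, stranded)
  })
  out <- do.call(c, unname(pieces))
  if (is.null(out) || length(out) == 0L) return(empty_clusters())
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

# Streaming pass over start-sorted reads of one chromosome(/strand).
cluster_one_group <- function(reads, min_gap, min_reads, count_mode, stranded) {
  st <- GenomicRanges::start(reads)
  en <- GenomicRanges::end(reads)
  o <- order(st, en)
  st <- st[o]; en <- en[o]
  wt <- reads$weight[o]

  n <- length(st)
  cl <- integer(n)
  cur <- 1L
  cl[1] <- 1L
  max_end <- en[1]
  for (i in seq_len(n)[-1]) {
    gap <- st[i] - max_end - 1L   # bp strictly between footprints
    if (gap < min_gap) {
      cl[i] <- cur
      if (en[i] > max_end) max_end <- en[i]
    } else {
      cur <- cur + 1L
      cl[i] <- cur
      max_end <- en[i]
    }
  }
  f <- factor(cl, levels = seq_len(cur))  # keep numeric cluster order
  wsum <- as.numeric(tapply(wt, f, sum))
  count <- if (count_mode == "weighted") wsum else as.numeric(tabulate(cl, cur))
  keep <- which(count >= min_reads)
  if (!length(keep)) return(NULL)
  cstart <- as.integer(tapply(st, f, min))[keep]
  cend <- as.integer(tapply(en, f, max))[keep]
  chrom <- as.character(GenomicRanges::seqnames(reads)[1])
  strnd <- if (stranded) as.character(GenomicRanges::strand(reads)[1]) else "*"
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(cstart, cend), strnd,
                               seqinfo = GenomeInfoDb::seqinfo(reads))
  gr$ugr_id <- sprintf("%s:%d-%d", chrom, cstart, cend)
  gr$weighted_count <- wsum[keep]
  gr$n_reads <- as.integer(tabulate(cl, cur)[keep])
  gr
}

empty_clusters <- function() {
  gr <- GenomicRanges::GRanges()
  gr$ugr_id <- character(0)
  gr$weighted_count <- numeric(0)
  gr$n_reads <- integer(0)
  gr
}

#' Merge per-sample cluster sets into a unified locus set
#'
#' Unions intervals that overlap by at least 1 bp (same chromosome, and strand
#' when \code{stranded}) across samples, producing the shared, de novo
#' assembled locus set against which every sample is quantified.
#'
#' @param cluster_sets Named list of \code{GRanges} cluster sets, one per
#'   sample.
#' @param stranded Respect strand when unioning (default \code{FALSE}).
#' @return Sorted, non-overlapping \code{GRanges} with columns \code{ugr_id}
#'   and \code{samples} (a \code{CharacterList} of contributing sample names).
#' @export
merge_cluster_sets <- function(cluster_sets, stranded = FALSE) {
  stopifnot(length(cluster_sets) >= 1L)
  if (is.null(names(cluster_sets))) {
    names(cluster_sets) <- paste0("sample", seq_along(cluster_sets))
  }
  all <- unlist(GenomicRanges::GRangesList(lapply(cluster_sets, function(g) {
    S4Vectors::mcols(g) <- NULL
    g
  })), use.names = FALSE)
  if (length(all) == 0L) return(empty_clusters())
  if (!stranded) GenomicRanges::strand(all) <- "*"
  merged <- GenomicRanges::reduce(all, ignore.strand = !stranded)
  merged <- GenomicRanges::sort(merged, ignore.strand = TRUE)
  merged$ugr_id <- sprintf("%s:%d-%d", GenomicRanges::seqnames(merged),
                           GenomicRanges::start(merged), GenomicRanges::end(merged))
  contrib <- lapply(seq_along(merged), function(i) {
    hit <- vapply(cluster_sets, function(g) {
      if (!stranded) GenomicRanges::strand(g) <- "*"
      length(GenomicRanges::findOverlaps(merged[i], g,
                                         ignore.strand = !stranded)) > 0L
    }, logical(1))
    names(cluster_sets)[hit]
  })
  merged$samples <- IRanges::CharacterList(contrib)
  merged
}

#' Write clusters as BED6
#'
#' BED output is 0-based half-open; the \code{name} field is the 1-based
#' \code{ugr_id} locus string and \code{score} the rounded weighted count
#' (capped at 1000 per BED convention).
#'
#' @param clusters \code{GRanges} from \code{\link{call_clusters}}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_clusters_bed <- function(clusters, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(clusters)),
    start = GenomicRanges::start(clusters) - 1L,
    end = GenomicRanges::end(clusters),
    name = clusters$ugr_id,
    score = pmin(1000L, as.integer(round(clusters$weighted_count))),
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(clusters))))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
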