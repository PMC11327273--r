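#' Coverage-entropy complexity of a read cluster
#'
#' Quantifies read tiling efficiency on a 0-1 scale: 0 for a single
#' single-read peak (all reads share one start position) and 1 for a uniform
#' distribution of read starts across the cluster span. Defined as the
#' Shannon entropy of the weighted read start-position distribution,
#' normalized by the log of the cluster span:
#' \deqn{C = -\sum_b p_b \ln p_b \,/\, \ln(L)}
#' where \eqn{p_b} is the fraction of read weight starting at base \eqn{b}
#' and \eqn{L} the cluster length in bp. A cluster of span 1 scores 0.
#'
#' @param starts Integer vector of member read start positions.
#' @param weights Numeric read weights (default 1 each).
#' @param span Cluster length in bp; defaults to
#'   \code{max(starts) - min(starts) + 1} (used when member reads define the
#'   cluster footprint by their starts alone; pass the true footprint length
#'   when reads extend past the last start).
#' @return Numeric scalar in \code{[0, 1]}.
#' @export
cluster_complexity <- function(starts, weights = rep(1, length(starts)),
                               span = NULL) {
  stopifnot(length(starts) >= 1L, length(weights) == length(starts))
  if (is.null(span)) span <- max(starts) - min(starts) + 1L
  if (span <= 1L) return(0)
  p <- tapply(weights, factor(starts), sum)
  p <- as.numeric(p) / sum(weights)
  p <- p[p > 0]
  if (length(p) == 1L) return(0)
  H <- -sum(p * log(p))
  H / log(span)
}

#' Peak position, coverage and fraction of a cluster
#'
#' The peak is the base with maximal weighted read depth within the cluster
#' (leftmost on ties). Peak coverage is the total weight of member reads
#' whose footprint covers the peak base; peak fraction divides by the
#' cluster's total weighted count.
#'
#' @param starts,ends Integer vectors of member read footprints (1-based,
#'   inclusive).
#' @param weights Numeric read weights (default 1 each).
#' @return List with \code{peak_pos}, \code{peak_coverage},
#'   \code{peak_fraction}.
#' @export
peak_stats <- function(starts, ends, weights = rep(1, length(starts))) {
  stopifnot(length(starts) >= 1L, length(starts) == length(ends),
            all(ends >= starts))
  lo <- min(starts)
  depth <- numeric(max(ends) - lo + 1L)
  for (i in seq_along(starts)) {
    a <- starts[i] - lo + 1L
    b <- ends[i] - lo + 1L
    depth[a:b] <- depth[a:b] + weights[i]
  }
  peak <- which.max(depth)            # leftmost maximum
  peak_pos <- peak + lo - 1L
  covers <- starts <= peak_pos & ends >= peak_pos
  pc <- sum(weights[covers])
  list(peak_pos = peak_pos, peak_coverage = pc,
       peak_fraction = pc / sum(weights))
}

#' Majority-vote consensus sequence of a cluster peak
#'
#' Builds the consensus over the reads covering the cluster's peak base.
#' The consensus spans \code{[min start, max end]} of those reads; each
#' column takes the weighted-majority base among reads aligned there, with
#' ties broken in the fixed order A < C < G < T and zero-coverage columns
#' emitted as \code{N}. Alignments are assumed ungapped (match/mismatch
#' columns only), the regime produced by short-read aligners on small RNA.
#'
#' @param starts,ends Member read footprints (1-based inclusive).
#' @param seqs Character vector of aligned read sequences
#'   (forward-genome orientation); \code{NA} for sequence-less reads.
#' @param weights Numeric read weights (default 1 each).
#' @param peak_pos Peak base; computed via \code{\link{peak_stats}} when
#'   missing.
#' @return Consensus as a character scalar (\code{""} with a warning when no
#'   peak read carries sequence).
#' @export
peak_consensus <- function(starts, ends, seqs,
                           weights = rep(1, length(starts)),
                           peak_pos = NULL) {
  stopifnot(length(starts) == length(ends), length(starts) == length(seqs))
  if (is.null(peak_pos)) {
    peak_pos <- peak_stats(starts, ends, weights)$peak_pos
  }
  sel <- which(starts <= peak_pos & ends >= peak_pos & !is.na(seqs) &
                 nzchar(seqs))
  if (!length(sel)) {
    warning("no sequence-bearing reads cover the peak; empty consensus")
    return("")
  }
  lo <- min(starts[sel])
  hi <- max(ends[sel])
  bases <- c("A", "C", "G", "T")
  votes <- matrix(0, nrow = 4L, ncol = hi - lo + 1L,
                  dimnames = list(bases, NULL))
  for (i in sel) {
    s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    ncol_i <- min(length(s), ends[i] - starts[i] + 1L)
    for (j in seq_len(ncol_i)) {
      b <- s[j]
      if (b %in% bases) {
        col <- starts[i] - lo + j
        votes[b, col] <- votes[b, col] + weights[i]
      }
    }
  }
  cons <- apply(votes, 2L, function(v) {
    if (all(v == 0)) "N" else bases[which.max(v)]  # which.max: first = A<C<G<T
  })
  paste(cons, collapse = "")
}

#' Characterize called clusters
#'
#' Annotates each cluster with the full metric set: length, weighted count,
#' number of member read sites, unique-read count and fraction, number of
#' distinct member sequences, coverage-entropy complexity, peak position /
#' coverage / fraction, and the peak consensus sequence.
#'
#' Membership is by overlap: clusters are separated by construction, so every
#' retained read site overlaps at most one cluster.
#'
#' @param clusters \code{GRanges} from \code{\link{call_clusters}}.
#' @param reads Weighted reads (\code{GRanges} with \code{weight}; optional
#'   \code{n_sites} and \code{seq} columns enable unique-read counts and
#'   consensus).
#' @param consensus Compute consensus sequences (default \code{TRUE}).
#' @return \code{clusters} with added metric columns.
#' @export
cluster_metrics <- function(clusters, reads, consensus = TRUE) {
  if (length(clusters) == 0L) return(clusters)
  if (is.null(reads$weight)) reads$weight <- rep(1, length(reads))
  hits <- GenomicRanges::findOverlaps(reads, clusters, ignore.strand = TRUE)
  n <- length(clusters)
  len <- GenomicRanges::width(clusters)
  cx <- pfrac <- pcov <- wsum <- numeric(n)
  ppos <- nmem <- integer(n)
  nuniq <- ndist <- integer(n)
  cons <- character(n)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  for (i in seq_len(n)) {
    idx <- q[s == i]
    if (!length(idx)) next
    st <- GenomicRanges::start(reads)[idx]
    en <- GenomicRanges::end(reads)[idx]
    wt <- reads$weight[idx]
    nmem[i] <- length(idx)
    wsum[i] <- sum(wt)
    cx[i] <- cluster_complexity(st, wt, span = len[i])
    pk <- peak_stats(st, en, wt)
    ppos[i] <- pk$peak_pos
    pcov[i] <- pk$peak_coverage
    pfrac[i] <- pk$peak_fraction
    nuniq[i] <- if (!is.null(reads$n_sites)) sum(reads$n_sites[idx] == 1L) else NA_integer_
    ndist[i] <- if (!is.null(reads$seq)) length(unique(reads$seq[idx])) else NA_integer_
    if (consensus && !is.null(reads$seq)) {
      cons[i] <- peak_consensus(st, en, reads$seq[idx], wt, peak_pos = pk$peak_pos)
    }
  }
  if (is.null(clusters$n_reads)) clusters$n_reads <- nmem
  if (is.null(clusters$weighted_count)) clusters$weighted_count <- wsum
  clusters$length <- len
  clusters$complexity <- cx
  clusters$peak_pos <- ppos
  clusters$peak_coverage <- pcov
  clusters$peak_fraction <- pfrac
  clusters$n_unique_reads <- nuniq
  clusters$unique_read_fraction <- ifelse(clusters$n_reads > 0,
                                          nuniq / clusters$n_reads, NA_real_)
  clusters$n_distinct_sequences <- ndist
  if (consensus) clusters$consensus <- cons
  clusters
}

#' Compare cluster properties between two groups
#'
#' Two-sided Wilcoxon rank-sum tests on one or more cluster properties
#' between two groups of clusters, with Benjamini-Hochberg adjustment across
#' the tested properties.
#'
#' @param group_a,group_b \code{GRanges} (with metric columns) or data.frames
#'   of cluster properties.
#' @param properties Character vector of property column names to test
#'   (default \code{c("length", "complexity", "peak_fraction",
#'   "n_unique_reads")}).
#' @return data.frame with \code{property}, \code{statistic}, \code{p_value},
#'   \code{fdr}, \code{degenerate} (constant pooled values).
#' @export
compare_properties <- function(group_a, group_b,
                               properties = c("length", "complexity",
                                              "peak_fraction", "n_unique_reads")) {
  a <- as_property_df(group_a)
  b <- as_property_df(group_b)
  stopifnot(nrow(a) > 0L, nrow(b) > 0L)
  res <- lapply(properties, function(p) {
    x <- a[[p]]; y <- b[[p]]
    if (is.null(x) || is.null(y)) stop("unknown property: ", p)
    pooled <- c(x, y)
    if (length(unique(pooled)) == 1L) {
      return(data.frame(property = p, statistic = NA_real_, p_value = 1,
                        degenerate = TRUE))
    }
    wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
    data.frame(property = p, statistic = unname(wt$statistic),
               p_value = wt$p.value, degenerate = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out[, c("property", "statistic", "p_value", "fdr", "degenerate")]
}

as_property_df <- function(x) {
  if (methods::is(x, "GRanges")) {
    df <- as.data.frame(S4Vectors::mcols(x))
    df$length <- GenomicRanges::width(x)
    df
  } else {
    as.data.frame(x)
  }
}
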