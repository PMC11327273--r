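#' Quantify samples against a unified cluster set
#'
#' Builds the cluster-by-sample count matrix. Each weighted read is assigned
#' to the cluster it overlaps most (at least 1 bp; ties go to the leftmost
#' cluster) and contributes its weight there, never to more than one cluster.
#'
#' @param samples Named list of weighted-read \code{GRanges} (a \code{weight}
#'   column; missing weights default to 1), one element per sample.
#' @param clusters Non-overlapping \code{GRanges} with \code{ugr_id}.
#' @param library_sizes Optional numeric vector of per-sample total weighted
#'   retained reads; defaults to each sample's total weight.
#' @return Numeric matrix (rows = \code{ugr_id}, columns = sample names) with
#'   attribute \code{library_sizes}.
#' @export
quantify_clusters <- function(samples, clusters, library_sizes = NULL) {
  stopifnot(length(samples) >= 1L)
  if (is.null(names(samples))) names(samples) <- paste0("sample", seq_along(samples))
  if (length(clusters) > 1L) {
    ol <- GenomicRanges::findOverlaps(clusters, clusters, ignore.strand = TRUE)
    if (any(S4Vectors::queryHits(ol) != S4Vectors::subjectHits(ol))) {
      stop("cluster set must be non-overlapping")
    }
  }
  m <- matrix(0, nrow = length(clusters), ncol = length(samples),
              dimnames = list(clusters$ugr_id, names(samples)))
  libs <- numeric(length(samples))
  for (k in seq_along(samples)) {
    reads <- samples[[k]]
    if (is.null(reads$weight)) reads$weight <- rep(1, length(reads))
    libs[k] <- sum(reads$weight)
    if (length(reads) == 0L) {
      warning("sample '", names(samples)[k], "' has zero retained reads")
      next
    }
    hits <- GenomicRanges::findOverlaps(reads, clusters, ignore.strand = TRUE)
    if (length(hits) == 0L) next
    ov <- GenomicRanges::pintersect(reads[S4Vectors::queryHits(hits)],
                                    clusters[S4Vectors::subjectHits(hits)],
                                    ignore.strand = TRUE)
    ow <- GenomicRanges::width(ov)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    # best cluster per read: max overlap, ties -> leftmost (smaller subject
    # index in the sorted cluster set)
    o <- order(qh, -ow, sh)
    first <- !duplicated(qh[o])
    assign_read <- qh[o][first]
    assign_cl <- sh[o][first]
    agg <- tapply(reads$weight[assign_read],
                  factor(assign_cl, levels = seq_along(clusters)), sum)
    agg[is.na(agg)] <- 0
    m[, k] <- as.numeric(agg)
  }
  if (!is.null(library_sizes)) {
    stopifnot(length(library_sizes) == length(samples))
    libs <- library_sizes
  }
  attr(m, "library_sizes") <- stats::setNames(libs, names(samples))
  m
}

#' Counts per million
#'
#' @param counts Count matrix with a \code{library_sizes} attribute (or pass
#'   \code{library_sizes}).
#' @param library_sizes Per-sample library sizes.
#' @return Matrix of CPM values.
#' @export
cpm <- function(counts, library_sizes = NULL) {
  if (is.null(library_sizes)) library_sizes <- attr(counts, "library_sizes")
  stopifnot(!is.null(library_sizes), all(library_sizes > 0))
  out <- sweep(counts, 2L, library_sizes / 1e6, "/")
  attr(out, "library_sizes") <- library_sizes
  out
}

#' log2 counts per million with a fixed pseudo-count
#'
#' voom-style transform: \code{log2((count + prior) / (library_size + 2 *
#' prior) * 1e6)}. The pseudo-count (default 0.5 reads) is recorded in the
#' \code{prior} attribute of the result.
#'
#' @inheritParams cpm
#' @param prior Pseudo-count in reads (default 0.5).
#' @return Matrix of log2-CPM values.
#' @export
log2_cpm <- function(counts, library_sizes = NULL, prior = 0.5) {
  if (is.null(library_sizes)) library_sizes <- attr(counts, "library_sizes")
  stopifnot(!is.null(library_sizes), all(library_sizes > 0), prior > 0)
  out <- log2(sweep(counts + prior, 2L, (library_sizes + 2 * prior) / 1e6, "/"))
  attr(out, "library_sizes") <- library_sizes
  attr(out, "prior") <- prior
  out
}

#' Filter under-expressed clusters
#'
#' Keeps a row when at least \code{min_samples} samples exceed the CPM
#' threshold; with a sample grouping, the requirement must hold within at
#' least one group (low-count loci across all samples of a phenotype are
#' removed).
#'
#' @param counts Count matrix with \code{library_sizes} attribute.
#' @param cpm_threshold Keep requires CPM strictly greater than this
#'   (default 10).
#' @param min_samples Minimum qualifying samples (default 1).
#' @param groups Optional character/factor of length \code{ncol(counts)}
#'   assigning samples to phenotype groups.
#' @return Filtered matrix with attributes \code{library_sizes},
#'   \code{n_kept}, \code{n_dropped}, \code{kept} (logical per input row).
#' @export
filter_expressed <- function(counts, cpm_threshold = 10, min_samples = 1L,
                             groups = NULL) {
  stopifnot(cpm_threshold > 0, min_samples >= 1L)
  x <- cpm(counts)
  pass <- x > cpm_threshold
  if (is.null(groups)) {
    keep <- rowSums(pass) >= min_samples
  } else {
    stopifnot(length(groups) == ncol(counts))
    keep <- Reduce(`|`, lapply(split(seq_len(ncol(counts)), groups), function(idx) {
      rowSums(pass[, idx, drop = FALSE]) >= min_samples
    }))
  }
  out <- counts[keep, , drop = FALSE]
  attr(out, "library_sizes") <- attr(counts, "library_sizes")
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "kept") <- keep
  out
}

#' Spearman correlation between mean expression profiles
#'
#' Rank correlation of the mean log2-CPM profile of one sample set against
#' another, the comparison used to contrast cellular and vesicle-derived
#' expression landscapes.
#'
#' @param counts Count matrix with \code{library_sizes} attribute.
#' @param set_a,set_b Column names or indices of the two sample sets.
#' @param prior Pseudo-count passed to \code{\link{log2_cpm}}.
#' @return List with \code{rho} (\code{NA} with \code{degenerate = TRUE} when
#'   a mean profile is constant) and \code{n} shared rows.
#' @export
spearman_profile_correlation <- function(counts, set_a, set_b, prior = 0.5) {
  lc <- log2_cpm(counts, prior = prior)
  a <- rowMeans(lc[, set_a, drop = FALSE])
  b <- rowMeans(lc[, set_b, drop = FALSE])
  stopifnot(length(a) >= 3L)
  if (length(unique(a)) == 1L || length(unique(b)) == 1L) {
    return(list(rho = NA_real_, n = length(a), degenerate = TRUE))
  }
  list(rho = stats::cor(a, b, method = "spearman"), n = length(a),
       degenerate = FALSE)
}

#' Write a count matrix and its library sizes as TSV
#'
#' @param counts Matrix from \code{\link{quantify_clusters}}.
#' @param path Output TSV path (rows = ugr_id); library sizes go to
#'   \code{<path>.libsizes.tsv} unless \code{lib_path} is given.
#' @param lib_path Optional explicit library-size TSV path.
#' @return Invisibly, \code{path}.
#' @export
write_count_matrix <- function(counts, path, lib_path = NULL) {
  df <- data.frame(ugr_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  libs <- attr(counts, "library_sizes")
  if (!is.null(libs)) {
    if (is.null(lib_path)) lib_path <- paste0(path, ".libsizes.tsv")
    utils::write.table(
      data.frame(sample = names(libs), library_size = as.numeric(libs)),
      lib_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a count matrix written by \code{\link{write_count_matrix}}
#'
#' @param path Counts TSV path.
#' @param lib_path Library-size TSV path (default \code{<path>.libsizes.tsv}).
#' @return Numeric matrix with \code{library_sizes} attribute when available.
#' @export
read_count_matrix <- function(path, lib_path = paste0(path, ".libsizes.tsv")) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (file.exists(lib_path)) {
    ls <- utils::read.table(lib_path, sep = "\t", header = TRUE)
    attr(m, "library_sizes") <- stats::setNames(ls$library_size, ls$sample)
  }
  m
}
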