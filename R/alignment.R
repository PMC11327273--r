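#' Load small RNA alignments from SAM/BAM
#'
#' Reads all mapped alignment records (primary plus secondary) from a SAM or
#' BAM file and returns them as a \link[GenomicRanges]{GRanges} with one range
#' per alignment site, carrying \code{read_id}, \code{n_sites} (number of
#' reported sites for the read) and the aligned sequence.
#'
#' The number of sites per read is taken from the \code{NH} tag when present
#' and otherwise obtained by counting records sharing a read id. Reads
#' reported at more than \code{max_sites} sites are discarded entirely;
#' the number of discarded reads is available as
#' \code{metadata(x)$n_discarded_max_sites}. Records whose CIGAR contains
#' reference-skip (\code{N}) or padding (\code{P}) operations are skipped
#' with a warning.
#'
#' @param path Path to a SAM or BAM file. SAM input is converted on the fly.
#' @param max_sites Maximum number of alignment sites per read (default 15);
#'   reads exceeding it are dropped.
#'
#' @return A \code{GRanges} (1-based, inclusive; strand from the alignment
#'   flag) with metadata columns \code{read_id}, \code{n_sites}, \code{seq}.
#'   Counters are stored in \code{S4Vectors::metadata}.
#' @export
load_alignments <- function(path, max_sites = 15L) {
  stopifnot(max_sites >= 1L)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "strand", "pos", "cigar", "seq"),
    tag = "NH",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(res$qname)
  if (n == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::metadata(gr) <- list(n_discarded_max_sites = 0L, n_skipped_cigar = 0L)
    return(gr)
  }
  bad_cigar <- grepl("[NP]", res$cigar)
  if (any(bad_cigar)) {
    warning(sum(bad_cigar), " record(s) with reference-skip/padding CIGAR skipped")
  }
  keep <- !bad_cigar
  width <- GenomicAlignments_width(res$cigar[keep])
  nh <- res$tag$NH[keep]
  qname <- as.character(res$qname[keep])
  if (is.null(nh) || all(is.na(nh))) {
    nh <- as.integer(table(qname)[qname])
  } else if (anyNA(nh)) {
    cnt <- table(qname)
    nh[is.na(nh)] <- as.integer(cnt[qname[is.na(nh)]])
  }
  gr <- GenomicRanges::GRanges(
    seqnames = res$rname[keep],
    ranges = IRanges::IRanges(start = res$pos[keep], width = width),
    strand = res$strand[keep])
  gr$read_id <- qname
  gr$n_sites <- as.integer(nh)
  gr$seq <- as.character(res$seq[keep])
  over <- gr$n_sites > max_sites
  n_disc <- length(unique(gr$read_id[over]))
  gr <- gr[!over]
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  S4Vectors::metadata(gr) <- list(n_discarded_max_sites = n_disc,
                                  n_skipped_cigar = sum(bad_cigar))
  gr
}

# Reference-space width of a CIGAR string (M/D/N/=/X consume reference).
GenomicAlignments_width <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1]]
    toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    sum(vapply(toks, function(t) {
      op <- substr(t, nchar(t), nchar(t))
      len <- as.integer(substr(t, 1L, nchar(t) - 1L))
      if (op %in% c("M", "D", "N", "=", "X")) len else 0L
    }, integer(1)))
  }, integer(1), USE.NAMES = FALSE)
}

#' Per-base depth of uniquely mapped reads
#'
#' Coverage over the genome counting only alignments whose read maps to a
#' single site (\code{n_sites == 1}). This distribution drives the
#' redistribution of multi-mapped reads.
#'
#' @param alignments \code{GRanges} from \code{\link{load_alignments}} with a
#'   \code{n_sites} column.
#' @return An \link[IRanges]{RleList} of per-base depths, one element per
#'   sequence level present in \code{alignments}.
#' @export
unique_depth <- function(alignments) {
  uniq <- alignments[alignments$n_sites == 1L]
  GenomicRanges::coverage(uniq)
}

#' Redistribute multi-mapped reads by the unique-read mapping distribution
#'
#' Each multi-mapped read contributes total weight 1, split across its
#' retained alignment sites in proportion to the mean unique-read depth over
#' each site's footprint (optionally extended by \code{rescue_window} bp on
#' both sides). When no site has unique coverage the read is split uniformly.
#' Uniquely mapped reads keep weight 1. The redistribution is a single
#' unique-read-informed pass, not an iterative EM.
#'
#' @param alignments \code{GRanges} with \code{read_id} and \code{n_sites}
#'   columns (all retained sites of all reads).
#' @param udepth Unique-read coverage as returned by
#'   \code{\link{unique_depth}}; computed from \code{alignments} when missing.
#' @param rescue_window Integer bp added to each side of a site's footprint
#'   when averaging unique depth (default 0).
#'
#' @return \code{alignments} with an added numeric \code{weight} column;
#'   weights of each read's sites sum to 1.
#' @export
rescue_multimapped <- function(alignments, udepth = NULL, rescue_window = 0L) {
  stopifnot(rescue_window >= 0L)
  if (length(alignments) == 0L) {
    alignments$weight <- numeric(0)
    return(alignments)
  }
  if (is.null(udepth)) udepth <- unique_depth(alignments)
  w <- rep(1, length(alignments))
  multi <- which(alignments$n_sites > 1L)
  if (length(multi)) {
    sites <- alignments[multi]
    probe <- sites
    if (rescue_window > 0L) {
      probe <- GenomicRanges::resize(sites,
        width = GenomicRanges::width(sites) + 2L * rescue_window, fix = "center")
      probe <- GenomicRanges::trim(probe)
    }
    u <- mean_depth_over(probe, udepth)
    spl <- split(seq_along(sites), sites$read_id)
    for (idx in spl) {
      tot <- sum(u[idx])
      w[multi[idx]] <- if (tot > 0) u[idx] / tot else 1 / length(idx)
    }
  }
  alignments$weight <- w
  alignments
}

# Mean coverage of `cov` (RleList) over each range of `gr`; ranges on
# sequences absent from `cov` get 0.
mean_depth_over <- function(gr, cov) {
  out <- numeric(length(gr))
  chroms <- as.character(GenomicRanges::seqnames(gr))
  for (chr in unique(chroms)) {
    sel <- which(chroms == chr)
    if (!chr %in% names(cov)) next
    v <- cov[[chr]]
    r <- IRanges::ranges(gr[sel])
    r <- IRanges::restrict(r, start = 1L, end = length(v),
                           keep.all.ranges = TRUE)
    ok <- IRanges::width(r) > 0L
    if (any(ok)) {
      views <- IRanges::Views(v, r[ok])
      out[sel[ok]] <- IRanges::viewMeans(views)
    }
  }
  out
}
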