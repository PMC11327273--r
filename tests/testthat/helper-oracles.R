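# Independent reference implementations used as oracles. These deliberately
# use different algorithms (per-base painting, integer-code comparison) from
# the package code paths they check.

# Adapter trimming oracle: integer-coded comparison, exhaustive tabulation of
# every candidate occurrence followed by an explicit sort on the selection
# criteria. Mirrors the documented semantics of the standard 3'-adapter
# trimmer at defaults: occurrence of overlap L valid when mismatches <=
# floor(0.1 * L) and L >= 3; most matching bases wins, then fewest
# mismatches, then leftmost; N never matches.
oracle_trim <- function(sequence, head_trim = 3L, adapter = "AAAAAAAAAA",
                        min_length = 15L, error_rate = 0.1, min_overlap = 3L) {
  if (nchar(sequence) <= head_trim) return(list(kept = FALSE, sequence = ""))
  s <- utf8ToInt(substr(sequence, head_trim + 1L, nchar(sequence)))
  a <- utf8ToInt(adapter)
  nN <- utf8ToInt("N")
  cand <- data.frame(i = integer(0), matches = integer(0), mism = integer(0))
  for (i in seq_along(s)) {
    L <- min(length(a), length(s) - i + 1L)
    if (L < min_overlap) break
    frag <- s[i:(i + L - 1L)]
    mism <- sum(frag != a[1:L] | frag == nN)
    if (mism <= floor(error_rate * L)) {
      cand <- rbind(cand, data.frame(i = i, matches = L - mism, mism = mism))
    }
  }
  cut <- if (nrow(cand) == 0L) NA_integer_ else {
    cand <- cand[order(-cand$matches, cand$mism, cand$i), ]
    cand$i[1L]
  }
  out <- if (is.na(cut)) s else s[seq_len(cut - 1L)]
  if (length(out) < min_length) return(list(kept = FALSE, sequence = ""))
  list(kept = TRUE, sequence = intToUtf8(out))
}

# Cluster-calling oracle: paint read footprints on a base vector, close gaps
# shorter than min_gap, then group reads by the merged run containing them.
oracle_clusters <- function(starts, ends, weights, min_gap, min_reads) {
  stopifnot(length(starts) == length(ends))
  lo <- min(starts); hi <- max(ends)
  covered <- logical(hi - lo + 1L)
  for (i in seq_along(starts)) {
    covered[(starts[i] - lo + 1L):(ends[i] - lo + 1L)] <- TRUE
  }
  # close gaps of < min_gap uncovered bases between covered runs
  r <- rle(covered)
  pos_end <- cumsum(r$lengths)
  pos_start <- pos_end - r$lengths + 1L
  inner <- which(!r$values & seq_along(r$values) > 1L &
                   seq_along(r$values) < length(r$values))
  for (k in inner) {
    if (r$lengths[k] < min_gap) covered[pos_start[k]:pos_end[k]] <- TRUE
  }
  r <- rle(covered)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  runs <- which(r$values)
  out <- list()
  for (k in runs) {
    members <- which(starts - lo + 1L >= run_start[k] &
                       starts - lo + 1L <= run_end[k])
    if (sum(weights[members]) >= min_reads) {
      out[[length(out) + 1L]] <- data.frame(
        start = min(starts[members]), end = max(ends[members]),
        weighted_count = sum(weights[members]))
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      weighted_count = numeric(0)))
  }
  df <- do.call(rbind, out)
  df[order(df$start), , drop = FALSE]
}

# Per-base depth oracle: explicit loop over every base of every range.
oracle_depth <- function(starts, ends, lo, hi) {
  d <- integer(hi - lo + 1L)
  for (i in seq_along(starts)) {
    for (b in starts[i]:ends[i]) {
      if (b >= lo && b <= hi) d[b - lo + 1L] <- d[b - lo + 1L] + 1L
    }
  }
  d
}

# Order raw SAM record lines by chromosome then position.
sort_sam <- function(recs) {
  chrom <- vapply(strsplit(recs, "\t"), `[`, character(1), 3L)
  pos <- as.integer(vapply(strsplit(recs, "\t"), `[`, character(1), 4L))
  recs[order(chrom, pos)]
}

# Build a GRanges of unit-weight reads from vectors.
make_reads <- function(chrom, starts, width = 22L, weights = NULL,
                       strand = "+", seq = NULL, n_sites = 1L) {
  gr <- if (length(starts) == 0L) GenomicRanges::GRanges() else
    GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, width = width),
                           strand)
  gr$read_id <- sprintf("r%d", seq_along(gr))
  gr$n_sites <- rep(as.integer(n_sites), length.out = length(gr))
  gr$weight <- if (is.null(weights)) rep(1, length(gr)) else weights
  if (!is.null(seq)) gr$seq <- rep(seq, length.out = length(gr))
  gr
}

# A small GTF written to a temp file; returns the path.
write_test_gtf <- function(lines, path = tempfile(fileext = ".gtf")) {
  writeLines(lines, path)
  path
}

gtf_line <- function(chrom, src, type, start, end, strand, attrs) {
  sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s", chrom, src, type, start, end,
          strand, attrs)
}
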