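#' Trim a single small RNA read
#'
#' Applies the library-preparation trimming used for SMARTer-style small RNA
#' libraries: remove a fixed number of bases from the 5' end (the template
#' switching triad), then locate a 3' homopolymer adapter and remove it
#' together with everything 3' of it, and finally discard reads shorter than
#' a minimum length.
#'
#' Adapter matching follows standard 3'-adapter semantics: the adapter may
#' occur internally (full-length occurrence, everything from its first base
#' onward is removed) or partially overlap the 3' end of the read. A candidate
#' occurrence at position \code{i} compares the first
#' \code{min(nchar(adapter), n - i + 1)} adapter bases against the read;
#' it is accepted when the number of mismatches does not exceed
#' \code{floor(error_rate * overlap)} and the overlap is at least
#' \code{min_overlap}. Among accepted occurrences, the one with the most
#' matching bases is trimmed (ties: fewer mismatches, then leftmost).
#' \code{N} bases never match the adapter.
#'
#' @param sequence Character scalar, the read sequence over A/C/G/T/N.
#' @param qualities Character scalar of equal length, the per-base quality
#'   string, or \code{NULL} when qualities are not tracked.
#' @param head_trim Integer, number of bases removed unconditionally from the
#'   5' end (default 3).
#' @param adapter 3' adapter sequence (default \code{"AAAAAAAAAA"}, the
#'   oligo-dT derived poly-A homopolymer).
#' @param min_length Minimum retained read length (default 15).
#' @param error_rate Maximum fraction of mismatches tolerated in an adapter
#'   occurrence (default 0.1).
#' @param min_overlap Minimum overlap, in bases, between the adapter and the
#'   read 3' end for a partial occurrence to be trimmed (default 3).
#'
#' @return A list with elements \code{kept} (logical), \code{sequence}
#'   (trimmed sequence, \code{""} when dropped) and \code{qualities}
#'   (trimmed quality string or \code{NULL}).
#'
#' @examples
#' trim_read("GGGACGTACGTACGTACGTAAAAAAAAAAGTC")
#' @export
trim_read <- function(sequence, qualities = NULL, head_trim = 3L,
                      adapter = "AAAAAAAAAA", min_length = 15L,
                      error_rate = 0.1, min_overlap = 3L) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            head_trim >= 0L, nzchar(adapter), min_length >= 1L)
  if (!is.null(qualities)) {
    if (nchar(qualities) != nchar(sequence)) {
      stop("malformed read: sequence and quality strings differ in length")
    }
  }
  n <- nchar(sequence)
  if (n <= head_trim) {
    return(list(kept = FALSE, sequence = "", qualities = if (is.null(qualities)) NULL else ""))
  }
  seq <- substr(sequence, head_trim + 1L, n)
  qual <- if (is.null(qualities)) NULL else substr(qualities, head_trim + 1L, n)

  cut <- adapter_match_start(seq, adapter, error_rate, min_overlap)
  if (!is.na(cut)) {
    seq <- if (cut == 1L) "" else substr(seq, 1L, cut - 1L)
    if (!is.null(qual)) qual <- if (cut == 1L) "" else substr(qual, 1L, cut - 1L)
  }
  if (nchar(seq) < min_length) {
    return(list(kept = FALSE, sequence = "", qualities = if (is.null(qual)) NULL else ""))
  }
  list(kept = TRUE, sequence = seq, qualities = qual)
}

#' Locate the best accepted 3' adapter occurrence
#'
#' Scores every candidate start position: an occurrence of overlap \code{l}
#' with \code{m} mismatches is valid when \code{m <= floor(error_rate * l)}
#' and \code{l >= min_overlap}; among valid occurrences the one with the most
#' matching bases wins, ties going to fewer mismatches and then to the
#' leftmost position (which trims the most), matching the behavior of
#' standard 3'-adapter trimmers at their defaults.
#'
#' @param seq Read sequence after head trimming.
#' @inheritParams trim_read
#' @return 1-based start position of the occurrence, or \code{NA} when no
#'   occurrence is accepted.
#' @keywords internal
adapter_match_start <- function(seq, adapter, error_rate = 0.1, min_overlap = 3L) {
  n <- nchar(seq)
  alen <- nchar(adapter)
  if (n == 0L) return(NA_integer_)
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  a <- strsplit(adapter, "", fixed = TRUE)[[1]]
  best <- NA_integer_
  best_matches <- -1L
  best_mism <- Inf
  for (i in seq_len(n)) {
    l <- min(alen, n - i + 1L)
    if (l < min_overlap) break
    frag <- s[i:(i + l - 1L)]
    ad <- a[seq_len(l)]
    mism <- sum(frag != ad | frag == "N")
    if (mism > floor(error_rate * l)) next
    matches <- l - mism
    if (matches > best_matches ||
        (matches == best_matches && mism < best_mism)) {
      best <- i
      best_matches <- matches
      best_mism <- mism
    }
  }
  best
}

#' Trim a FASTQ file
#'
#' Applies \code{\link{trim_read}} to every record of a (plain or gzipped)
#' 4-line FASTQ file and writes the kept reads to \code{out}. Record order is
#' preserved.
#'
#' @param input Path to the input FASTQ (optionally gzipped).
#' @param out Path for the trimmed FASTQ output; \code{.gz} suffix triggers
#'   gzip compression. \code{NULL} suppresses writing.
#' @inheritParams trim_read
#' @param report Optional path for a JSON report of input/kept/discarded
#'   counts.
#'
#' @return Invisibly, a list with \code{n_input}, \code{n_kept},
#'   \code{n_discarded}, \code{n_malformed} and the trimmed records as a
#'   data.frame (\code{id}, \code{sequence}, \code{qualities}).
#' @export
trim_fastq <- function(input, out = NULL, head_trim = 3L,
                       adapter = "AAAAAAAAAA", min_length = 15L,
                       error_rate = 0.1, min_overlap = 3L, report = NULL) {
  rec <- read_fastq(input)
  n <- nrow(rec)
  kept <- logical(n)
  seqs <- character(n)
  quals <- character(n)
  malformed <- 0L
  for (i in seq_len(n)) {
    if (nchar(rec$sequence[i]) != nchar(rec$qualities[i]) ||
        !nzchar(rec$sequence[i])) {
      malformed <- malformed + 1L
      warning(sprintf("record %d (%s) malformed; dropped", i, rec$id[i]))
      next
    }
    tr <- trim_read(rec$sequence[i], rec$qualities[i], head_trim = head_trim,
                    adapter = adapter, min_length = min_length,
                    error_rate = error_rate, min_overlap = min_overlap)
    if (tr$kept) {
      kept[i] <- TRUE
      seqs[i] <- tr$sequence
      quals[i] <- tr$qualities
    }
  }
  res <- data.frame(id = rec$id[kept], sequence = seqs[kept],
                    qualities = quals[kept], stringsAsFactors = FALSE)
  if (!is.null(out)) write_fastq(res, out)
  stats <- list(n_input = n, n_kept = nrow(res),
                n_discarded = n - nrow(res) - malformed,
                n_malformed = malformed)
  if (!is.null(report)) {
    jsonlite::write_json(stats, report, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(c(stats, list(reads = res)))
}

# Minimal strict 4-line FASTQ reader/writer. Kept local because quality
# strings must round-trip byte-identically, including characters that
# quality-aware containers reinterpret.
read_fastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4L != 0L) {
    stop("FASTQ record count is not a multiple of 4: ", path)
  }
  idx <- seq(1L, length(lines), by = 4L)
  data.frame(id = sub("^@", "", lines[idx]),
             sequence = lines[idx + 1L],
             qualities = lines[idx + 3L],
             stringsAsFactors = FALSE)
}

write_fastq <- function(records, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (nrow(records)) {
    out <- as.vector(rbind(paste0("@", records$id), records$sequence,
                           "+", records$qualities))
    writeLines(out, con)
  }
  invisible(path)
}
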