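#' Build a simulation configuration
#'
#' Declares a synthetic genome, a set of planted read clusters, and the
#' samples to emit. Planted clusters mimic the regimes observed in small RNA
#' sequencing of cells and extracellular vesicles: peak-dominated stacks
#' (\code{shape = "point"}), uniformly tiled high-complexity regions
#' (\code{"uniform"}), and diffuse accumulations (\code{"gaussian"});
#' cluster read counts may span 1 to 10,000; loci may be duplicated elsewhere
#' in the genome to create genuine multi-mapping; background reads are
#' scattered below the calling threshold.
#'
#' @param seed Integer seed governing every random draw.
#' @param genome Named integer vector of chromosome lengths (each >= 1000).
#' @param clusters data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (1-based inclusive footprint), \code{n_reads}, \code{shape}
#'   (\code{point}/\code{uniform}/\code{gaussian}), and optionally
#'   \code{sigma} (bp, gaussian only), \code{read_length} (default 22),
#'   \code{strand} (default \code{+}), \code{multimap_copies} (default 1),
#'   \code{multimap_fraction} (fraction of the cluster's reads reported at
#'   every copy; default 0.5 when copies > 1), \code{annotated_as} (biotype
#'   or \code{NA}).
#' @param samples Named numeric vector of per-sample library-size multipliers
#'   applied to every cluster's \code{n_reads} (default one sample at 1).
#' @param background_reads Unique reads scattered uniformly per sample
#'   (default 0); isolated, so they stay below the calling threshold.
#' @param error_rate Per-base substitution rate applied to read sequences
#'   (default 0).
#' @return A \code{smrc_sim_config} list.
#' @export
sim_config <- function(seed, genome = c(chr1 = 100000L, chr2 = 100000L),
                       clusters, samples = c(s1 = 1),
                       background_reads = 0L, error_rate = 0) {
  stopifnot(is.numeric(seed), all(genome >= 1000L), is.data.frame(clusters),
            all(c("chrom", "start", "end", "n_reads", "shape") %in% names(clusters)))
  defaults <- list(sigma = 10, read_length = 22L, strand = "+",
                   multimap_copies = 1L, multimap_fraction = 0.5,
                   annotated_as = NA_character_)
  for (nm in names(defaults)) {
    if (is.null(clusters[[nm]])) clusters[[nm]] <- defaults[[nm]]
  }
  stopifnot(all(clusters$shape %in% c("point", "uniform", "gaussian")),
            all(clusters$end - clusters$start + 1L >= clusters$read_length),
            all(clusters$n_reads >= 1L),
            all(clusters$chrom %in% names(genome)),
            all(clusters$end <= genome[clusters$chrom]))
  # planted footprints must not overlap each other
  gr <- GenomicRanges::GRanges(clusters$chrom,
                               IRanges::IRanges(clusters$start, clusters$end))
  ol <- GenomicRanges::findOverlaps(gr, gr)
  if (any(S4Vectors::queryHits(ol) != S4Vectors::subjectHits(ol))) {
    stop("planted cluster footprints overlap")
  }
  structure(list(seed = as.integer(seed), genome = genome,
                 clusters = clusters, samples = samples,
                 background_reads = as.integer(background_reads),
                 error_rate = error_rate),
            class = "smrc_sim_config")
}

#' Simulate the reference genome
#'
#' Draws uniform random A/C/G/T per chromosome, then copies the footprint
#' sequence of every cluster with \code{multimap_copies > 1} verbatim to the
#' required number of decoy loci (placed away from all planted footprints and
#' other decoys), so that reads from the duplicated locus genuinely map to
#' multiple sites.
#'
#' @param config \code{smrc_sim_config}.
#' @param fasta Optional path to write the genome as FASTA.
#' @return List with \code{genome} (\link[Biostrings]{DNAStringSet}) and
#'   \code{decoys} (data.frame \code{cluster}, \code{chrom}, \code{start},
#'   \code{end}).
#' @export
simulate_genome <- function(config, fasta = NULL) {
  stopifnot(inherits(config, "smrc_sim_config"))
  set.seed(config$seed)
  genome <- lapply(config$genome, function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  })
  cl <- config$clusters
  occupied <- GenomicRanges::GRanges(cl$chrom, IRanges::IRanges(cl$start, cl$end))
  decoys <- list()
  for (i in seq_len(nrow(cl))) {
    k <- cl$multimap_copies[i]
    if (k <= 1L) next
    fp <- substr(genome[[cl$chrom[i]]], cl$start[i], cl$end[i])
    w <- nchar(fp)
    for (copy in seq_len(k - 1L)) {
      placed <- FALSE
      for (try in 1:200) {
        chr <- sample(names(config$genome), 1L)
        pos <- sample.int(config$genome[[chr]] - w + 1L, 1L)
        cand <- GenomicRanges::GRanges(chr, IRanges::IRanges(pos, pos + w - 1L))
        # keep decoys >= 200 bp away from anything planted so clusters stay
        # well separated
        near <- GenomicRanges::findOverlaps(cand, occupied, maxgap = 200L)
        if (length(near) == 0L) {
          substr(genome[[chr]], pos, pos + w - 1L) <- fp
          occupied <- c(occupied, cand)
          decoys[[length(decoys) + 1L]] <- data.frame(
            cluster = i, chrom = chr, start = pos, end = pos + w - 1L)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place decoy locus for cluster ", i,
                        "; enlarge the genome")
    }
  }
  dna <- Biostrings::DNAStringSet(unlist(genome))
  names(dna) <- names(config$genome)
  if (!is.null(fasta)) Biostrings::writeXStringSet(dna, fasta)
  decoys <- if (length(decoys)) do.call(rbind, decoys) else
    data.frame(cluster = integer(0), chrom = character(0),
               start = integer(0), end = integer(0))
  list(genome = dna, decoys = decoys)
}

#' Simulate per-sample alignments and the planted truth set
#'
#' Draws reads from each planted cluster according to its shape, copies their
#' sequences from the genome (with optional substitution errors), emits every
#' candidate alignment site of multi-mapped reads with correct \code{NH}
#' tags, adds scattered background reads, and writes one coordinate-sorted
#' SAM per sample. The truth table records, per planted cluster, the expected
#' call interval under default caller settings and the analytic complexity of
#' the planted start distribution (0 for \code{point};
#' \eqn{\ln S / \ln L} for \code{uniform} tiling with \eqn{S} distinct
#' starts over span \eqn{L}; \code{NA} for \code{gaussian}).
#'
#' Uniform tiling is deterministic: starts are spread evenly over the
#' footprint so the realized start distribution equals the planted one.
#'
#' @param config \code{smrc_sim_config}.
#' @param sim_genome Result of \code{\link{simulate_genome}}.
#' @param out_dir Directory for output files; created if needed. \code{NULL}
#'   skips file output.
#' @param emit_fastq Also write per-sample raw FASTQ (reads wrapped with the
#'   5' GGG triad and a 3' poly-A adapter) for exercising the trimming stage.
#' @return List with \code{reads} (named list of per-sample \code{GRanges}
#'   with \code{read_id}, \code{n_sites}, \code{seq}, \code{true_site}),
#'   \code{truth} (\code{GRanges} of planted clusters with expectations),
#'   \code{sam_paths}, \code{fastq_paths}.
#' @export
simulate_reads <- function(config, sim_genome, out_dir = NULL,
                           emit_fastq = FALSE) {
  stopifnot(inherits(config, "smrc_sim_config"))
  set.seed(config$seed + 1L)
  genome <- sim_genome$genome
  decoys <- sim_genome$decoys
  cl <- config$clusters
  samples <- config$samples
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  truth <- make_truth(config)
  reads_by_sample <- list()
  sam_paths <- character(0)
  fastq_paths <- character(0)

  for (s in names(samples)) {
    mult <- samples[[s]]
    recs <- list()
    for (i in seq_len(nrow(cl))) {
      n <- max(1L, as.integer(round(cl$n_reads[i] * mult)))
      rl <- cl$read_length[i]
      starts <- draw_starts(cl$shape[i], cl$start[i], cl$end[i], rl, n,
                            cl$sigma[i])
      k <- cl$multimap_copies[i]
      n_multi <- if (k > 1L) as.integer(round(n * cl$multimap_fraction[i])) else 0L
      dec <- decoys[decoys$cluster == i, , drop = FALSE]
      for (j in seq_along(starts)) {
        st <- starts[j]
        seqj <- mutate_seq(substr(as.character(genome[[cl$chrom[i]]]),
                                  st, st + rl - 1L), config$error_rate)
        rid <- sprintf("%s_c%d_r%d", s, i, j)
        is_multi <- j <= n_multi
        nh <- if (is_multi) k else 1L
        recs[[length(recs) + 1L]] <- data.frame(
          read_id = rid, chrom = cl$chrom[i], start = st,
          end = st + rl - 1L, strand = cl$strand[i], seq = seqj,
          n_sites = nh, true_site = TRUE)
        if (is_multi && nrow(dec)) {
          off <- st - cl$start[i]
          for (d in seq_len(nrow(dec))) {
            recs[[length(recs) + 1L]] <- data.frame(
              read_id = rid, chrom = dec$chrom[d],
              start = dec$start[d] + off, end = dec$start[d] + off + rl - 1L,
              strand = cl$strand[i], seq = seqj, n_sites = nh,
              true_site = FALSE)
          }
        }
      }
    }
    n_bg <- as.integer(round(config$background_reads * mult))
    if (n_bg > 0L) {
      for (j in seq_len(n_bg)) {
        chr <- sample(names(config$genome), 1L)
        rl <- 22L
        st <- sample.int(config$genome[[chr]] - rl + 1L, 1L)
        recs[[length(recs) + 1L]] <- data.frame(
          read_id = sprintf("%s_bg_r%d", s, j), chrom = chr, start = st,
          end = st + rl - 1L, strand = "+",
          seq = mutate_seq(substr(as.character(genome[[chr]]), st, st + rl - 1L),
                           config$error_rate),
          n_sites = 1L, true_site = FALSE)
      }
    }
    df <- do.call(rbind, recs)
    gr <- GenomicRanges::GRanges(
      df$chrom, IRanges::IRanges(df$start, df$end), df$strand,
      seqinfo = GenomeInfoDb::Seqinfo(names(config$genome),
                                      unname(config$genome)))
    gr$read_id <- df$read_id
    gr$n_sites <- df$n_sites
    gr$seq <- df$seq
    gr$true_site <- df$true_site
    gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
    reads_by_sample[[s]] <- gr
    if (!is.null(out_dir)) {
      sam <- file.path(out_dir, paste0(s, ".sam"))
      write_sam(gr, config$genome, sam)
      sam_paths[s] <- sam
      if (emit_fastq) {
        fq <- file.path(out_dir, paste0(s, ".fastq"))
        write_raw_fastq(gr, fq)
        fastq_paths[s] <- fq
      }
    }
  }
  if (!is.null(out_dir)) {
    write_clusters_bed(truth, file.path(out_dir, "truth.bed"))
    utils::write.table(as.data.frame(truth), file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(reads = reads_by_sample, truth = truth, sam_paths = sam_paths,
       fastq_paths = fastq_paths)
}

# Expected call interval and analytic metrics per planted cluster.
make_truth <- function(config) {
  cl <- config$clusters
  exp_start <- exp_end <- integer(nrow(cl))
  exp_cx <- numeric(nrow(cl))
  for (i in seq_len(nrow(cl))) {
    rl <- cl$read_length[i]
    if (cl$shape[i] == "point") {
      exp_start[i] <- cl$start[i]
      exp_end[i] <- cl$start[i] + rl - 1L
      exp_cx[i] <- 0
    } else {
      exp_start[i] <- cl$start[i]
      exp_end[i] <- cl$end[i]
      if (cl$shape[i] == "uniform") {
        S <- cl$end[i] - cl$start[i] + 1L - rl + 1L
        L <- cl$end[i] - cl$start[i] + 1L
        # evenly tiled starts: entropy of the realized (near-)equal counts
        n <- cl$n_reads[i]
        cnt <- tabulate(rep_len(seq_len(S), n), S)
        p <- cnt / n
        exp_cx[i] <- -sum(p[p > 0] * log(p[p > 0])) / log(L)
      } else {
        exp_cx[i] <- NA_real_
      }
    }
  }
  gr <- GenomicRanges::GRanges(cl$chrom, IRanges::IRanges(exp_start, exp_end),
                               cl$strand)
  gr$ugr_id <- sprintf("%s:%d-%d", cl$chrom, exp_start, exp_end)
  gr$n_reads <- cl$n_reads
  gr$shape <- cl$shape
  gr$expected_complexity <- exp_cx
  gr$expected_peak_fraction <- ifelse(cl$shape == "point", 1, NA_real_)
  gr$multimap_copies <- cl$multimap_copies
  gr$annotated_as <- cl$annotated_as
  gr$expected_call <- cl$n_reads >= 100
  gr$weighted_count <- cl$n_reads
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

draw_starts <- function(shape, start, end, read_length, n, sigma) {
  last <- end - read_length + 1L
  switch(shape,
    point = rep(start, n),
    uniform = {
      S <- last - start + 1L
      sort(start - 1L + rep_len(seq_len(S), n))
    },
    gaussian = {
      mid <- as.integer((start + last) / 2)
      st <- as.integer(round(stats::rnorm(n, mid, sigma)))
      pmin(pmax(st, start), last)
    })
}

mutate_seq <- function(seq, error_rate) {
  if (error_rate <= 0) return(seq)
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(s)) < error_rate
  if (any(hit)) {
    s[hit] <- vapply(s[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1))
  }
  paste(s, collapse = "")
}

# Coordinate-sorted SAM with NH tags; one record per alignment site,
# secondary flag on all but the first site of each read.
write_sam <- function(gr, genome_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome_lengths),
                   unname(genome_lengths)))
  first_site <- !duplicated(gr$read_id)
  flag <- ifelse(as.character(GenomicRanges::strand(gr)) == "-", 16L, 0L) +
    ifelse(first_site, 0L, 256L)
  w <- GenomicRanges::width(gr)
  lines <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s\tNH:i:%d",
                   gr$read_id, flag,
                   as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr), w, gr$seq,
                   strrep("I", w), gr$n_sites)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

# Raw FASTQ with the 5' triad and 3' poly-A adapter re-attached, so the
# trimming stage can be exercised end to end.
write_raw_fastq <- function(gr, path) {
  first_site <- !duplicated(gr$read_id)
  g <- gr[first_site]
  recs <- data.frame(
    id = g$read_id,
    sequence = paste0("GGG", g$seq, "AAAAAAAAAA"),
    qualities = strrep("I", nchar(g$seq) + 13L))
  write_fastq(recs, path)
}
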