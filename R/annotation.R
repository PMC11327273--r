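#' Build an annotation index from a GTF/GFF gene model
#'
#' Imports gene, exon and CDS features, recovers the gene biotype
#' (\code{gene_biotype} or \code{gene_type} attribute; \code{"unknown"} when
#' absent), and derives intron intervals as each gene's span minus its exons.
#' When the file carries no explicit \code{gene} features, gene spans are
#' reconstructed as the per-gene range of the sub-features.
#'
#' @param gtf Path to a GTF/GFF file (Ensembl/GENCODE dialects).
#' @return List with \code{GRanges} elements \code{genes}, \code{exons},
#'   \code{cds}, \code{introns}; each carries \code{gene_id},
#'   \code{gene_name}, \code{biotype}.
#' @export
build_annotation_index <- function(gtf) {
  fmt <- if (grepl("\\.gff3?(\\.gz)?$", gtf, ignore.case = TRUE)) "gff3" else "gtf"
  feats <- rtracklayer::import(sanitize_gtf(gtf), format = fmt)
  mc <- S4Vectors::mcols(feats)
  biotype <- if (!is.null(mc$gene_biotype)) mc$gene_biotype
             else if (!is.null(mc$gene_type)) mc$gene_type
             else rep(NA_character_, length(feats))
  if (anyNA(biotype)) {
    warning(sum(is.na(biotype)), " feature(s) without a biotype attribute; ",
            "indexed as 'unknown'")
    biotype[is.na(biotype)] <- "unknown"
  }
  gene_id <- if (!is.null(mc$gene_id)) mc$gene_id else rep(NA_character_, length(feats))
  gene_name <- if (!is.null(mc$gene_name)) mc$gene_name else gene_id
  keep_cols <- function(g, sel) {
    g <- g[sel]
    S4Vectors::mcols(g) <- S4Vectors::DataFrame(
      gene_id = gene_id[sel], gene_name = gene_name[sel],
      biotype = biotype[sel])
    g
  }
  type <- as.character(feats$type)
  genes <- keep_cols(feats, type == "gene")
  exons <- keep_cols(feats, type == "exon")
  cds <- keep_cols(feats, type == "CDS")
  if (length(genes) == 0L && length(exons) > 0L) {
    spl <- split(exons, exons$gene_id)
    genes <- unlist(range(spl), use.names = FALSE)
    first <- !duplicated(exons$gene_id)
    S4Vectors::mcols(genes) <- S4Vectors::DataFrame(
      gene_id = exons$gene_id[first][match(names(spl), exons$gene_id[first])],
      gene_name = exons$gene_name[first][match(names(spl), exons$gene_id[first])],
      biotype = exons$biotype[first][match(names(spl), exons$gene_id[first])])
  }
  introns <- derive_introns(genes, exons)
  list(genes = genes, exons = exons, cds = cds, introns = introns)
}

# Drop lines without the 9 tab-separated GTF fields (warning with line
# numbers) so one malformed record does not abort the import.
sanitize_gtf <- function(gtf) {
  lines <- readLines(gtf)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  bad <- body & nf < 9L
  if (!any(bad)) return(gtf)
  warning("skipping ", sum(bad), " malformed GTF line(s): ",
          paste(utils::head(which(bad), 5L), collapse = ", "))
  tmp <- tempfile(fileext = ".gtf")
  writeLines(lines[!bad], tmp)
  tmp
}

derive_introns <- function(genes, exons) {
  if (length(genes) == 0L || length(exons) == 0L) {
    g <- GenomicRanges::GRanges()
    S4Vectors::mcols(g) <- S4Vectors::DataFrame(gene_id = character(0),
                                                gene_name = character(0),
                                                biotype = character(0))
    return(g)
  }
  out <- list()
  for (i in seq_along(genes)) {
    gid <- genes$gene_id[i]
    ex <- exons[exons$gene_id == gid]
    if (length(ex) == 0L) next
    intr <- GenomicRanges::setdiff(genes[i], GenomicRanges::reduce(ex),
                                   ignore.strand = FALSE)
    if (length(intr)) {
      S4Vectors::mcols(intr) <- S4Vectors::DataFrame(
        gene_id = gid, gene_name = genes$gene_name[i],
        biotype = genes$biotype[i])
      out[[length(out) + 1L]] <- intr
    }
  }
  if (!length(out)) return(derive_introns(GenomicRanges::GRanges(), GenomicRanges::GRanges()))
  unlist(GenomicRanges::GRangesList(out), use.names = FALSE)
}

# Fixed tie-break priority: small RNA classes first (miRNA genes commonly nest
# inside host genes), then lincRNA, protein_coding, pseudogene classes.
biotype_priority <- function(biotypes) {
  order_list <- c("miRNA", "snoRNA", "snRNA", "rRNA", "tRNA", "Mt_tRNA",
                  "misc_RNA", "lincRNA", "lncRNA", "protein_coding")
  rank <- match(biotypes, order_list)
  pseud <- grepl("pseudogene", biotypes)
  rank[is.na(rank) & pseud] <- length(order_list) + 1L
  rank[is.na(rank)] <- length(order_list) + 2L
  rank
}

#' Annotate clusters against a gene model
#'
#' Labels each cluster \code{annotated} when it overlaps any gene feature by
#' at least 1 bp (strand-aware only in stranded mode), else
#' \code{unannotated}. The biotype comes from the gene with the largest
#' overlap; ties fall to a fixed priority favoring small RNA classes
#' (miRNA > snoRNA > snRNA > rRNA > tRNA > lincRNA > protein_coding >
#' pseudogenes > other), then alphabetical order.
#'
#' @param clusters \code{GRanges} of called clusters (with \code{ugr_id}).
#' @param index Annotation index from \code{\link{build_annotation_index}}.
#' @param stranded Require matching strand for an overlap (default
#'   \code{FALSE}).
#' @return \code{clusters} with added columns \code{status}, \code{biotype},
#'   \code{gene_id}, \code{gene_name}, \code{overlap_bp},
#'   \code{overlap_fraction}.
#' @export
annotate_clusters <- function(clusters, index, stranded = FALSE) {
  n <- length(clusters)
  status <- rep("unannotated", n)
  biotype <- rep("unannotated", n)
  gene_id <- gene_name <- rep(NA_character_, n)
  overlap_bp <- integer(n)
  genes <- index$genes
  if (length(genes) > 0L && n > 0L) {
    hits <- GenomicRanges::findOverlaps(clusters, genes,
                                        ignore.strand = !stranded)
    if (length(hits)) {
      ov <- GenomicRanges::pintersect(
        clusters[S4Vectors::queryHits(hits)],
        genes[S4Vectors::subjectHits(hits)], ignore.strand = !stranded)
      ow <- GenomicRanges::width(ov)
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      for (i in unique(qh)) {
        sel <- which(qh == i)
        cand <- sh[sel]
        w <- ow[sel]
        best <- which(w == max(w))
        if (length(best) > 1L) {
          bt <- genes$biotype[cand[best]]
          best <- best[order(biotype_priority(bt), bt)][1L]
        }
        j <- cand[best]
        status[i] <- "annotated"
        biotype[i] <- genes$biotype[j]
        gene_id[i] <- genes$gene_id[j]
        gene_name[i] <- genes$gene_name[j]
        overlap_bp[i] <- max(w)
      }
    }
  }
  clusters$status <- status
  clusters$biotype <- biotype
  clusters$gene_id <- gene_id
  clusters$gene_name <- gene_name
  clusters$overlap_bp <- overlap_bp
  clusters$overlap_fraction <- ifelse(GenomicRanges::width(clusters) > 0,
                                      overlap_bp / GenomicRanges::width(clusters), 0)
  clusters
}

#' Per-biotype molecule and expression summary
#'
#' Aggregates a count matrix by cluster biotype: number of clusters, total
#' molecules after library-size adjustment (counts scaled to the mean library
#' size), and mean RPKM (count per kb of locus length per million library
#' reads). The \code{"unannotated"} biotype appears as its own row, enabling
#' a rank-by-expression comparison of unannotated loci against annotated
#' classes.
#'
#' @param clusters Annotated clusters (with \code{ugr_id}, \code{biotype}).
#' @param counts Count matrix from \code{\link{quantify_clusters}} (rows =
#'   \code{ugr_id}) with a \code{library_sizes} attribute, or a plain matrix
#'   plus \code{library_sizes}.
#' @param library_sizes Per-sample library sizes; taken from
#'   \code{attr(counts, "library_sizes")} when missing.
#' @return data.frame with \code{biotype}, \code{n_ugrs},
#'   \code{total_molecules_adj}, \code{mean_rpkm}, sorted by decreasing mean
#'   RPKM.
#' @export
biotype_summary <- function(clusters, counts, library_sizes = NULL) {
  if (is.null(library_sizes)) library_sizes <- attr(counts, "library_sizes")
  stopifnot(!is.null(library_sizes), ncol(counts) == length(library_sizes))
  m <- counts[match(clusters$ugr_id, rownames(counts)), , drop = FALSE]
  stopifnot(!anyNA(m))
  len_kb <- GenomicRanges::width(clusters) / 1e3
  libM <- library_sizes / 1e6
  rpkm <- sweep(m / len_kb, 2L, libM, "/")
  adj <- sweep(m, 2L, mean(library_sizes) / library_sizes, "*")
  bt <- clusters$biotype
  out <- do.call(rbind, lapply(split(seq_along(bt), bt), function(idx) {
    data.frame(biotype = bt[idx[1L]],
               n_ugrs = length(idx),
               total_counts = sum(m[idx, , drop = FALSE]),
               total_molecules_adj = sum(adj[idx, , drop = FALSE]),
               mean_rpkm = mean(rpkm[idx, , drop = FALSE]))
  }))
  rownames(out) <- NULL
  out[order(-out$mean_rpkm), ]
}
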