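#' Run the full cluster-discovery pipeline
#'
#' Executes the stages in order — load alignments, redistribute multi-mapped
#' reads, call clusters (pooled across samples by default), characterize,
#' optionally annotate against a gene model, and quantify every sample
#' against the unified cluster set — and writes a run manifest capturing
#' parameters, input checksums and per-stage record counts.
#'
#' In pooled mode (default) reads from all samples are pooled to define one
#' shared locus set, matching the construction of a single average de novo
#' assembled small RNA landscape with one count matrix; \code{per_sample =
#' TRUE} instead calls clusters per sample and unions the overlapping
#' intervals.
#'
#' @param alignment_files Named character vector of SAM/BAM paths, one per
#'   sample (names become sample ids; basenames are used when unnamed).
#' @param gtf Optional annotation GTF/GFF for biotype labeling.
#' @param max_sites,rescue_window Multimap handling, see
#'   \code{\link{load_alignments}} and \code{\link{rescue_multimapped}}.
#' @param min_gap,min_reads,stranded,count_mode Caller settings, see
#'   \code{\link{call_clusters}}.
#' @param per_sample Call per sample and merge instead of pooling.
#' @param cpm_threshold,min_samples Expression filter, see
#'   \code{\link{filter_expressed}}.
#' @param out_dir Optional output directory for BED/TSV/manifest files.
#' @return List with \code{clusters} (characterized, annotated when a GTF is
#'   given), \code{counts}, \code{counts_filtered}, \code{reads} (per-sample
#'   weighted \code{GRanges}) and \code{manifest}.
#' @export
run_pipeline <- function(alignment_files, gtf = NULL,
                         max_sites = 15L, rescue_window = 0L,
                         min_gap = 75L, min_reads = 100,
                         stranded = FALSE, count_mode = "weighted",
                         per_sample = FALSE,
                         cpm_threshold = 10, min_samples = 1L,
                         out_dir = NULL) {
  if (is.null(names(alignment_files))) {
    names(alignment_files) <- tools::file_path_sans_ext(basename(alignment_files))
  }
  stopifnot(all(file.exists(alignment_files)))
  if (!is.null(gtf) && !file.exists(gtf)) {
    stop("configuration error: annotation file not found: ", gtf)
  }

  stage_counts <- list()
  reads <- lapply(alignment_files, function(f) {
    aln <- load_alignments(f, max_sites = max_sites)
    rescue_multimapped(aln, rescue_window = rescue_window)
  })
  stage_counts$reads_retained <- vapply(reads, function(g)
    length(unique(g$read_id)), integer(1))
  stage_counts$sites_discarded_max_sites <- vapply(reads, function(g)
    S4Vectors::metadata(g)$n_discarded_max_sites, integer(1))

  if (per_sample) {
    sets <- lapply(reads, call_clusters, min_gap = min_gap,
                   min_reads = min_reads, stranded = stranded,
                   count_mode = count_mode)
    clusters <- merge_cluster_sets(sets, stranded = stranded)
  } else {
    pooled <- unlist(GenomicRanges::GRangesList(lapply(reads, function(g) {
      S4Vectors::mcols(g) <- S4Vectors::mcols(g)[c("read_id", "n_sites",
                                                   "seq", "weight")]
      g
    })), use.names = FALSE)
    clusters <- call_clusters(pooled, min_gap = min_gap,
                              min_reads = min_reads, stranded = stranded,
                              count_mode = count_mode)
  }
  stage_counts$clusters_called <- length(clusters)

  pooled_reads <- unlist(GenomicRanges::GRangesList(lapply(reads, function(g) {
    S4Vectors::mcols(g) <- S4Vectors::mcols(g)[c("read_id", "n_sites",
                                                 "seq", "weight")]
    g
  })), use.names = FALSE)
  clusters <- cluster_metrics(clusters, pooled_reads)

  if (!is.null(gtf)) {
    idx <- build_annotation_index(gtf)
    clusters <- annotate_clusters(clusters, idx, stranded = stranded)
    stage_counts$clusters_annotated <- sum(clusters$status == "annotated")
    stage_counts$clusters_unannotated <- sum(clusters$status == "unannotated")
  }

  counts <- quantify_clusters(reads, clusters)
  counts_filtered <- filter_expressed(counts, cpm_threshold = cpm_threshold,
                                      min_samples = min_samples)
  stage_counts$clusters_expressed <- attr(counts_filtered, "n_kept")

  manifest <- list(
    tool = paste0("smrclust ", as.character(utils::packageVersion("smrclust"))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = list(max_sites = max_sites, rescue_window = rescue_window,
                      min_gap = min_gap, min_reads = min_reads,
                      stranded = stranded, count_mode = count_mode,
                      per_sample = per_sample, cpm_threshold = cpm_threshold,
                      min_samples = min_samples),
    inputs = lapply(stats::setNames(nm = names(alignment_files)), function(s)
      list(path = unname(alignment_files[s]),
           md5 = unname(tools::md5sum(alignment_files[s])))),
    gtf = gtf,
    stage_counts = stage_counts)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_clusters_bed(clusters, file.path(out_dir, "clusters.bed"))
    cdf <- as.data.frame(clusters)
    for (cc in names(cdf)) {   # flatten list columns (e.g. contributing samples)
      if (is.list(cdf[[cc]])) {
        cdf[[cc]] <- vapply(cdf[[cc]], paste, character(1), collapse = ",")
      }
    }
    utils::write.table(cdf, file.path(out_dir, "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_count_matrix(counts, file.path(out_dir, "counts.tsv"))
    write_count_matrix(counts_filtered,
                       file.path(out_dir, "counts_filtered.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(clusters = clusters, counts = counts,
       counts_filtered = counts_filtered, reads = reads,
       manifest = manifest)
}
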