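#' Filter CLIP peaks to significance
#'
#' Keeps peaks at least `min_fold`-enriched over input with an enrichment
#' p-value strictly below `max_p` (sub-threshold peaks are removed; the
#' fold boundary is inclusive, the p boundary exclusive).
#'
#' @param peaks data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `fold_enrichment`, `p_value`, `sample_id`.
#' @param min_fold minimum fold enrichment (default 8).
#' @param max_p exclusive p-value bound (default 1e-5).
#' @return the filtered peak data.frame. Idempotent.
#' @export
filter_peaks <- function(peaks, min_fold = 8, max_p = 1e-5) {
  stopifnot(all(c("fold_enrichment", "p_value") %in% names(peaks)))
  bad_fold <- which(peaks$fold_enrichment < 0 | !is.finite(peaks$fold_enrichment))
  if (length(bad_fold))
    stop("negative or non-finite fold_enrichment in peak record ", bad_fold[1])
  bad_p <- which(!(peaks$p_value > 0 & peaks$p_value <= 1))
  if (length(bad_p))
    stop("p_value outside (0,1] in peak record ", bad_p[1])
  if (any(peaks$end <= peaks$start)) stop("peak with end <= start")
  peaks[peaks$fold_enrichment >= min_fold & peaks$p_value < max_p, ,
        drop = FALSE]
}

#' Intersect peaks with gene spans
#'
#' A peak is assigned to every gene whose intron-inclusive genomic span it
#' overlaps by at least one nucleotide (strand-agnostic, half-open
#' intervals: a touching peak does not overlap). Peaks on chromosomes
#' absent from the annotation are skipped with a message.
#'
#' @param peaks peak data.frame (see [filter_peaks()]); pass filtered peaks
#'   to obtain significance-based binding summaries.
#' @param models a [transcript_models] object (or a data.frame of gene
#'   spans as returned by [gene_spans()]).
#' @param exonic_only if `TRUE`, intersect against exon intervals instead
#'   of whole gene spans.
#' @return data.frame with `gene_id`, `n_peaks_total`,
#'   `n_samples_with_peak` for every gene in the annotation (zeros
#'   included).
#' @export
overlap_genes <- function(peaks, models, exonic_only = FALSE) {
  if (inherits(models, "transcript_models")) {
    spans <- if (exonic_only) {
      exmap <- merge(models$exons,
                     models$transcripts[, c("transcript_id", "gene_id", "chrom")],
                     by = "transcript_id")
      exmap[, c("gene_id", "chrom", "start", "end")]
    } else gene_spans(models)
  } else spans <- models
  all_genes <- unique(spans$gene_id)
  unknown <- !peaks$chrom %in% unique(spans$chrom)
  if (any(unknown)) {
    message(sum(unknown), " peaks on unknown chromosomes skipped")
    peaks <- peaks[!unknown, , drop = FALSE]
  }
  if (nrow(peaks)) {
    pgr <- GenomicRanges::GRanges(
      seqnames = peaks$chrom,
      ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end))
    ggr <- GenomicRanges::GRanges(
      seqnames = spans$chrom,
      ranges = IRanges::IRanges(start = spans$start + 1L, end = spans$end))
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(pgr, ggr, minoverlap = 1L,
                                  ignore.strand = TRUE))
    assign_df <- data.frame(
      gene_id = spans$gene_id[S4Vectors::subjectHits(hits)],
      sample_id = peaks$sample_id[S4Vectors::queryHits(hits)],
      stringsAsFactors = FALSE)
  } else {
    assign_df <- data.frame(gene_id = character(), sample_id = character())
  }
  dt <- data.table::as.data.table(assign_df)
  agg <- dt[, list(n_peaks_total = .N,
                   n_samples_with_peak = length(unique(sample_id))),
            by = "gene_id"]
  out <- data.frame(gene_id = all_genes, stringsAsFactors = FALSE)
  m <- match(out$gene_id, agg$gene_id)
  out$n_peaks_total <- ifelse(is.na(m), 0L, agg$n_peaks_total[m])
  out$n_samples_with_peak <- ifelse(is.na(m), 0L, agg$n_samples_with_peak[m])
  out
}

#' Partition labeled genes by CLIP binding evidence
#'
#' @param labels output of [assign_labels()].
#' @param summaries output of [overlap_genes()] computed from *filtered*
#'   peaks.
#' @return list with character vectors `dpp_clip` (DPPs with a significant
#'   peak in at least one sample), `ndp_noclip` (NDPs with none) and
#'   `unp_clip`.
#' @export
partition_by_binding <- function(labels, summaries) {
  m <- match(labels$gene_id, summaries$gene_id)
  n_samp <- ifelse(is.na(m), 0L, summaries$n_samples_with_peak[m])
  list(
    dpp_clip   = labels$gene_id[labels$label == "DPP" & n_samp >= 1L],
    ndp_noclip = labels$gene_id[labels$label == "NDP" & n_samp == 0L],
    unp_clip   = labels$gene_id[labels$label == "UNP" & n_samp >= 1L])
}
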