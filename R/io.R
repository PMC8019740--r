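#' @name io
#' @title Readers and writers for the pipeline's plain-text formats
#' @description All genomic coordinates are 0-based half-open in memory;
#'   GTF-like files (1-based inclusive) and BED-like files (0-based
#'   half-open) are converted on read/write. Tables are TSV with header.
NULL

#' Write / read a TSV table
#' @param x data.frame.
#' @param path file path.
#' @rdname io
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
}

#' Write transcript models as a GTF-like file
#' @param models a [transcript_models] object.
#' @rdname io
#' @export
write_gtf <- function(models, path) {
  tx <- models$transcripts
  ex <- merge(models$exons,
              tx[, c("transcript_id", "gene_id", "chrom", "strand")],
              by = "transcript_id")
  attr_str <- function(g, t) sprintf('gene_id "%s"; transcript_id "%s";', g, t)
  spdt <- data.table::as.data.table(models$exons)[
    , list(start = min(start), end = max(end)), by = "transcript_id"]
  sp <- as.data.frame(spdt)
  sp <- merge(sp, tx, by = "transcript_id")
  rows <- rbind(
    data.frame(seqname = sp$chrom, feature = "transcript",
               start = sp$start + 1L, end = sp$end, strand = sp$strand,
               attribute = attr_str(sp$gene_id, sp$transcript_id)),
    data.frame(seqname = ex$chrom, feature = "exon",
               start = ex$start + 1L, end = ex$end, strand = ex$strand,
               attribute = attr_str(ex$gene_id, ex$transcript_id)),
    data.frame(seqname = tx$chrom, feature = "CDS",
               start = tx$cds_start + 1L, end = tx$cds_end,
               strand = tx$strand,
               attribute = attr_str(tx$gene_id, tx$transcript_id)))
  rows <- rows[order(rows$seqname, rows$start, rows$attribute,
                     factor(rows$feature, c("transcript", "exon", "CDS"))), ]
  out <- data.frame(rows$seqname, "rbpcall", rows$feature, rows$start,
                    rows$end, ".", rows$strand, ".", rows$attribute)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_gtf <- function(path) {
  g <- as.data.frame(data.table::fread(
    path, sep = "\t", header = FALSE,
    col.names = c("seqname", "source", "feature", "start", "end",
                  "score", "strand", "frame", "attribute")))
  att <- function(field) {
    m <- regmatches(g$attribute,
                    regexpr(paste0(field, ' "[^"]+"'), g$attribute))
    sub(paste0(field, ' "([^"]+)"'), "\\1", m)
  }
  g$gene_id <- att("gene_id")
  g$transcript_id <- att("transcript_id")
  cds <- g[g$feature == "CDS", ]
  exon <- g[g$feature == "exon", ]
  tx <- data.frame(transcript_id = cds$transcript_id,
                   gene_id = cds$gene_id, chrom = cds$seqname,
                   strand = cds$strand,
                   cds_start = cds$start - 1L, cds_end = cds$end,
                   stringsAsFactors = FALSE)
  exons <- data.frame(transcript_id = exon$transcript_id,
                      start = exon$start - 1L, end = exon$end,
                      stringsAsFactors = FALSE)
  transcript_models(tx, exons)
}

#' Write peaks as BED6+2 (columns 7-8: fold_enrichment, p-value column)
#' @param peaks peak data.frame.
#' @param p_col `"neglog10p"` (default; column 8 holds -log10 p) or `"p"`.
#' @rdname io
#' @export
write_peaks_bed <- function(peaks, path, p_col = c("neglog10p", "p")) {
  p_col <- match.arg(p_col)
  col8 <- if (p_col == "neglog10p") -log10(peaks$p_value) else peaks$p_value
  out <- data.frame(peaks$chrom, peaks$start, peaks$end,
                    if ("name" %in% names(peaks)) peaks$name else ".",
                    0L, peaks$strand, peaks$fold_enrichment, col8)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @param sample_id sample label attached to every peak read from `path`.
#' @param fold_scale `"linear"` (default) or `"log2"` if column 7 holds
#'   log2 fold enrichments.
#' @rdname io
#' @export
read_peaks_bed <- function(path, sample_id, p_col = c("neglog10p", "p"),
                           fold_scale = c("linear", "log2")) {
  p_col <- match.arg(p_col); fold_scale <- match.arg(fold_scale)
  b <- as.data.frame(data.table::fread(
    path, sep = "\t", header = FALSE,
    col.names = c("chrom", "start", "end", "name", "score", "strand",
                  "fold_enrichment", "p8")))
  fold <- if (fold_scale == "log2") 2^b$fold_enrichment else b$fold_enrichment
  p <- if (p_col == "neglog10p") 10^(-b$p8) else b$p8
  data.frame(chrom = b$chrom, start = b$start, end = b$end,
             name = b$name, strand = b$strand, fold_enrichment = fold,
             p_value = p, sample_id = sample_id, stringsAsFactors = FALSE)
}

#' Write / read 3'UTR sequences as FASTA keyed by transcript_id
#' @param seqs named character vector of RNA/DNA sequences.
#' @rdname io
#' @export
write_utr3_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::RNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname io
#' @export
read_utr3_fasta <- function(path) {
  x <- Biostrings::readRNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
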