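#' Transcript model set
#'
#' Container for gene/transcript structures on genomic coordinates. All
#' coordinates are 0-based half-open (BED convention); GTF-like files are
#' converted on read/write.
#'
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `strand` (`"+"`/`"-"`), `cds_start`, `cds_end` (genomic bounds
#'   of the coding region, 0-based half-open).
#' @param exons data.frame with columns `transcript_id`, `start`, `end`;
#'   exons of one transcript must be sorted and non-overlapping.
#' @return An object of class `transcript_models`.
#' @export
transcript_models <- function(transcripts, exons) {
  req_tx <- c("transcript_id", "gene_id", "chrom", "strand", "cds_start", "cds_end")
  req_ex <- c("transcript_id", "start", "end")
  stopifnot(all(req_tx %in% names(transcripts)), all(req_ex %in% names(exons)))
  if (anyDuplicated(transcripts$transcript_id))
    stop("duplicated transcript_id in transcript table")
  if (!all(transcripts$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(exons$end <= exons$start))
    stop("exon with end <= start")
  ex <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  # non-overlap within transcript
  same <- ex$transcript_id[-1] == ex$transcript_id[-nrow(ex)]
  if (nrow(ex) > 1 && any(same & ex$start[-1] < ex$end[-nrow(ex)]))
    stop("overlapping or unsorted exons within a transcript")
  obj <- structure(list(transcripts = as.data.frame(transcripts),
                        exons = as.data.frame(ex)),
                   class = "transcript_models")
  .check_cds(obj)
  obj
}

#' @export
print.transcript_models <- function(x, ...) {
  cat(sprintf("transcript_models: %d transcripts, %d genes, %d exons\n",
              nrow(x$transcripts), length(unique(x$transcripts$gene_id)),
              nrow(x$exons)))
  invisible(x)
}

.check_cds <- function(models) {
  tx <- models$transcripts
  for (i in seq_len(nrow(tx))) {
    ex <- .tx_exons(models, tx$transcript_id[i])
    cs <- tx$cds_start[i]; ce <- tx$cds_end[i]
    if (ce <= cs) stop("CDS end <= CDS start for ", tx$transcript_id[i])
    if (is.na(.genomic_to_tx(cs, ex, "+")) || is.na(.genomic_to_tx(ce - 1L, ex, "+")))
      stop("CDS outside exons for transcript ", tx$transcript_id[i])
  }
  invisible(TRUE)
}

.tx_exons <- function(models, transcript_id) {
  ex <- models$exons[models$exons$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(ex) == 0L) stop("no exons for transcript ", transcript_id)
  ex[order(ex$start), , drop = FALSE]
}

# genomic position(s) -> transcript coordinate (0-based from transcript 5' end),
# NA for intronic/intergenic. `exons` sorted ascending, 0-based half-open.
.genomic_to_tx <- function(gpos, exons, strand) {
  w <- exons$end - exons$start
  mature <- sum(w)
  cb <- cumsum(c(0L, w[-length(w)]))
  idx <- findInterval(gpos, exons$start)
  off <- rep(NA_integer_, length(gpos))
  ok <- idx >= 1L
  oki <- which(ok)
  if (length(oki)) {
    inblk <- gpos[oki] < exons$end[idx[oki]]
    oki <- oki[inblk]
    off[oki] <- cb[idx[oki]] + (gpos[oki] - exons$start[idx[oki]])
  }
  if (strand == "-") off <- mature - 1L - off
  off
}

# transcript coordinate(s) -> genomic position; txpos must lie in [0, mature)
.tx_to_genomic <- function(txpos, exons, strand) {
  w <- exons$end - exons$start
  mature <- sum(w)
  if (any(txpos < 0L | txpos >= mature)) stop("transcript coordinate out of range")
  offp <- if (strand == "-") mature - 1L - txpos else txpos
  cb <- cumsum(c(0L, w[-length(w)]))
  idx <- findInterval(offp, cb)
  exons$start[idx] + (offp - cb[idx])
}

#' Genomic span of every gene
#'
#' Union span (intron-inclusive) of all transcripts of each gene, used for
#' strand-agnostic peak/gene intersection.
#'
#' @param models a [transcript_models] object.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @export
gene_spans <- function(models) {
  ex <- data.table::as.data.table(models$exons)
  map <- data.table::as.data.table(
    models$transcripts[, c("transcript_id", "gene_id", "chrom")])
  dt <- merge(ex, map, by = "transcript_id")
  out <- dt[, list(chrom = chrom[1L], start = min(start), end = max(end)),
            by = "gene_id"]
  as.data.frame(out)
}

#' Exonic 5'UTR / CDS / 3'UTR lengths of one transcript
#'
#' Lengths are exonic (introns excluded) and strand-aware: on the minus
#' strand the 3'UTR is the exonic sequence genomically 5'-ward of the CDS.
#'
#' @param models a [transcript_models] object.
#' @param transcript_id transcript to measure.
#' @return named numeric `c(utr5=, cds=, utr3=)` in nucleotides.
#' @export
utr_lengths <- function(models, transcript_id) {
  i <- match(transcript_id, models$transcripts$transcript_id)
  if (is.na(i)) stop("unknown transcript ", transcript_id)
  tx <- models$transcripts[i, ]
  ex <- .tx_exons(models, transcript_id)
  before <- sum(pmax(0L, pmin(ex$end, tx$cds_start) - ex$start))
  within <- sum(pmax(0L, pmin(ex$end, tx$cds_end) - pmax(ex$start, tx$cds_start)))
  after  <- sum(pmax(0L, ex$end - pmax(ex$start, tx$cds_end)))
  if (tx$strand == "+") c(utr5 = before, cds = within, utr3 = after)
  else                  c(utr5 = after,  cds = within, utr3 = before)
}

#' Region lengths for all transcripts
#'
#' @param models a [transcript_models] object.
#' @return data.frame with `transcript_id`, `gene_id`, `strand`, `utr5`,
#'   `cds`, `utr3`, `mature`.
#' @export
transcript_regions <- function(models) {
  ex <- data.table::as.data.table(models$exons)
  info <- data.table::as.data.table(
    models$transcripts[, c("transcript_id", "gene_id", "strand",
                           "cds_start", "cds_end")])
  dt <- merge(ex, info, by = "transcript_id")
  dt[, `:=`(
    before = pmax(0L, pmin(end, cds_start) - start),
    within = pmax(0L, pmin(end, cds_end) - pmax(start, cds_start)),
    after  = pmax(0L, end - pmax(start, cds_end)))]
  agg <- dt[, list(gene_id = gene_id[1L], strand = strand[1L],
                   before = sum(before), cds = sum(within), after = sum(after)),
            by = "transcript_id"]
  agg[, `:=`(utr5 = ifelse(strand == "+", before, after),
             utr3 = ifelse(strand == "+", after, before))]
  agg[, mature := utr5 + cds + utr3]
  as.data.frame(agg[, c("transcript_id", "gene_id", "strand",
                        "utr5", "cds", "utr3", "mature"), with = FALSE])
}

#' Maximum 3'UTR length per gene
#'
#' For each gene, the longest exonic 3'UTR over its transcripts (the
#' representative-isoform rule used throughout the 3'UTR feature
#' comparisons).
#'
#' @param models a [transcript_models] object.
#' @param genes optional character vector restricting the output.
#' @return data.frame with `gene_id`, `max_utr3`, and `transcript_id` of the
#'   longest-3'UTR transcript (ties broken by transcript_id).
#' @export
max_utr3 <- function(models, genes = NULL) {
  reg <- transcript_regions(models)
  reg <- reg[order(reg$gene_id, -reg$utr3, reg$transcript_id), ]
  top <- reg[!duplicated(reg$gene_id), c("gene_id", "utr3", "transcript_id")]
  names(top)[2] <- "max_utr3"
  if (!is.null(genes)) {
    top <- top[match(genes, top$gene_id), ]
    if (anyNA(top$gene_id)) stop("genes absent from annotation")
  }
  rownames(top) <- NULL
  top
}
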