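#' Count m6A sites per gene (maximum-transcript rule)
#'
#' Sites are matched to transcripts by exonic position (intronic sites are
#' not counted); each gene is assigned the site count of its
#' maximally-modified transcript.
#'
#' @param sites data.frame with columns `chrom`, `pos` (0-based genomic
#'   position) and optionally `strand` (`"."`/`"*"` matches both strands).
#' @param models a [transcript_models] object.
#' @param genes optional character vector of genes to report (others are
#'   dropped); defaults to all genes in the annotation.
#' @return data.frame with `gene_id` and `m6a_sites`; genes without any
#'   exonic site get 0.
#' @export
m6a_counts <- function(sites, models, genes = NULL) {
  tx <- models$transcripts
  if (is.null(genes)) genes <- unique(tx$gene_id)
  exmap <- merge(models$exons,
                 tx[, c("transcript_id", "chrom", "strand")],
                 by = "transcript_id")
  exgr <- GenomicRanges::GRanges(
    seqnames = exmap$chrom,
    ranges = IRanges::IRanges(start = exmap$start + 1L, end = exmap$end),
    strand = exmap$strand)
  sstrand <- if ("strand" %in% names(sites)) {
    ifelse(sites$strand %in% c("+", "-"), sites$strand, "*")
  } else "*"
  sgr <- GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$pos + 1L, width = 1L),
    strand = sstrand)
  common <- intersect(as.character(GenomicRanges::seqnames(sgr)),
                      as.character(GenomicRanges::seqnames(exgr)))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(sgr, exgr, ignore.strand = FALSE))
  per_tx <- table(exmap$transcript_id[S4Vectors::subjectHits(hits)])
  cnt <- data.frame(transcript_id = names(per_tx),
                    n = as.integer(per_tx), stringsAsFactors = FALSE)
  cnt <- merge(cnt, tx[, c("transcript_id", "gene_id")], by = "transcript_id")
  per_gene <- if (nrow(cnt)) tapply(cnt$n, cnt$gene_id, max) else integer()
  out <- data.frame(gene_id = genes,
                    m6a_sites = as.integer(per_gene[genes]),
                    stringsAsFactors = FALSE)
  out$m6a_sites[is.na(out$m6a_sites)] <- 0L
  out
}

#' @rdname m6a_counts
#' @param gene a single gene_id.
#' @export
m6a_count <- function(gene, sites, models) {
  m6a_counts(sites, models, genes = gene)$m6a_sites
}

.clean_nt <- function(seq) {
  s <- chartr("u", "U", toupper(seq))
  s <- chartr("U", "T", s)
  if (grepl("[^ACGT]", s)) stop("non-nucleotide characters in sequence")
  s
}

#' Scan a 3'UTR for AU-rich elements
#'
#' An ARE call requires at least one AUUUA pentamer whose enclosing 13-nt
#' window (4-nt flanks, shifted inward at sequence edges) has an AU fraction
#' of at least 10/13. Overlapping pentamers are counted individually. T and
#' U are treated identically.
#'
#' @param utr3_seq character string over A/C/G/U/T.
#' @return list with `has_are` (logical) and `n_pentamers` (count of
#'   overlapping AUUUA occurrences).
#' @export
are_scan <- function(utr3_seq) {
  s <- .clean_nt(utr3_seq)
  n <- nchar(s)
  m <- gregexpr("(?=ATTTA)", s, perl = TRUE)[[1]]
  starts <- if (m[1] == -1L) integer() else as.integer(m)
  if (!length(starts))
    return(list(has_are = FALSE, n_pentamers = 0L))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  is_au <- chars %in% c("A", "T")
  has <- FALSE
  for (st in starts) {
    ws <- max(1L, min(st - 4L, n - 12L))
    we <- min(n, ws + 12L)
    frac <- sum(is_au[ws:we]) / (we - ws + 1L)
    if (frac >= 10 / 13 - 1e-12) { has <- TRUE; break }
  }
  list(has_are = has, n_pentamers = length(starts))
}

.IUPAC <- c(A = "A", C = "C", G = "G", T = "T", U = "T",
            R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
            B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

.iupac_regex <- function(motif) {
  chars <- strsplit(toupper(motif), "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(.IUPAC))
  if (length(bad)) stop("unknown IUPAC code: ", paste(bad, collapse = ","))
  paste0(vapply(chars, function(ch) {
    ex <- .IUPAC[[ch]]
    if (nchar(ex) == 1L) ex else paste0("[", ex, "]")
  }, character(1)), collapse = "")
}

#' Per-nucleotide motif densities in a sequence
#'
#' Overlapping matches of each IUPAC 4-mer are counted and normalized by the
#' number of 4-mer positions (`nchar(seq) - 3`).
#'
#' @param seq character string over A/C/G/U/T.
#' @param motifs character vector of IUPAC motifs.
#' @param motif_length required motif length (default 4; deviating motifs
#'   raise an error).
#' @return named numeric vector of densities, one per motif.
#' @export
motif_density <- function(seq, motifs, motif_length = 4L) {
  s <- .clean_nt(seq)
  if (nchar(s) < motif_length) stop("sequence shorter than motif length")
  if (any(nchar(motifs) != motif_length))
    stop("all motifs must have length ", motif_length)
  denom <- nchar(s) - motif_length + 1L
  dens <- vapply(motifs, function(m) {
    rx <- paste0("(?=", .iupac_regex(m), ")")
    hits <- gregexpr(rx, s, perl = TRUE)[[1]]
    n <- if (hits[1] == -1L) 0L else length(hits)
    n / denom
  }, numeric(1))
  names(dens) <- motifs
  dens
}

#' Mann-Whitney comparison of two groups
#'
#' Mid-rank Mann-Whitney U test; the p-value is exact (full enumeration)
#' when the pooled sample size is at most 12 and there are no ties,
#' otherwise the normal approximation with tie and continuity correction is
#' used. Identical pooled values are flagged degenerate with p = 1.
#'
#' @param values_a,values_b numeric vectors (both non-empty).
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (for
#'   `values_a` relative to `values_b`).
#' @return list with `U`, `p_value`, `degenerate`.
#' @export
compare_groups <- function(values_a, values_b,
                           alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(values_a) > 0, length(values_b) > 0)
  pooled <- c(values_a, values_b)
  if (length(unique(pooled)) == 1L) {
    return(list(U = length(values_a) * length(values_b) / 2,
                p_value = 1, degenerate = TRUE))
  }
  exact <- (length(pooled) <= 12L) && !anyDuplicated(pooled)
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, alternative = alternative,
                       exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value, degenerate = FALSE)
}
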