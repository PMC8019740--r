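#' Restrict a differential-expression table to selected biotypes
#'
#' @param table data.frame with at least `gene_id`, `biotype`, `log2fc`,
#'   `fdr`.
#' @param allowed character vector of biotypes to keep (records with any
#'   other biotype string are dropped; a count of dropped unknown biotypes
#'   is reported via `message()`).
#' @return the filtered table, row order preserved.
#' @export
filter_biotype <- function(table, allowed = c("protein_coding", "lincRNA")) {
  stopifnot(nrow(table) > 0, "biotype" %in% names(table))
  known <- c("protein_coding", "lincRNA", "other")
  keep <- table$biotype %in% allowed
  n_unknown <- sum(!table$biotype %in% known & !keep)
  if (n_unknown > 0)
    message(n_unknown, " records with unknown biotype dropped")
  table[keep, , drop = FALSE]
}

#' Classify cross-experiment regulation consistency
#'
#' A gene is called consistently downregulated when its FDR is strictly
#' below `fdr_sig` with a negative log2 fold change in every experiment
#' (symmetrically for upregulation), and consistently unchanged when its
#' FDR is at least `fdr_stable` in every experiment. Genes missing from any
#' table, or meeting none of the three patterns, are `inconsistent`.
#'
#' @param tables list of at least two DEG data.frames (`gene_id`, `log2fc`,
#'   `fdr`).
#' @param fdr_sig significance threshold (strict `<`; default 0.05).
#' @param fdr_stable no-change threshold (`>=`; default 0.95).
#' @return data.frame with `gene_id`, `status` (one of `cons_up`,
#'   `cons_down`, `cons_unchanged`, `inconsistent`) and
#'   `n_experiments_significant`.
#' @export
classify_consistency <- function(tables, fdr_sig = 0.05, fdr_stable = 0.95) {
  stopifnot(length(tables) >= 2,
            fdr_sig > 0, fdr_sig < 1, fdr_stable > 0, fdr_stable < 1,
            fdr_sig < fdr_stable)
  for (i in seq_along(tables)) {
    dup <- tables[[i]]$gene_id[duplicated(tables[[i]]$gene_id)]
    if (length(dup))
      stop("gene duplicated within table ", i, ": ", dup[1])
  }
  genes <- sort(unique(unlist(lapply(tables, `[[`, "gene_id"))))
  k <- length(tables)
  fdr <- lfc <- matrix(NA_real_, nrow = length(genes), ncol = k)
  for (i in seq_len(k)) {
    m <- match(genes, tables[[i]]$gene_id)
    fdr[, i] <- tables[[i]]$fdr[m]
    lfc[, i] <- tables[[i]]$log2fc[m]
  }
  present <- rowSums(is.na(fdr)) == 0L
  sig  <- fdr < fdr_sig
  down <- present & rowSums(sig & lfc < 0, na.rm = TRUE) == k
  up   <- present & rowSums(sig & lfc > 0, na.rm = TRUE) == k
  stab <- present & rowSums(fdr >= fdr_stable, na.rm = TRUE) == k
  status <- rep("inconsistent", length(genes))
  status[stab] <- "cons_unchanged"
  status[down] <- "cons_down"
  status[up]   <- "cons_up"
  data.frame(gene_id = genes, status = status,
             n_experiments_significant = rowSums(sig, na.rm = TRUE),
             stringsAsFactors = FALSE)
}
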