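#' Spearman correlation with explicit degenerate handling
#'
#' Pearson correlation of mid-ranks. A zero-variance rank vector on either
#' side makes the coefficient undefined; `NA` is returned and such cohorts
#' are excluded from sign tallies.
#'
#' @param x,y numeric vectors of equal length (at least 3), finite values.
#' @return Spearman's rho in \[-1, 1\], or `NA_real_` when undefined.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0)
    return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Tally per-cohort correlation signs against the driver gene
#'
#' For each gene, counts tumor cohorts where the Spearman correlation with
#' the driver gene's expression is strictly positive and strictly negative.
#' Undefined correlations (zero variance) and cohorts lacking the gene are
#' excluded from both counts; rho = 0 counts to neither.
#'
#' @param driver gene_id of the driver (must be present in every cohort).
#' @param genes character vector of genes to tally.
#' @param cohorts list of cohort objects, each a list with `cohort_id`,
#'   `expression` (gene x sample matrix with rownames) and `survival`.
#' @return data.frame with `gene_id`, `n_pos`, `n_neg`, `n_used`; the full
#'   gene x cohort rho matrix is attached as attribute `"rho"`.
#' @export
tally_signs <- function(driver, genes, cohorts) {
  rho <- matrix(NA_real_, nrow = length(genes), ncol = length(cohorts),
                dimnames = list(genes,
                                vapply(cohorts, `[[`, "", "cohort_id")))
  n_skipped <- 0L
  for (j in seq_along(cohorts)) {
    expr <- cohorts[[j]]$expression
    if (!driver %in% rownames(expr))
      stop("driver gene absent from cohort ", cohorts[[j]]$cohort_id)
    if (ncol(expr) < 3) next
    d <- expr[driver, ]
    present <- genes[genes %in% rownames(expr)]
    n_skipped <- n_skipped + (length(genes) - length(present))
    if (!length(present)) next
    sub <- expr[present, , drop = FALSE]
    r <- suppressWarnings(
      stats::cor(d, t(sub), method = "spearman")[1, ])
    rho[present, j] <- r
  }
  if (n_skipped > 0)
    message(n_skipped, " gene/cohort combinations skipped (gene absent)")
  out <- data.frame(gene_id = genes,
                    n_pos = rowSums(rho > 0, na.rm = TRUE),
                    n_neg = rowSums(rho < 0, na.rm = TRUE),
                    n_used = rowSums(!is.na(rho)),
                    stringsAsFactors = FALSE)
  attr(out, "rho") <- rho
  out
}

#' Assign UNP / DPP / NDP class labels
#'
#' DPP: consistently downregulated and positively correlated with the
#' driver in at least `min_cohorts` cohorts. UNP: consistently upregulated
#' and negatively correlated in at least `min_cohorts` cohorts. NDP:
#' consistently unchanged, regardless of correlation. Everything else is
#' `unlabeled`.
#'
#' @param calls output of [classify_consistency()].
#' @param tallies output of [tally_signs()] (covering at least the
#'   cons_up/cons_down genes; genes without a tally are treated as having
#'   zero sign counts).
#' @param min_cohorts minimum number of same-sign cohorts (default 20).
#' @return data.frame with `gene_id`, `label` in
#'   `{UNP, DPP, NDP, unlabeled}`.
#' @export
assign_labels <- function(calls, tallies, min_cohorts = 20) {
  m <- match(calls$gene_id, tallies$gene_id)
  n_pos <- ifelse(is.na(m), 0L, tallies$n_pos[m])
  n_neg <- ifelse(is.na(m), 0L, tallies$n_neg[m])
  label <- rep("unlabeled", nrow(calls))
  label[calls$status == "cons_down" & n_pos >= min_cohorts] <- "DPP"
  label[calls$status == "cons_up"   & n_neg >= min_cohorts] <- "UNP"
  label[calls$status == "cons_unchanged"] <- "NDP"
  data.frame(gene_id = calls$gene_id, label = label,
             stringsAsFactors = FALSE)
}
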