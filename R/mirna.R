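#' Multi-database miRNA-target consensus
#'
#' A miRNA-gene pair is retained when predicted by at least `min_dbs`
#' *distinct* databases (duplicate rows from one database count once).
#'
#' @param preds data.frame with `mirna_id`, `gene_id`, `db_name`.
#' @param min_dbs minimum number of distinct supporting databases
#'   (default 2).
#' @param db_names optional character vector of the configured database
#'   labels; any `db_name` outside it is an error.
#' @return data.frame of retained pairs (`mirna_id`, `gene_id`, `n_dbs`).
#' @export
consensus_pairs <- function(preds, min_dbs = 2L, db_names = NULL) {
  stopifnot(all(c("mirna_id", "gene_id", "db_name") %in% names(preds)))
  if (!is.null(db_names)) {
    bad <- setdiff(unique(preds$db_name), db_names)
    if (length(bad)) stop("unknown database name: ", bad[1])
  }
  dt <- unique(data.table::as.data.table(
    preds[, c("mirna_id", "gene_id", "db_name")]))
  agg <- dt[, list(n_dbs = .N), by = c("mirna_id", "gene_id")]
  as.data.frame(agg[agg$n_dbs >= min_dbs, ])
}

#' Select expressed miRNAs across cell lines
#'
#' Replicate CPM values are averaged per cell line first; a miRNA is kept
#' when its per-line mean passes the CPM threshold in at least `min_lines`
#' cell lines. The default direction `"ge"` (mean CPM >= threshold) selects
#' expressed miRNAs; `direction = "lt"` gives the literal below-threshold
#' reading (see the methods vignette for why both exist).
#'
#' @param expr data.frame with `mirna_id`, `cell_line`, `cpm`.
#' @param cpm_threshold CPM cutoff (default 100).
#' @param min_lines minimum number of passing cell lines (default 4).
#' @param direction `"ge"` (default) or `"lt"`.
#' @return character vector of retained miRNA ids.
#' @export
expressed_mirnas <- function(expr, cpm_threshold = 100, min_lines = 4L,
                             direction = c("ge", "lt")) {
  direction <- match.arg(direction)
  stopifnot(all(is.finite(expr$cpm)), all(expr$cpm >= 0))
  dt <- data.table::as.data.table(expr)
  per_line <- dt[, list(mean_cpm = mean(cpm)),
                 by = c("mirna_id", "cell_line")]
  pass <- if (direction == "ge") per_line$mean_cpm >= cpm_threshold
          else per_line$mean_cpm < cpm_threshold
  per_line$pass <- pass
  agg <- per_line[, list(n_pass = sum(pass)), by = "mirna_id"]
  sort(agg$mirna_id[agg$n_pass >= min_lines])
}

#' Per-gene, per-miRNA and per-family targeting counts
#'
#' @param pairs consensus pair data.frame (`mirna_id`, `gene_id`).
#' @param genes gene set to count over (genes without predicted miRNAs get
#'   0).
#' @param mirnas miRNA set to count over (pairs outside it are ignored).
#' @param family_map optional data.frame (`mirna_id`, `family`); family
#'   counts collapse member miRNAs, so a gene targeted by two members of
#'   one family counts once for that family.
#' @return list with data.frames `per_gene` (`gene_id`, `n_mirnas`),
#'   `per_mirna` (`mirna_id`, `n_genes`) and, when `family_map` is given,
#'   `per_family` (`family`, `n_genes`).
#' @export
targeting_counts <- function(pairs, genes, mirnas, family_map = NULL) {
  p <- unique(pairs[pairs$gene_id %in% genes & pairs$mirna_id %in% mirnas,
                    c("mirna_id", "gene_id")])
  per_gene <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  tab <- table(p$gene_id)
  per_gene$n_mirnas <- as.integer(tab[per_gene$gene_id])
  per_gene$n_mirnas[is.na(per_gene$n_mirnas)] <- 0L
  per_mirna <- data.frame(mirna_id = sort(mirnas), stringsAsFactors = FALSE)
  tab2 <- table(p$mirna_id)
  per_mirna$n_genes <- as.integer(tab2[per_mirna$mirna_id])
  per_mirna$n_genes[is.na(per_mirna$n_genes)] <- 0L
  out <- list(per_gene = per_gene, per_mirna = per_mirna)
  if (!is.null(family_map)) {
    pf <- merge(p, family_map, by = "mirna_id")
    pf <- unique(pf[, c("family", "gene_id")])
    tab3 <- table(pf$family)
    fam <- sort(unique(family_map$family))
    per_family <- data.frame(family = fam,
                             n_genes = as.integer(tab3[fam]),
                             stringsAsFactors = FALSE)
    per_family$n_genes[is.na(per_family$n_genes)] <- 0L
    out$per_family <- per_family
  }
  out
}
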