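#' Build a ranked gene list
#'
#' Orders genes by descending score; ties are broken by gene_id
#' (lexicographic) so the ranking is deterministic.
#'
#' @param scores named numeric vector (e.g. log2 fold changes); names are
#'   gene ids and must be unique.
#' @return named numeric vector sorted for use with [gsea_es()].
#' @export
ranked_list <- function(scores) {
  stopifnot(!is.null(names(scores)), all(nzchar(names(scores))))
  if (anyDuplicated(names(scores))) stop("duplicate genes in ranked list")
  scores[order(-scores, names(scores))]
}

.ranked_ids <- function(ranked) {
  if (is.character(ranked)) ranked else names(ranked)
}

#' Unweighted GSEA enrichment score
#'
#' Running-sum statistic with exponent 0: the sum increments by
#' `1/N_hit` at gene-set members and decrements by `1/N_miss` elsewhere;
#' the enrichment score is the running-sum value of maximal absolute
#' deviation from zero (signed).
#'
#' @param ranked a [ranked_list()] (named numeric) or an ordered character
#'   vector of gene ids.
#' @param gene_set character vector; must intersect the ranked list.
#' @return enrichment score in \[-1, 1\].
#' @export
gsea_es <- function(ranked, gene_set) {
  ids <- .ranked_ids(ranked)
  hits <- ids %in% gene_set
  if (!any(hits)) stop("gene set disjoint from ranked list")
  .es_from_hits(hits)
}

.es_from_hits <- function(hits) {
  nh <- sum(hits)
  nm <- length(hits) - nh
  steps <- ifelse(hits, 1 / nh, if (nm > 0) -1 / nm else 0)
  rs <- cumsum(steps)
  # signed extremum; on an exact magnitude tie the negative deviation wins
  # (the running sum ends at 0, so max(rs) >= 0 and min(rs) <= 0)
  top <- max(rs); bot <- min(rs)
  if (top > -bot) top else bot
}

# ES from sorted hit positions p (1-based) in a list of length N.
# Extremes of the running sum occur right after a hit or right before one.
.es_from_positions <- function(p, N) {
  nh <- length(p)
  nm <- N - nh
  j <- seq_len(nh)
  if (nm == 0L) return(1)
  at_hit <- j / nh - (p - j) / nm
  before_hit <- (j - 1) / nh - (p - j) / nm
  top <- max(at_hit, 0); bot <- min(before_hit, 0)
  if (top > -bot) top else bot
}

#' Permutation significance for an unweighted GSEA score
#'
#' The null distribution is obtained by drawing random gene sets of the
#' observed size from the ranked universe. The p-value counts same-sign
#' null scores at least as extreme as the observed one,
#' `p = (1 + k) / (1 + m)` over the `m` same-sign permutations; NES divides
#' the observed score by the mean same-sign null magnitude.
#'
#' @inheritParams gsea_es
#' @param n_perm number of random gene sets (at least 100; default 1000).
#' @param seed integer seed.
#' @return list with `es`, `nes`, `p_value`, `n_perm`.
#' @export
gsea_significance <- function(ranked, gene_set, n_perm = 1000L, seed = 1L) {
  stopifnot(n_perm >= 100L)
  ids <- .ranked_ids(ranked)
  N <- length(ids)
  nh <- sum(ids %in% gene_set)
  es <- gsea_es(ranked, gene_set)
  set.seed(seed)
  null_es <- vapply(seq_len(n_perm), function(i) {
    .es_from_positions(sort(sample.int(N, nh)), N)
  }, numeric(1))
  same <- null_es * sign(es) > 0
  m <- sum(same)
  k <- sum(abs(null_es[same]) >= abs(es))
  p <- (1 + k) / (1 + m)
  nes <- if (m > 0) es / mean(abs(null_es[same])) else NA_real_
  list(es = es, nes = nes, p_value = p, n_perm = n_perm)
}

#' Test several gene sets against one ranked list
#'
#' @inheritParams gsea_significance
#' @param gene_sets named list of gene sets.
#' @return data.frame with `set_id`, `es`, `nes`, `p_value` and
#'   BH-adjusted `fdr` across the tested sets (a permutation-based
#'   approximation, not the fgsea-internal FDR).
#' @export
gsea_test_sets <- function(ranked, gene_sets, n_perm = 1000L, seed = 1L) {
  res <- lapply(seq_along(gene_sets), function(i) {
    r <- gsea_significance(ranked, gene_sets[[i]], n_perm = n_perm,
                           seed = seed + i)
    data.frame(set_id = names(gene_sets)[i], es = r$es, nes = r$nes,
               p_value = r$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Right-sided hypergeometric overrepresentation test
#'
#' `p = P(X >= overlap)` for `X ~ Hypergeom(|universe|, |term|, |query|)`.
#'
#' @param query,term,universe character vectors of gene ids; `query` and
#'   `term` must be subsets of `universe`.
#' @return list with `overlap`, `expected`, `p_value`.
#' @export
ora_hypergeom <- function(query, term, universe) {
  if (!length(universe)) stop("empty universe")
  query <- unique(query); term <- unique(term); universe <- unique(universe)
  if (!all(query %in% universe) || !all(term %in% universe))
    stop("query and term must be subsets of the universe")
  ov <- length(intersect(query, term))
  N <- length(universe); K <- length(term); n <- length(query)
  p <- stats::phyper(ov - 1, K, N - K, n, lower.tail = FALSE)
  list(overlap = ov, expected = n * K / N, p_value = p)
}

#' ORA over a collection of terms with BH correction
#'
#' @param query,universe character vectors of gene ids.
#' @param terms named list of gene sets (intersected with the universe).
#' @return data.frame with `term_id`, `overlap`, `expected`, `p_value`,
#'   `bh_fdr`.
#' @export
ora_test_terms <- function(query, terms, universe) {
  res <- lapply(seq_along(terms), function(i) {
    r <- ora_hypergeom(query, intersect(terms[[i]], universe), universe)
    data.frame(term_id = names(terms)[i], overlap = r$overlap,
               expected = r$expected, p_value = r$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$bh_fdr <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Subsampling null for transcription-factor enrichment
#'
#' Repeatedly draws `n_draw` genes without replacement from a background
#' pool (the NDP genes), runs the right-sided hypergeometric ORA for every
#' annotated TF with the pool as universe, BH-corrects within each draw,
#' and counts how many TFs of a designated family (e.g. the E2Fs) are
#' enriched below `alpha`.
#'
#' @param pool character vector of background genes.
#' @param tf_annotation named list: TF id -> annotated target genes.
#' @param tf_family character vector of family TF ids (subset of the
#'   annotation names).
#' @param n_draw genes per draw (default 179).
#' @param n_reps number of repetitions (default 1000).
#' @param alpha BH-FDR cutoff (default 0.05).
#' @param seed integer seed.
#' @return integer vector of length `n_reps`: enriched family-TF count per
#'   draw (tabulate for the histogram).
#' @export
subsample_tf_null <- function(pool, tf_annotation, tf_family,
                              n_draw = 179L, n_reps = 1000L, alpha = 0.05,
                              seed = 1L) {
  stopifnot(length(pool) >= n_draw)
  tfs <- names(tf_annotation)
  if (!length(tfs)) return(integer(n_reps))
  if (!all(tf_family %in% tfs)) stop("tf_family must be annotated TFs")
  pool <- unique(pool)
  N <- length(pool)
  member <- vapply(tf_annotation,
                   function(g) pool %in% g, logical(N))  # N x nTF
  K <- colSums(member)
  fam_idx <- match(tf_family, tfs)
  set.seed(seed)
  out <- integer(n_reps)
  for (r in seq_len(n_reps)) {
    draw <- sample.int(N, n_draw)
    ov <- colSums(member[draw, , drop = FALSE])
    p <- stats::phyper(ov - 1, K, N - K, n_draw, lower.tail = FALSE)
    fdr <- stats::p.adjust(p, method = "BH")
    out[r] <- sum(fdr[fam_idx] < alpha)
  }
  out
}
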