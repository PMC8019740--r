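#' Run the integrated target-calling pipeline
#'
#' Chains the full procedure: biotype restriction, cross-experiment
#' consistency classification, pan-cohort correlation tallies and
#' UNP/DPP/NDP labeling, CLIP peak filtering and gene intersection, and
#' the binding-based partition into DPP_CLIP / NDP_noCLIP / UNP_CLIP.
#'
#' @param de_tables list of DEG data.frames (`gene_id`, `biotype`,
#'   `log2fc`, `fdr`), one per knockdown experiment.
#' @param cohorts list of cohort objects (see [tally_signs()]).
#' @param peaks peak data.frame, or list of per-sample peak data.frames.
#' @param models a [transcript_models] object.
#' @param driver driver gene id present in every cohort.
#' @param allowed_biotypes biotypes analyzed (default protein-coding only;
#'   lincRNA results are reported separately upstream and not carried into
#'   the correlation/CLIP stages).
#' @param fdr_sig,fdr_stable consistency thresholds (see
#'   [classify_consistency()]).
#' @param min_cohorts same-sign cohort threshold (see [assign_labels()]).
#' @param min_fold,max_p CLIP significance filter (see [filter_peaks()]).
#' @return list with `calls`, `tallies`, `labels`, `binding` (per-gene
#'   summaries from significant peaks) and `sets` (`dpp_clip`,
#'   `ndp_noclip`, `unp_clip`).
#' @export
run_target_pipeline <- function(de_tables, cohorts, peaks, models,
                                driver = "IGF2BP1",
                                allowed_biotypes = "protein_coding",
                                fdr_sig = 0.05, fdr_stable = 0.95,
                                min_cohorts = 20L,
                                min_fold = 8, max_p = 1e-5) {
  filtered <- lapply(de_tables, filter_biotype, allowed = allowed_biotypes)
  calls <- classify_consistency(filtered, fdr_sig = fdr_sig,
                                fdr_stable = fdr_stable)
  dereg <- calls$gene_id[calls$status %in% c("cons_up", "cons_down")]
  tallies <- tally_signs(driver, dereg, cohorts)
  labels <- assign_labels(calls, tallies, min_cohorts = min_cohorts)
  if (is.list(peaks) && !is.data.frame(peaks))
    peaks <- do.call(rbind, peaks)
  sig <- filter_peaks(peaks, min_fold = min_fold, max_p = max_p)
  binding <- overlap_genes(sig, models)
  sets <- partition_by_binding(labels, binding)
  list(calls = calls, tallies = tallies, labels = labels,
       binding = binding, sets = sets)
}

#' Per-gene 3'UTR regulatory feature table
#'
#' Combines maximum 3'UTR length, maximum-transcript m6A site counts and
#' ARE presence (scanned on the designated longest-3'UTR transcript's
#' sequence) into one row per gene.
#'
#' @param genes character vector of gene ids.
#' @param models a [transcript_models] object.
#' @param m6a_sites m6A site data.frame (see [m6a_counts()]); may be
#'   `NULL`.
#' @param utr3_seqs named character vector of 3'UTR sequences keyed by
#'   transcript_id; may be `NULL` to skip the ARE scan.
#' @return data.frame with `gene_id`, `max_utr3`, `m6a_sites`, `has_are`,
#'   `n_pentamers`.
#' @export
feature_table <- function(genes, models, m6a_sites = NULL, utr3_seqs = NULL) {
  mx <- max_utr3(models, genes)
  out <- data.frame(gene_id = genes, max_utr3 = mx$max_utr3,
                    stringsAsFactors = FALSE)
  if (!is.null(m6a_sites)) {
    out$m6a_sites <- m6a_counts(m6a_sites, models, genes)$m6a_sites
  }
  if (!is.null(utr3_seqs)) {
    seqs <- utr3_seqs[mx$transcript_id]
    scans <- lapply(seqs, are_scan)
    out$has_are <- vapply(scans, `[[`, logical(1), "has_are")
    out$n_pentamers <- vapply(scans, `[[`, integer(1), "n_pentamers")
  }
  out
}
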