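# Small configurations and toy transcript models built in code.

small_cfg <- function(seed = 7L, ...) {
  sim_config(seed = seed, n_genes = 120L, n_planted_down = 15L,
             n_planted_up = 5L, n_planted_null = 40L, n_cohorts = 8L,
             n_samples_per_cohort = 60L, ...)
}

# single-exon and two-exon toy models used across feature tests
toy_models <- function() {
  tx <- data.frame(
    transcript_id = c("t_plus", "t_minus", "t_split"),
    gene_id = c("gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    cds_start = c(10L, 10L, 10L),
    cds_end = c(70L, 70L, 120L))
  ex <- data.frame(
    transcript_id = c("t_plus", "t_minus", "t_split", "t_split"),
    start = c(0L, 0L, 0L, 100L),
    end = c(100L, 100L, 50L, 150L))
  transcript_models(tx, ex)
}

# independent per-base classifier: walks every exonic base of a transcript
brute_region_lengths <- function(models, transcript_id) {
  i <- match(transcript_id, models$transcripts$transcript_id)
  tx <- models$transcripts[i, ]
  ex <- models$exons[models$exons$transcript_id == transcript_id, ]
  pos <- unlist(mapply(function(s, e) s:(e - 1), ex$start, ex$end,
                       SIMPLIFY = FALSE))
  cls <- ifelse(pos < tx$cds_start, "left",
                ifelse(pos < tx$cds_end, "cds", "right"))
  n <- table(factor(cls, c("left", "cds", "right")))
  if (tx$strand == "+")
    c(utr5 = unname(n["left"]), cds = unname(n["cds"]),
      utr3 = unname(n["right"]))
  else
    c(utr5 = unname(n["right"]), cds = unname(n["cds"]),
      utr3 = unname(n["left"]))
}

# brute-force half-open interval intersection (nested comparison)
brute_overlap <- function(peaks, spans) {
  hits <- list()
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(spans))) {
      if (peaks$chrom[i] == spans$chrom[j] &&
          peaks$start[i] < spans$end[j] && spans$start[j] < peaks$end[i]) {
        hits[[length(hits) + 1L]] <- data.frame(
          gene_id = spans$gene_id[j], sample_id = peaks$sample_id[i])
      }
    }
  }
  if (!length(hits)) return(data.frame(gene_id = character(),
                                       sample_id = character()))
  do.call(rbind, hits)
}

# exhaustive running-sum GSEA oracle (ties between +/- extrema resolve to
# the negative deviation, matching the documented convention)
brute_es <- function(ids, gene_set) {
  hits <- ids %in% gene_set
  nh <- sum(hits); nm <- length(ids) - nh
  rs <- 0; top <- 0; bot <- 0
  for (h in hits) {
    rs <- rs + if (h) 1 / nh else if (nm > 0) -1 / nm else 0
    top <- max(top, rs); bot <- min(bot, rs)
  }
  if (top > -bot) top else bot
}

# full rank-assignment enumeration of the Mann-Whitney U distribution
brute_mw_p <- function(a, b, alternative) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(na + nb, na)
  u_all <- apply(combos, 2, function(ix) sum(r[ix]) - na * (na + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  switch(alternative,
         less = p_le,
         greater = p_ge,
         two.sided = min(1, 2 * (if (u_obs > na * nb / 2) p_ge else p_le)))
}
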