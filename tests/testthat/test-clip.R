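mk_peaks <- function(fold, p, chrom = "c1", start = 0L, end = 50L,
                     sample_id = "s1") {
  data.frame(chrom = chrom, start = start, end = end, strand = "+",
             fold_enrichment = fold, p_value = p, sample_id = sample_id,
             stringsAsFactors = FALSE)
}

test_that("peak significance boundaries follow the removal rule", {
  pk <- mk_peaks(c(7.9, 12, 8.0), c(1e-9, 1e-5, 1e-6))
  kept <- filter_peaks(pk)
  # fold < 8 removed; p exactly 1e-5 removed; fold == 8 with small p kept
  expect_equal(kept$fold_enrichment, 8.0)
  expect_equal(filter_peaks(kept), kept)  # idempotent
  expect_error(filter_peaks(mk_peaks(-1, 0.5)), "fold")
  expect_error(filter_peaks(mk_peaks(9, 0)), "p_value")
})

test_that("half-open peak/gene intersection counts >=1 nt overlaps", {
  spans <- data.frame(gene_id = c("gA", "gB"), chrom = "c1",
                      start = c(140L, 150L), end = c(500L, 800L))
  pk <- mk_peaks(10, 1e-8, start = 100L, end = 150L)
  res <- overlap_genes(pk, spans)
  expect_equal(res$n_peaks_total[res$gene_id == "gA"], 1L)  # 10 nt overlap
  expect_equal(res$n_peaks_total[res$gene_id == "gB"], 0L)  # touching only
})

test_that("intersection equals the brute-force nested loop on random instances", {
  set.seed(21)
  for (rep in 1:3) {
    spans <- data.frame(
      gene_id = sprintf("g%03d", 1:50), chrom = sample(c("c1", "c2"), 50, TRUE),
      start = sample(0:5000, 50))
    spans$end <- spans$start + sample(50:800, 50, TRUE)
    pk <- data.frame(
      chrom = sample(c("c1", "c2", "c3"), 200, TRUE),
      start = sample(0:5500, 200), strand = "+",
      fold_enrichment = 10, p_value = 1e-8,
      sample_id = sample(c("s1", "s2"), 200, TRUE))
    pk$end <- pk$start + sample(10:200, 200, TRUE)
    got <- suppressMessages(overlap_genes(pk, spans))
    want <- brute_overlap(pk, spans)
    tab <- table(factor(want$gene_id, spans$gene_id))
    expect_equal(got$n_peaks_total, unname(as.integer(tab[got$gene_id])))
    nsamp <- tapply(want$sample_id, factor(want$gene_id, spans$gene_id),
                    function(s) length(unique(s)))
    nsamp[is.na(nsamp)] <- 0L
    expect_equal(got$n_samples_with_peak, unname(as.integer(nsamp[got$gene_id])))
  }
})

test_that("binding partition respects significance-filtered summaries", {
  labels <- data.frame(gene_id = c("d1", "d2", "n1", "n2", "u1"),
                       label = c("DPP", "DPP", "NDP", "NDP", "UNP"))
  summaries <- data.frame(gene_id = c("d1", "d2", "n1", "n2", "u1"),
                          n_peaks_total = c(3L, 0L, 1L, 0L, 2L),
                          n_samples_with_peak = c(2L, 0L, 1L, 0L, 1L))
  parts <- partition_by_binding(labels, summaries)
  expect_equal(parts$dpp_clip, "d1")
  expect_equal(parts$ndp_noclip, "n2")
  expect_equal(parts$unp_clip, "u1")
  # |DPP_CLIP| + |DPP without peaks| = |DPP|
  expect_equal(length(parts$dpp_clip) +
                 sum(labels$label == "DPP" & summaries$n_samples_with_peak == 0),
               sum(labels$label == "DPP"))
})

test_that("BED6+2 peak files round-trip in both p-value dialects", {
  pk <- mk_peaks(c(9.5, 20), c(1e-7, 1e-9))
  pk$name <- c("p1", "p2")
  path <- withr::local_tempfile(fileext = ".bed")
  write_peaks_bed(pk, path, p_col = "neglog10p")
  back <- read_peaks_bed(path, sample_id = "s1", p_col = "neglog10p")
  expect_equal(back$fold_enrichment, pk$fold_enrichment)
  expect_equal(back$p_value, pk$p_value, tolerance = 1e-12)
  write_peaks_bed(pk, path, p_col = "p")
  back2 <- read_peaks_bed(path, sample_id = "s1", p_col = "p")
  expect_equal(back2$p_value, pk$p_value, tolerance = 1e-12)
})
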