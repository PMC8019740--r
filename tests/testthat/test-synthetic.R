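test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_genes = 10, n_planted_down = 8, n_planted_up = 8,
                          n_planted_null = 8))
  expect_error(sim_config(rho_strength = 1.2))
  expect_error(sim_config(frac_clip_on_targets = -0.1))
})

test_that("every generated gene appears in the truth exactly once", {
  cfg <- small_cfg(seed = 2)
  sim <- simulate_dataset(cfg)
  expect_equal(anyDuplicated(sim$truth$gene_id), 0L)
  expect_equal(nrow(sim$truth), cfg$n_genes)
  expect_setequal(unique(sim$annotation$models$transcripts$gene_id),
                  sim$truth$gene_id)
  for (tbl in sim$de_tables)
    expect_setequal(tbl$gene_id, sim$truth$gene_id)
})

test_that("planted DE structure holds by construction", {
  cfg <- small_cfg(seed = 4)
  sim <- simulate_dataset(cfg)
  down <- sim$truth$label == "target_down"
  stab <- sim$truth$label == "stable_null"
  for (tbl in sim$de_tables) {
    m <- match(sim$truth$gene_id, tbl$gene_id)
    expect_true(all(tbl$fdr[m][down] < 0.05 & tbl$log2fc[m][down] < 0))
    expect_true(all(tbl$fdr[m][stab] >= 0.95))
  }
})

test_that("target 3'UTRs draw from the long-tailed distribution", {
  cfg <- sim_config(seed = 10, n_genes = 500, n_planted_down = 200,
                    n_planted_up = 20, n_planted_null = 250,
                    n_cohorts = 2, n_samples_per_cohort = 10)
  set.seed(cfg$seed)
  truth <- make_truth(cfg)
  ann <- generate_annotation(cfg, truth)
  mx <- max_utr3(ann$models, truth$gene_id)
  med_t <- median(mx$max_utr3[truth$label == "target_down"])
  med_n <- median(mx$max_utr3[truth$label == "stable_null"])
  expect_gt(med_t, med_n)
  # 5'UTR + CDS + 3'UTR sums to mature length for every emitted transcript
  reg <- transcript_regions(ann$models)
  expect_equal(reg$utr5 + reg$cds + reg$utr3, reg$mature)
  # emitted 3'UTR sequence lengths match the annotation
  expect_equal(unname(nchar(ann$utr3_seqs[reg$transcript_id])), reg$utr3)
})

test_that("every bound gene carries a significant peak; decoys never pass", {
  cfg <- small_cfg(seed = 6)
  sim <- simulate_dataset(cfg)
  pk <- do.call(rbind, sim$peaks)
  sig <- filter_peaks(pk)
  bound <- sim$truth$gene_id[sim$truth$clip_bound]
  expect_true(all(bound %in% sig$gene_id))
  nulls <- sim$truth$gene_id[sim$truth$label == "stable_null"]
  expect_false(any(sig$gene_id %in% nulls))
})

test_that("m6A counts separate targets from length-coupled nulls", {
  cfg <- small_cfg(seed = 8)
  sim <- simulate_dataset(cfg)
  cnt <- m6a_counts(sim$m6a, sim$annotation$models, sim$truth$gene_id)
  tgt <- cnt$m6a_sites[sim$truth$label == "target_down"]
  nul <- cnt$m6a_sites[sim$truth$label == "stable_null"]
  expect_gt(median(tgt), 15)
  expect_lte(median(nul), 3)
})

test_that("identical config and seed give byte-identical output files", {
  cfg <- sim_config(seed = 77, n_genes = 80, n_planted_down = 10,
                    n_planted_up = 4, n_planted_null = 20,
                    n_cohorts = 4, n_samples_per_cohort = 30)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(cfg, outdir = d1)
  simulate_dataset(cfg, outdir = d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  f2 <- sort(list.files(d2, recursive = TRUE))
  expect_identical(f1, f2)
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f2))
  expect_identical(unname(h1), unname(h2))
})
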