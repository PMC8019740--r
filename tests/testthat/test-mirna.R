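mk_preds <- function(...) {
  do.call(rbind, lapply(list(...), function(x)
    data.frame(mirna_id = x[1], gene_id = x[2], db_name = x[3],
               stringsAsFactors = FALSE)))
}

test_that("consensus requires two distinct databases", {
  preds <- mk_preds(c("m1", "gA", "dbA"),          # 1 db -> dropped
                    c("m2", "gA", "dbA"), c("m2", "gA", "dbB"),  # kept
                    c("m3", "gB", "dbA"), c("m3", "gB", "dbA"))  # dup db
  cp <- consensus_pairs(preds)
  expect_equal(nrow(cp), 1L)
  expect_equal(cp$mirna_id, "m2")
  expect_error(consensus_pairs(preds, db_names = c("dbA")), "unknown database")
  # anti-monotone in the threshold
  cp1 <- consensus_pairs(preds, min_dbs = 1)
  expect_true(all(paste(cp$mirna_id, cp$gene_id) %in%
                  paste(cp1$mirna_id, cp1$gene_id)))
})

test_that("expressed-miRNA selection averages replicates per cell line", {
  lines4 <- c("l1", "l2", "l3", "l4")
  expr <- data.frame(
    mirna_id = c(rep("hi", 8), rep("lo", 4), rep("mid", 4)),
    cell_line = c(rep(lines4, each = 2), lines4, lines4),
    # "hi" has two replicates per line averaging to 150 despite one low value
    cpm = c(rep(c(260, 40), 4), rep(10, 4), c(150, 150, 150, 50)))
  expect_equal(expressed_mirnas(expr, min_lines = 4), "hi")
  # mid passes in 3 of 4 lines only
  expect_equal(expressed_mirnas(expr, min_lines = 3), c("hi", "mid"))
  # threshold 0 retains everything
  expect_equal(expressed_mirnas(expr, cpm_threshold = 0, min_lines = 4),
               c("hi", "lo", "mid"))
  # literal below-threshold reading
  expect_equal(expressed_mirnas(expr, min_lines = 4, direction = "lt"), "lo")
})

test_that("targeting counts collapse families and cover zero-count genes", {
  pairs <- data.frame(mirna_id = c("let7a", "let7b", "mA", "mA"),
                      gene_id = c("g1", "g1", "g1", "g2"))
  fam <- data.frame(mirna_id = c("let7a", "let7b", "mA"),
                    family = c("let7", "let7", "mA"))
  tc <- targeting_counts(pairs, genes = c("g1", "g2", "g3"),
                         mirnas = c("let7a", "let7b", "mA"),
                         family_map = fam)
  expect_equal(tc$per_gene$n_mirnas, c(3L, 1L, 0L))
  expect_equal(tc$per_family$n_genes[tc$per_family$family == "let7"], 1L)
  expect_equal(tc$per_family$n_genes[tc$per_family$family == "mA"], 2L)
})

test_that("generator predictions recover the planted interaction structure", {
  cfg <- small_cfg(seed = 23)
  set.seed(cfg$seed)
  truth <- make_truth(cfg)
  mir <- generate_mirna(cfg, truth)
  cp <- consensus_pairs(mir$predictions, db_names = cfg$db_names)
  tgt <- truth$gene_id[truth$label == "target_down"]
  nul <- truth$gene_id[truth$label == "stable_null"]
  tc <- targeting_counts(cp, genes = c(tgt, nul),
                         mirnas = unique(mir$expression$mirna_id))
  mt <- mean(tc$per_gene$n_mirnas[tc$per_gene$gene_id %in% tgt])
  mn <- mean(tc$per_gene$n_mirnas[tc$per_gene$gene_id %in% nul])
  expect_gt(mt, mn)
  # per-gene counts match a brute-force tally over truth + database noise
  dt <- unique(mir$predictions)
  for (g in tgt[1:5]) {
    sub <- dt[dt$gene_id == g, ]
    n_brute <- sum(table(sub$mirna_id) >= 2)  # rows unique: one per db
    expect_equal(tc$per_gene$n_mirnas[tc$per_gene$gene_id == g], n_brute)
  }
})
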