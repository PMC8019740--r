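test_that("unweighted ES hits the extremes for top/bottom singleton sets", {
  ids <- paste0("g", 1:5)
  scores <- setNames(5:1, ids)
  expect_equal(gsea_es(ranked_list(scores), "g1"), 1.0)
  expect_equal(gsea_es(ranked_list(scores), "g5"), -1.0)
  expect_equal(gsea_es(ranked_list(scores), ids), 1.0)  # whole-list set
  expect_error(gsea_es(ranked_list(scores), "absent"), "disjoint")
})

test_that("ES equals the exhaustive running-sum oracle for all 8-gene subsets", {
  ids <- paste0("g", 1:8)
  scores <- setNames(seq(4, -3), ids)
  rl <- ranked_list(scores)
  for (mask in 1:255) {
    gs <- ids[bitwAnd(mask, 2^(0:7)) > 0]
    expect_equal(gsea_es(rl, gs), brute_es(ids, gs), info = mask)
  }
})

test_that("ES is antisymmetric under list reversal for tie-free extrema", {
  set.seed(14)
  n_checked <- 0
  for (i in 1:20) {
    scores <- setNames(sample(100, 12), paste0("g", 1:12))
    gs <- sample(names(scores), 4)
    rl <- ranked_list(scores)
    hits <- names(rl) %in% gs
    rs <- cumsum(ifelse(hits, 1 / 4, -1 / 8))
    if (abs(max(rs) + min(rs)) < 1e-9) next  # tied extrema: sign ambiguous
    expect_equal(gsea_es(rev(names(rl)), gs), -gsea_es(rl, gs), info = i)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 5)
})

test_that("ES agrees with fgsea's unweighted statistic", {
  set.seed(25)
  scores <- setNames(sort(rnorm(50), decreasing = TRUE), sprintf("g%02d", 1:50))
  for (i in 1:10) {
    gs <- sample(names(scores), sample(3:15, 1))
    expect_equal(gsea_es(ranked_list(scores), gs),
                 fgsea::calcGseaStat(scores, which(names(scores) %in% gs),
                                     gseaParam = 0),
                 tolerance = 1e-12)
  }
})

test_that("permutation significance is seeded and detects a top-loaded set", {
  scores <- setNames(seq(10, 0.01, length.out = 1000),
                     sprintf("g%04d", 1:1000))
  rl <- ranked_list(scores)
  top <- names(rl)[1:10]
  r1 <- gsea_significance(rl, top, n_perm = 1000, seed = 5)
  r2 <- gsea_significance(rl, top, n_perm = 1000, seed = 5)
  expect_identical(r1, r2)
  expect_lte(r1$p_value, 0.01)
  expect_equal(sign(r1$nes), sign(r1$es))
  expect_equal(r1$es, 1.0)
})

test_that("hypergeometric ORA matches the closed-form tail", {
  u <- paste0("g", 1:10)
  res <- ora_hypergeom(u[1:4], u[1:5], u)
  expect_equal(res$overlap, 4L)
  expect_equal(res$p_value, 5 / 210, tolerance = 1e-12)
  expect_equal(ora_hypergeom(u[5:8], u[1:4], u)$p_value, 1)  # overlap 0
  expect_equal(ora_hypergeom(u[1:4], u, u)$p_value, 1)       # term = universe
  expect_error(ora_hypergeom("x", u[1:2], u), "subsets")
  expect_error(ora_hypergeom("g1", "g1", character(0)), "empty universe")
})

test_that("ORA p-values match an urn Monte-Carlo within 3 SE", {
  set.seed(31)
  u <- sprintf("g%03d", 1:60)
  for (i in 1:5) {
    term <- sample(u, 12)
    query <- sample(u, 15)
    p <- ora_hypergeom(query, term, u)$p_value
    ov <- length(intersect(query, term))
    draws <- replicate(20000, sum(sample(u, 15) %in% term) >= ov)
    p_mc <- mean(draws)
    se <- sqrt(p_mc * (1 - p_mc) / 20000)
    expect_lt(abs(p - p_mc), 3 * se + 1e-9)
  }
})

test_that("the TF subsampling null is seeded and empty annotations give zeros", {
  pool <- sprintf("g%03d", 1:200)
  expect_equal(subsample_tf_null(pool, list(), c(), n_draw = 50, n_reps = 20),
               integer(20))
  set.seed(2)
  ann <- lapply(1:10, function(i) sample(pool, 30))
  names(ann) <- paste0("TF", 1:10)
  c1 <- subsample_tf_null(pool, ann, c("TF1", "TF2"), n_draw = 50,
                          n_reps = 50, seed = 4)
  c2 <- subsample_tf_null(pool, ann, c("TF1", "TF2"), n_draw = 50,
                          n_reps = 50, seed = 4)
  expect_identical(c1, c2)
  expect_true(all(c1 >= 0 & c1 <= 2))
})

test_that("planted E2F-like annotation is enriched in targets but not in the null", {
  cfg <- small_cfg(seed = 19)
  set.seed(cfg$seed)
  truth <- make_truth(cfg)
  tf <- generate_motif_annotation(cfg, truth)
  ann <- split(tf$annotation$gene_id, tf$annotation$tf_id)
  universe <- truth$gene_id
  down <- truth$gene_id[truth$label == "target_down"]
  res <- ora_test_terms(down, ann, universe)
  fam <- res[res$term_id %in% tf$tf_family, ]
  expect_true(all(fam$bh_fdr < 0.05))
})
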