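test_that("ARE scanning counts overlapping pentamers in AU-rich context", {
  expect_equal(are_scan("GCGCGCGCGCGC"), list(has_are = FALSE, n_pentamers = 0L))
  # "UUUAUUUAUUUAU": AUUUA at offsets 4 and 8, verified by sliding-window scan
  s <- "UUUAUUUAUUUAU"
  brute <- sum(vapply(1:(nchar(s) - 4), function(i)
    substr(chartr("U", "T", s), i, i + 4) == "ATTTA", logical(1)))
  res <- are_scan(s)
  expect_equal(res$n_pentamers, 2L)
  expect_equal(res$n_pentamers, brute)
  expect_true(res$has_are)
  # pentamer in GC context fails the AU-window condition
  gc <- are_scan("GCGCGCGAUUUAGCGCGCGC")
  expect_equal(gc$n_pentamers, 1L)
  expect_false(gc$has_are)
  expect_error(are_scan("AUXGU"), "non-nucleotide")
})

test_that("random sequences agree with a brute-force pentamer scan", {
  set.seed(8)
  for (i in 1:25) {
    s <- paste(sample(c("A", "U", "C", "G"), 80, TRUE,
                      prob = c(.35, .35, .15, .15)), collapse = "")
    brute <- sum(vapply(1:(nchar(s) - 4), function(j)
      substr(chartr("U", "T", s), j, j + 4) == "ATTTA", logical(1)))
    expect_equal(are_scan(s)$n_pentamers, brute)
  }
})

test_that("planted target AREs exceed null ARE rates", {
  cfg <- small_cfg(seed = 17)
  set.seed(cfg$seed)
  truth <- make_truth(cfg)
  ann <- generate_annotation(cfg, truth)
  des <- ann$designated
  frac <- function(lbl) {
    ids <- des$transcript_id[truth$label == lbl]
    mean(vapply(ann$utr3_seqs[ids],
                function(s) are_scan(s)$has_are, logical(1)))
  }
  expect_gt(frac("target_down"), frac("stable_null"))
})

test_that("motif densities expand IUPAC codes and normalize by positions", {
  expect_equal(unname(motif_density("ACGU", "ACGU")), 1.0)
  d <- motif_density("CAUACAUCCAUUCAUG", "CAUH")
  # CAUH matches CAUA, CAUC, CAUU but not CAUG
  expect_equal(unname(d), 3 / 13)
  # appending a motif-free flank of equal length halves the density
  s <- "GGACGGACGGAC"
  d1 <- motif_density(s, "GGAC")
  d2 <- motif_density(paste0(s, strrep("C", nchar(s))), "GGAC")
  expect_equal(unname(d2) * (2 * nchar(s) - 3) / (nchar(s) - 3), unname(d1))
  expect_error(motif_density("ACGUACGU", "ACGUA"), "length")
})

test_that("m6A counts use the maximum-transcript rule and skip introns", {
  tx <- data.frame(transcript_id = c("t1", "t2"), gene_id = "g",
                   chrom = "c", strand = "+",
                   cds_start = c(10L, 10L), cds_end = c(40L, 40L))
  ex <- data.frame(transcript_id = c("t1", "t1", "t2"),
                   start = c(0L, 100L, 0L), end = c(50L, 200L, 50L))
  m <- transcript_models(tx, ex)
  sites <- data.frame(chrom = "c",
                      pos = c(5L, 20L, 45L, 60L, 120L, 150L, 199L),
                      strand = "+")
  # t1 exonic: all but pos 60 (intron) -> 6; t2 exonic: first three -> 3
  expect_equal(m6a_count("g", sites, m), 6L)
  res <- m6a_counts(sites, m)
  expect_equal(res$m6a_sites, 6L)
  # brute force on a random instance
  set.seed(4)
  pos <- sample(0:220, 60, TRUE)
  rnd <- data.frame(chrom = "c", pos = pos, strand = "+")
  in_t1 <- sum((pos >= 0 & pos < 50) | (pos >= 100 & pos < 200))
  in_t2 <- sum(pos >= 0 & pos < 50)
  expect_equal(m6a_count("g", rnd, m), max(in_t1, in_t2))
})

test_that("group comparison is exact for small tie-free samples", {
  res <- compare_groups(c(1, 2), c(3, 4), alternative = "less")
  expect_equal(res$p_value, 1 / 6)  # enumeration over C(4,2) assignments
  same <- compare_groups(c(5, 7, 9), c(5, 7, 9))
  expect_equal(same$U, 9 / 2)
  degen <- compare_groups(rep(2, 4), rep(2, 3))
  expect_true(degen$degenerate)
  expect_equal(degen$p_value, 1)
})

test_that("exact p-values equal full rank-assignment enumeration", {
  set.seed(12)
  for (i in 1:10) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    vals <- sample(1000, na + nb)  # tie-free
    a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
    for (alt in c("less", "greater", "two.sided")) {
      expect_equal(compare_groups(a, b, alt)$p_value,
                   brute_mw_p(a, b, alt), tolerance = 1e-12,
                   info = paste(i, alt))
    }
  }
})

test_that("p-values are invariant under monotone transforms and match MC", {
  set.seed(33)
  a <- rnorm(30); b <- rnorm(30, 0.3)
  p0 <- compare_groups(a, b)$p_value
  expect_equal(compare_groups(exp(a), exp(b))$p_value, p0)
  # Monte-Carlo permutation reference (1e5 resamples)
  pooled <- c(a, b); n <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[1:n]) - n * (n + 1) / 2
  dev_obs <- abs(u_obs - n * n / 2)
  mc <- replicate(1e5, {
    ix <- sample(60, 30)
    abs(sum(r[ix]) - n * (n + 1) / 2 - n * n / 2)
  })
  p_mc <- mean(mc >= dev_obs)
  expect_lt(abs(p0 - p_mc) / p_mc, 0.10)
})
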