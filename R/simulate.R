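#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: six knockdown
#' experiments with planted conserved-down/up/unchanged genes, 31 tumor
#' cohorts with planted driver-gene correlations and an expression-linked
#' survival hazard, CLIP peaks centered on the stop codons of planted
#' targets, elevated m6A site counts on targets, multi-database miRNA
#' predictions from a noisy true interaction matrix, and ARE/motif-bearing
#' 3'UTR sequences with a target-vs-null length asymmetry.
#'
#' @param seed integer; fixing it makes every generated file byte-identical
#'   across runs.
#' @param n_genes total genes.
#' @param n_experiments knockdown experiments (default 6).
#' @param n_cohorts tumor cohorts (default 31).
#' @param n_planted_down,n_planted_up,n_planted_null planted
#'   conserved-down / conserved-up / stable-null gene counts; the rest are
#'   background genes with mixed signals.
#' @param frac_clip_on_targets fraction of planted target genes carrying
#'   significant CLIP peaks (default 0.65).
#' @param effect_log2fc mean |log2 fold change| of planted targets
#'   (default 2, sd `effect_sd`).
#' @param effect_sd sd of planted log2 fold changes (default 0.3).
#' @param rho_strength latent driver-target correlation in \[0, 1);
#'   0 gives the coupling-free null.
#' @param hazard_log2hr planted log2 hazard ratio of the prognostic gene's
#'   high-expression group (0 gives the survival null).
#' @param n_samples_per_cohort samples per cohort (default 200).
#' @param n_clip_samples CLIP samples (default 3).
#' @param clip_sample_prob probability that a bound gene carries a peak in
#'   each additional CLIP sample beyond its guaranteed one (default 0.6).
#' @param n_mirnas,n_cell_lines miRNA panel size and cell-line count.
#' @param db_sensitivity,db_fpr per-database sensitivity and false-positive
#'   rate for observing the true miRNA-target matrix (defaults 0.7, 0.02).
#' @param utr3_lognormal_params list with `target` and `null` entries, each
#'   `c(mu=, sigma=)` of the log-normal 3'UTR length distribution.
#' @param planted_motifs literal 4-mers inserted at elevated rates into
#'   target 3'UTRs.
#' @param frac_are_targets fraction of target 3'UTRs receiving a planted
#'   ARE block (default 0.5).
#' @param censor_horizon administrative censoring time (days).
#' @param baseline_median_surv baseline median survival time (days).
#' @param prognostic_gene gene whose expression drives the survival
#'   hazard; `NULL` designates the first planted down gene.
#' @param driver_id driver gene identifier used in cohort matrices.
#' @param genes_per_contig,intergenic_gap synthetic contig layout.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 1000L,
                       n_experiments = 6L,
                       n_cohorts = 31L,
                       n_planted_down = 60L,
                       n_planted_up = 12L,
                       n_planted_null = 300L,
                       frac_clip_on_targets = 0.65,
                       effect_log2fc = 2,
                       effect_sd = 0.3,
                       rho_strength = 0.9,
                       hazard_log2hr = 1,
                       n_samples_per_cohort = 200L,
                       n_clip_samples = 3L,
                       clip_sample_prob = 0.6,
                       n_mirnas = 150L,
                       n_cell_lines = 6L,
                       db_sensitivity = 0.7,
                       db_fpr = 0.02,
                       utr3_lognormal_params = list(
                         target = c(mu = log(2300), sigma = 0.6),
                         null   = c(mu = log(420),  sigma = 1.1)),
                       planted_motifs = c("GGAC", "CAUC"),
                       frac_are_targets = 0.5,
                       censor_horizon = 1000,
                       baseline_median_surv = 500,
                       prognostic_gene = NULL,
                       driver_id = "IGF2BP1",
                       genes_per_contig = 50L,
                       intergenic_gap = 1000L) {
  cfg <- as.list(environment())
  counts <- c(n_genes, n_experiments, n_cohorts, n_planted_down,
              n_planted_up, n_planted_null, n_samples_per_cohort,
              n_clip_samples, n_mirnas, n_cell_lines)
  stopifnot(all(counts > 0),
            n_planted_down + n_planted_up + n_planted_null <= n_genes,
            frac_clip_on_targets >= 0, frac_clip_on_targets <= 1,
            rho_strength >= 0, rho_strength < 1,
            db_sensitivity >= 0, db_sensitivity <= 1,
            db_fpr >= 0, db_fpr <= 1,
            frac_are_targets >= 0, frac_are_targets <= 1)
  cfg$db_names <- c("targetscan", "miranda", "pita", "pictar",
                    "elmmo", "microt", "mirmap", "mirdb")
  structure(cfg, class = "sim_config")
}

.gene_ids <- function(cfg) {
  sprintf("G%0*d", max(4L, nchar(as.character(cfg$n_genes))),
          seq_len(cfg$n_genes))
}

#' Planted truth table
#'
#' Assigns every gene exactly one class label and the derived planted
#' quantities (true correlation sign, biotype). CLIP-bound flags and true
#' peak positions are filled in by [generate_peaks()].
#'
#' @param cfg a [sim_config()].
#' @return data.frame with `gene_id`, `label`
#'   (`target_down`/`target_up`/`stable_null`/`background`), `corr_sign`,
#'   `biotype`, `clip_bound`, `peak_positions`.
#' @export
make_truth <- function(cfg) {
  ids <- .gene_ids(cfg)
  label <- rep("background", cfg$n_genes)
  label[seq_len(cfg$n_planted_down)] <- "target_down"
  label[cfg$n_planted_down + seq_len(cfg$n_planted_up)] <- "target_up"
  label[cfg$n_planted_down + cfg$n_planted_up +
          seq_len(cfg$n_planted_null)] <- "stable_null"
  corr_sign <- ifelse(label == "target_down", 1L,
                      ifelse(label == "target_up", -1L, 0L))
  biotype <- rep("protein_coding", cfg$n_genes)
  bg <- which(label == "background")
  biotype[bg] <- sample(c("protein_coding", "lincRNA", "other"),
                        length(bg), replace = TRUE,
                        prob = c(0.8, 0.1, 0.1))
  data.frame(gene_id = ids, label = label, corr_sign = corr_sign,
             biotype = biotype, clip_bound = FALSE,
             peak_positions = "", stringsAsFactors = FALSE)
}

# keep the transcript-first L exonic bases of an ascending exon chain
.clip_exons <- function(exons, strand, L) {
  w <- exons$end - exons$start
  if (strand == "+") {
    keep <- cumsum(w) - w < L
    ex <- exons[keep, , drop = FALSE]
    excess <- sum(ex$end - ex$start) - L
    ex$end[nrow(ex)] <- ex$end[nrow(ex)] - excess
  } else {
    wr <- rev(w)
    keepr <- cumsum(wr) - wr < L
    ex <- exons[rev(keepr), , drop = FALSE]
    excess <- sum(ex$end - ex$start) - L
    ex$start[1] <- ex$start[1] + excess
  }
  ex
}

.random_seq <- function(n) {
  paste(sample(c("A", "U", "C", "G"), n, replace = TRUE,
               prob = c(0.28, 0.28, 0.22, 0.22)), collapse = "")
}

.overwrite_at <- function(seq, insert, pos) {
  # pos is 1-based; insert must fit
  paste0(substr(seq, 1, pos - 1), insert,
         substr(seq, pos + nchar(insert), nchar(seq)))
}

#' Generate the synthetic annotation and 3'UTR sequences
#'
#' Each gene gets 1-3 transcripts on a synthetic contig (about 50 genes per
#' contig, 1 kb intergenic spacing, random strand) sharing 5'UTR and CDS;
#' the first transcript carries the longest 3'UTR, drawn from the target or
#' null log-normal length distribution according to the gene's planted
#' class. Target 3'UTR sequences receive planted ARE blocks and extra
#' copies of the configured 4-mers.
#'
#' @param cfg a [sim_config()].
#' @param truth output of [make_truth()].
#' @return list with `models` ([transcript_models]), `utr3_seqs` (named by
#'   transcript_id) and `designated` (gene_id -> longest-3'UTR
#'   transcript_id).
#' @export
generate_annotation <- function(cfg, truth) {
  n <- cfg$n_genes
  is_target <- truth$label %in% c("target_down", "target_up")
  pt <- cfg$utr3_lognormal_params$target
  pn <- cfg$utr3_lognormal_params$null
  utr5 <- pmax(10L, round(stats::rlnorm(n, log(150), 0.5)))
  cds  <- pmax(90L, round(stats::rlnorm(n, log(1200), 0.35)))
  utr3 <- ifelse(is_target,
                 stats::rlnorm(n, pt[["mu"]], pt[["sigma"]]),
                 stats::rlnorm(n, pn[["mu"]], pn[["sigma"]]))
  utr3 <- pmax(30L, round(utr3))
  n_tx <- sample(1:3, n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  contig <- sprintf("ctg%03d", (seq_len(n) - 1L) %/% cfg$genes_per_contig + 1L)
  cursor <- stats::setNames(rep(0L, length(unique(contig))), unique(contig))

  tx_rows <- vector("list", n)
  ex_rows <- vector("list", n)
  seqs <- list()
  for (i in seq_len(n)) {
    mature <- utr5[i] + cds[i] + utr3[i]
    n_ex <- sample(1:4, 1)
    cuts <- if (n_ex > 1) sort(sample(mature - 1L, n_ex - 1L)) else integer()
    widths <- diff(c(0L, cuts, mature))
    introns <- if (n_ex > 1) round(stats::runif(n_ex - 1L, 100, 2000)) else integer()
    gstart <- cursor[[contig[i]]]
    starts <- gstart + cumsum(c(0L, widths[-n_ex] + introns))
    ends <- starts + widths
    cursor[[contig[i]]] <- ends[n_ex] + cfg$intergenic_gap
    ex1 <- data.frame(start = as.integer(starts), end = as.integer(ends))
    g1 <- .tx_to_genomic(utr5[i], ex1, strand[i])
    g2 <- .tx_to_genomic(utr5[i] + cds[i] - 1L, ex1, strand[i])
    cds_start <- min(g1, g2); cds_end <- max(g1, g2) + 1L
    gid <- truth$gene_id[i]
    tids <- sprintf("%s.t%d", gid, seq_len(n_tx[i]))
    utr3_k <- c(utr3[i],
                if (n_tx[i] > 1)
                  pmax(30L, round(utr3[i] * stats::runif(n_tx[i] - 1L, 0.2, 0.8))))
    # secondary 3'UTRs must stay strictly shorter than the designated one
    utr3_k[-1] <- pmin(utr3_k[-1], max(30L, utr3[i] - 1L))
    txs <- exs <- vector("list", n_tx[i])
    for (k in seq_len(n_tx[i])) {
      exk <- if (k == 1L) ex1 else
        .clip_exons(ex1, strand[i], utr5[i] + cds[i] + utr3_k[k])
      txs[[k]] <- data.frame(transcript_id = tids[k], gene_id = gid,
                             chrom = contig[i], strand = strand[i],
                             cds_start = cds_start, cds_end = cds_end,
                             stringsAsFactors = FALSE)
      exs[[k]] <- data.frame(transcript_id = tids[k],
                             start = exk$start, end = exk$end,
                             stringsAsFactors = FALSE)
    }
    tx_rows[[i]] <- do.call(rbind, txs)
    ex_rows[[i]] <- do.call(rbind, exs)
    # 3'UTR sequence of the designated transcript; secondaries are prefixes
    s <- .random_seq(utr3[i])
    if (is_target[i]) {
      if (stats::runif(1) < cfg$frac_are_targets && utr3[i] >= 20) {
        n_are <- 1L + stats::rpois(1, 1)
        for (a in seq_len(n_are)) {
          pos <- sample(utr3[i] - 12L, 1)
          s <- .overwrite_at(s, "AUUUAUUUAUUUA", pos)
        }
      }
      for (mot in cfg$planted_motifs) {
        n_extra <- stats::rpois(1, 3)
        if (n_extra > 0 && utr3[i] > nchar(mot)) {
          for (a in seq_len(n_extra)) {
            pos <- sample(utr3[i] - nchar(mot) + 1L, 1)
            s <- .overwrite_at(s, mot, pos)
          }
        }
      }
    }
    for (k in seq_len(n_tx[i]))
      seqs[[tids[k]]] <- substr(s, 1, utr3_k[k])
  }
  models <- transcript_models(do.call(rbind, tx_rows), do.call(rbind, ex_rows))
  designated <- data.frame(gene_id = truth$gene_id,
                           transcript_id = paste0(truth$gene_id, ".t1"),
                           stringsAsFactors = FALSE)
  list(models = models, utr3_seqs = unlist(seqs), designated = designated)
}

#' Generate per-experiment differential-expression tables
#'
#' Planted down genes are significant (FDR ~ U(0, 0.05)) with negative
#' log2FC in every experiment, planted up genes symmetrically positive;
#' stable nulls get FDR ~ U(0.95, 1) everywhere. Background genes carry
#' mixed signals: each is forced significant in one experiment and
#' intermediate in another, so no background gene can satisfy a
#' consistency rule.
#'
#' @param cfg a [sim_config()].
#' @param truth output of [make_truth()].
#' @return list of `n_experiments` data.frames (`gene_id`, `biotype`,
#'   `log2fc`, `fdr`).
#' @export
generate_de_tables <- function(cfg, truth) {
  n <- cfg$n_genes
  k <- cfg$n_experiments
  bg <- truth$label == "background"
  force_sig <- force_mid <- rep(NA_integer_, n)
  for (i in which(bg)) {
    pick <- sample(k, 2)
    force_sig[i] <- pick[1]; force_mid[i] <- pick[2]
  }
  lapply(seq_len(k), function(e) {
    fdr <- numeric(n); lfc <- numeric(n)
    down <- truth$label == "target_down"
    up <- truth$label == "target_up"
    stab <- truth$label == "stable_null"
    fdr[down] <- stats::runif(sum(down), 0, 0.05)
    lfc[down] <- stats::rnorm(sum(down), -cfg$effect_log2fc, cfg$effect_sd)
    fdr[up] <- stats::runif(sum(up), 0, 0.05)
    lfc[up] <- stats::rnorm(sum(up), cfg$effect_log2fc, cfg$effect_sd)
    fdr[stab] <- stats::runif(sum(stab), 0.95, 1)
    lfc[stab] <- stats::rnorm(sum(stab), 0, 0.1)
    fdr[bg] <- stats::runif(sum(bg))
    lfc[bg] <- stats::rnorm(sum(bg), 0, 1)
    sig_here <- bg & force_sig == e
    mid_here <- bg & force_mid == e
    fdr[sig_here] <- stats::runif(sum(sig_here), 0, 0.05)
    fdr[mid_here] <- stats::runif(sum(mid_here), 0.05, 0.95)
    data.frame(gene_id = truth$gene_id, biotype = truth$biotype,
               log2fc = lfc, fdr = fdr, stringsAsFactors = FALSE)
  })
}

#' Generate tumor cohorts with planted correlations and hazards
#'
#' Per cohort, a latent standard-normal driver variable couples to planted
#' target genes with strength `rho_strength` (positive for planted down
#' genes, negative for planted up genes); expression is a monotone
#' (exponential) transform of the latent values, so Spearman structure is
#' preserved. Survival times are exponential with the hazard multiplied by
#' `2^hazard_log2hr` for samples above the prognostic gene's median
#' expression, administratively censored at `censor_horizon`.
#'
#' @param cfg a [sim_config()].
#' @param truth output of [make_truth()].
#' @return list of cohorts, each `list(cohort_id, expression, survival)`;
#'   the expression matrix contains all genes plus the driver row.
#' @export
generate_cohorts <- function(cfg, truth) {
  n <- cfg$n_genes
  ns <- cfg$n_samples_per_cohort
  coupling <- cfg$rho_strength * truth$corr_sign
  pg <- cfg$prognostic_gene
  if (is.null(pg) && cfg$n_planted_down > 0)
    pg <- truth$gene_id[truth$label == "target_down"][1]
  lambda0 <- log(2) / cfg$baseline_median_surv
  lapply(seq_len(cfg$n_cohorts), function(ci) {
    cid <- sprintf("C%02d", ci)
    z <- stats::rnorm(ns)
    eps <- matrix(stats::rnorm(n * ns), n, ns)
    latent <- coupling %o% z + sqrt(1 - coupling^2) * eps
    expr <- exp(0.8 * latent + 2)
    expr <- rbind(expr, matrix(exp(0.8 * z + 2), 1, ns))
    rownames(expr) <- c(truth$gene_id, cfg$driver_id)
    colnames(expr) <- sprintf("%s_S%03d", cid, seq_len(ns))
    mult <- rep(1, ns)
    if (!is.null(pg)) {
      e <- expr[pg, ]
      mult <- 2^(cfg$hazard_log2hr * (e > stats::median(e)))
    }
    tt <- stats::rexp(ns, rate = lambda0 * mult)
    time <- pmin(tt, cfg$censor_horizon)
    survival <- data.frame(sample_id = colnames(expr),
                           time = time,
                           event = as.integer(tt <= cfg$censor_horizon),
                           stringsAsFactors = FALSE)
    list(cohort_id = cid, expression = expr, survival = survival)
  })
}

#' Generate CLIP peak sets with planted stop-codon-proximal binding
#'
#' A seeded fraction of planted target genes is designated CLIP-bound;
#' every bound gene receives a significant peak (fold >= 8, p < 1e-5) in at
#' least one sample, whose midpoint sits a few nucleotides from the stop
#' codon of the designated transcript. Sub-threshold decoy peaks are
#' scattered over null and background genes.
#'
#' @param cfg a [sim_config()].
#' @param truth output of [make_truth()] (returned updated).
#' @param ann output of [generate_annotation()].
#' @return list with `peaks` (one data.frame per CLIP sample) and the
#'   updated `truth` (clip_bound flags, true peak positions).
#' @export
generate_peaks <- function(cfg, truth, ann) {
  models <- ann$models
  tx <- models$transcripts
  reg <- transcript_regions(models)
  sample_ids <- sprintf("clip_s%d", seq_len(cfg$n_clip_samples))
  rows <- list()
  target_idx <- which(truth$label %in% c("target_down", "target_up"))
  bound <- target_idx[stats::runif(length(target_idx)) < cfg$frac_clip_on_targets]
  truth$clip_bound[bound] <- TRUE
  for (i in bound) {
    tid <- ann$designated$transcript_id[i]
    j <- match(tid, tx$transcript_id)
    ex <- .tx_exons(models, tid)
    r <- reg[match(tid, reg$transcript_id), ]
    stop_tx <- r$utr5 + r$cds
    in_samples <- unique(c(sample(cfg$n_clip_samples, 1),
                           which(stats::runif(cfg$n_clip_samples) <
                                   cfg$clip_sample_prob)))
    pos_list <- integer()
    for (s in in_samples) {
      ctx <- max(0L, min(r$mature - 1L, stop_tx + round(stats::rnorm(1, 0, 5))))
      cg <- .tx_to_genomic(ctx, ex, tx$strand[j])
      pos_list <- c(pos_list, cg)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = tx$chrom[j], start = max(0L, cg - 25L), end = cg + 25L,
        strand = tx$strand[j],
        fold_enrichment = 8 + stats::rexp(1, 1 / 10),
        p_value = 10^(-stats::runif(1, 6, 12)),
        sample_id = sample_ids[s], gene_id = truth$gene_id[i],
        stringsAsFactors = FALSE)
    }
    truth$peak_positions[i] <- paste(sort(pos_list), collapse = ";")
  }
  decoy_idx <- which(truth$label %in% c("stable_null", "background") &
                       stats::runif(cfg$n_genes) < 0.4)
  spans <- gene_spans(models)
  for (i in decoy_idx) {
    sp <- spans[match(truth$gene_id[i], spans$gene_id), ]
    st <- sp$start + sample(max(1L, sp$end - sp$start - 50L), 1) - 1L
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = sp$chrom, start = st, end = st + 50L, strand = "+",
      fold_enrichment = stats::runif(1, 1, 7.5),
      p_value = 10^(-stats::runif(1, 0, 4.5)),
      sample_id = sample_ids[sample(cfg$n_clip_samples, 1)],
      gene_id = truth$gene_id[i], stringsAsFactors = FALSE)
  }
  all_peaks <- do.call(rbind, rows)
  all_peaks$name <- sprintf("peak_%05d", seq_len(nrow(all_peaks)))
  peaks <- lapply(sample_ids, function(s)
    all_peaks[all_peaks$sample_id == s, , drop = FALSE])
  names(peaks) <- sample_ids
  list(peaks = peaks, truth = truth)
}

#' Generate m6A site tables
#'
#' Planted targets carry ~Pois(25) exonic sites, enriched near the stop
#' codon; null and background genes carry length-coupled low counts
#' (~Pois(3'UTR length / 800) sites placed in the 3'UTR), emulating the
#' correlation of m6A counts with 3'UTR length.
#'
#' @inheritParams generate_peaks
#' @return data.frame with `chrom`, `pos` (0-based), `strand`.
#' @export
generate_m6a <- function(cfg, truth, ann) {
  models <- ann$models
  tx <- models$transcripts
  reg <- transcript_regions(models)
  rows <- list()
  for (i in seq_len(cfg$n_genes)) {
    tid <- ann$designated$transcript_id[i]
    j <- match(tid, tx$transcript_id)
    r <- reg[match(tid, reg$transcript_id), ]
    is_target <- truth$label[i] %in% c("target_down", "target_up")
    nsite <- if (is_target) stats::rpois(1, 25)
             else stats::rpois(1, r$utr3 / 800)
    if (nsite == 0) next
    stop_tx <- r$utr5 + r$cds
    if (is_target) {
      near <- stats::runif(nsite) < 0.6
      ctx <- ifelse(near,
                    round(stats::rnorm(nsite, stop_tx, 30)),
                    sample.int(r$mature, nsite, replace = TRUE) - 1L)
    } else {
      ctx <- stop_tx + sample.int(r$utr3, nsite, replace = TRUE) - 1L
    }
    ctx <- pmax(0L, pmin(r$mature - 1L, as.integer(ctx)))
    ex <- .tx_exons(models, tid)
    g <- .tx_to_genomic(ctx, ex, tx$strand[j])
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = tx$chrom[j], pos = g, strand = tx$strand[j],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Generate miRNA expression and multi-database predictions
#'
#' A true miRNA-target interaction matrix plants ~Pois(8) partner miRNAs
#' on each target gene and ~Pois(1) on others; each of the eight
#' "databases" observes it independently with the configured sensitivity
#' and false-positive rate. Expression is log-normal CPM per cell line.
#'
#' @param cfg a [sim_config()].
#' @param truth output of [make_truth()].
#' @return list with `expression` (`mirna_id`, `cell_line`, `cpm`),
#'   `predictions` (`mirna_id`, `gene_id`, `db_name`), `family_map`
#'   (`mirna_id`, `family`) and `true_pairs`.
#' @export
generate_mirna <- function(cfg, truth) {
  mirnas <- sprintf("miR-%03d", seq_len(cfg$n_mirnas))
  n_fam <- min(15L, cfg$n_mirnas %/% 3L)
  family <- mirnas
  family[seq_len(3L * n_fam)] <- rep(sprintf("fam%02d", seq_len(n_fam)),
                                     each = 3L)
  family_map <- data.frame(mirna_id = mirnas, family = family,
                           stringsAsFactors = FALSE)
  is_target <- truth$label %in% c("target_down", "target_up")
  k <- stats::rpois(cfg$n_genes, ifelse(is_target, 8, 1))
  k <- pmin(k, cfg$n_mirnas)
  gene_rep <- rep(seq_len(cfg$n_genes), k)
  partner <- unlist(lapply(k, function(kk)
    if (kk > 0) sample.int(cfg$n_mirnas, kk) else integer()))
  true_pairs <- data.frame(mirna_id = mirnas[partner],
                           gene_id = truth$gene_id[gene_rep],
                           stringsAsFactors = FALSE)
  true_idx <- (partner - 1L) * cfg$n_genes + gene_rep
  M <- cfg$n_mirnas * cfg$n_genes
  preds <- list()
  for (db in cfg$db_names) {
    hit <- true_idx[stats::runif(length(true_idx)) < cfg$db_sensitivity]
    n_fp <- stats::rbinom(1, M - length(unique(true_idx)), cfg$db_fpr)
    fp <- sample(setdiff(seq_len(M), true_idx), n_fp)
    idx <- c(hit, fp)
    preds[[db]] <- data.frame(
      mirna_id = mirnas[(idx - 1L) %/% cfg$n_genes + 1L],
      gene_id = truth$gene_id[(idx - 1L) %% cfg$n_genes + 1L],
      db_name = db, stringsAsFactors = FALSE)
  }
  base <- stats::rlnorm(cfg$n_mirnas, log(120), 1.2)
  lines <- sprintf("cl%d", seq_len(cfg$n_cell_lines))
  expression <- data.frame(
    mirna_id = rep(mirnas, each = cfg$n_cell_lines),
    cell_line = rep(lines, cfg$n_mirnas),
    cpm = rep(base, each = cfg$n_cell_lines) *
      stats::rlnorm(cfg$n_mirnas * cfg$n_cell_lines, 0, 0.3),
    stringsAsFactors = FALSE)
  list(expression = expression, predictions = do.call(rbind, preds),
       family_map = family_map, true_pairs = unique(true_pairs))
}

#' Generate a TF-to-target-gene motif annotation
#'
#' A designated E2F-like TF family preferentially covers planted down
#' genes (rate 0.8 vs a background rate of 0.08); additional TFs annotate
#' genes at the background rate only.
#'
#' @param cfg a [sim_config()].
#' @param truth output of [make_truth()].
#' @param family_rate,background_rate inclusion probabilities.
#' @return list with `annotation` (data.frame `tf_id`, `gene_id`) and
#'   `tf_family` (the E2F-like TF ids).
#' @export
generate_motif_annotation <- function(cfg, truth, family_rate = 0.8,
                                      background_rate = 0.08) {
  fam <- c("E2F1", "E2F2", "E2F3")
  others <- sprintf("TF%02d", 4:30)
  down <- truth$label == "target_down"
  rows <- list()
  for (tf in fam) {
    p <- ifelse(down, family_rate, background_rate)
    keep <- stats::runif(cfg$n_genes) < p
    rows[[tf]] <- data.frame(tf_id = tf, gene_id = truth$gene_id[keep],
                             stringsAsFactors = FALSE)
  }
  for (tf in others) {
    keep <- stats::runif(cfg$n_genes) < background_rate
    rows[[tf]] <- data.frame(tf_id = tf, gene_id = truth$gene_id[keep],
                             stringsAsFactors = FALSE)
  }
  list(annotation = do.call(rbind, rows), tf_family = fam)
}

#' Generate a complete synthetic data set
#'
#' Runs every generator under a single seed, in a fixed order, so that a
#' given `(config, seed)` yields byte-identical outputs. When `outdir` is
#' given, all pipeline input files are written there as plain text
#' (GTF-like annotation, FASTA 3'UTRs, per-experiment DEG TSVs, cohort
#' expression/clinical TSVs, BED6+2 peak files, m6A/miRNA/TF TSVs, and the
#' serialized truth table).
#'
#' @param cfg a [sim_config()].
#' @param outdir optional output directory (created if needed).
#' @return list with `cfg`, `truth`, `annotation`, `de_tables`, `cohorts`,
#'   `peaks`, `m6a`, `mirna`, `tf`.
#' @export
simulate_dataset <- function(cfg, outdir = NULL) {
  set.seed(cfg$seed)
  truth <- make_truth(cfg)
  ann <- generate_annotation(cfg, truth)
  de <- generate_de_tables(cfg, truth)
  cohorts <- generate_cohorts(cfg, truth)
  pk <- generate_peaks(cfg, truth, ann)
  truth <- pk$truth
  m6a <- generate_m6a(cfg, truth, ann)
  mirna <- generate_mirna(cfg, truth)
  tf <- generate_motif_annotation(cfg, truth)
  sim <- list(cfg = cfg, truth = truth, annotation = ann, de_tables = de,
              cohorts = cohorts, peaks = pk$peaks, m6a = m6a,
              mirna = mirna, tf = tf)
  if (!is.null(outdir)) write_simulation(sim, outdir)
  sim
}

#' Write a simulated data set to plain-text files
#'
#' @param sim output of [simulate_dataset()].
#' @param outdir output directory.
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "cohorts"), showWarnings = FALSE)
  write_gtf(sim$annotation$models, file.path(outdir, "annotation.gtf"))
  write_utr3_fasta(sim$annotation$utr3_seqs, file.path(outdir, "utr3.fa"))
  for (i in seq_along(sim$de_tables))
    write_tsv(sim$de_tables[[i]], file.path(outdir, sprintf("deg_%d.tsv", i)))
  for (co in sim$cohorts) {
    em <- data.frame(gene_id = rownames(co$expression), co$expression,
                     check.names = FALSE)
    write_tsv(em, file.path(outdir, "cohorts",
                            sprintf("%s_expression.tsv", co$cohort_id)))
    write_tsv(co$survival, file.path(outdir, "cohorts",
                                     sprintf("%s_clinical.tsv", co$cohort_id)))
  }
  for (s in names(sim$peaks))
    write_peaks_bed(sim$peaks[[s]], file.path(outdir, sprintf("%s.bed", s)))
  write_tsv(sim$m6a, file.path(outdir, "m6a_sites.tsv"))
  write_tsv(sim$mirna$expression, file.path(outdir, "mirna_expression.tsv"))
  write_tsv(sim$mirna$predictions, file.path(outdir, "mirna_predictions.tsv"))
  write_tsv(sim$mirna$family_map, file.path(outdir, "mirna_families.tsv"))
  write_tsv(sim$tf$annotation, file.path(outdir, "tf_annotation.tsv"))
  write_tsv(sim$truth, file.path(outdir, "truth.tsv"))
  invisible(outdir)
}
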