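---
title: "Calling conserved RBP-stabilized target mRNAs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling conserved RBP-stabilized target mRNAs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbpcall)
```

# The procedure

`rbpcall` identifies mRNAs whose expression depends on an oncogenic
RNA-binding protein (the driver; IGF2BP1 is the motivating case) in a
*conserved* way, by chaining four filters, each of which removes a
different class of false positives:

1. **Consistency across knockdown experiments.** Per-experiment
   differential-expression tables (gene, biotype, log2FC, FDR) are first
   restricted to the analyzed biotypes (protein-coding by default;
   lincRNAs are reported separately and not carried downstream). A gene
   is `cons_down` when FDR < 0.05 *and* log2FC < 0 in every experiment,
   `cons_up` symmetrically, and `cons_unchanged` when FDR >= 0.95 in
   every experiment. The significance boundary is strict ("below 0.05"),
   so FDR exactly 0.05 in a single experiment breaks consistency. A gene
   with a significant FDR but log2FC exactly 0 is neither up nor down:
   the conserved sets are strictly signed. A gene absent from any one
   table cannot be consistent — consistency is positive evidence in all
   experiments, not absence of contradiction. This absent-gene rule is a
   design decision of this package; alternatives (e.g. requiring
   presence in only k of n tables) would admit genes that were never
   measured everywhere.
2. **Pan-cancer correlation.** Spearman's rho (Pearson correlation of
   mid-ranks) between each consistent gene and the driver is computed per
   cohort. `DPP` = `cons_down` with rho > 0 in at least `min_cohorts`
   (default 20) of the cohorts; `UNP` = `cons_up` with rho < 0 in at
   least `min_cohorts`; `NDP` = `cons_unchanged` with *no* correlation
   condition. A rho of exactly 0 counts to neither tally, and a cohort
   where either rank vector has zero variance yields an undefined rho
   that is excluded from both counts — `min_cohorts` is *not* rescaled
   when cohorts drop out, mirroring a fixed "20 of the 31" rule.
3. **CLIP binding.** Peaks are kept when fold enrichment >= 8 (the
   removal rule is "less than eight-fold", so 8.0 survives) and
   enrichment p strictly < 1e-5 (the removal rule is ">= 1e-5", so a peak
   at exactly 1e-5 is removed). Filtered peaks are intersected with
   intron-inclusive gene spans, strand-agnostically, with >= 1 nt overlap
   on half-open coordinates — the conventions of a default
   `bedtools intersect` run against gene annotations. Exon-restricted
   intersection is available (`exonic_only = TRUE`). `DPP_CLIP` are DPPs
   with a significant peak in >= 1 sample; `NDP_noCLIP` are NDPs with
   none.
4. **Length-matched control.** Because most regulatory 3'UTR features
   scale with 3'UTR length, `NDP_noCLIP_LM` re-samples `NDP_noCLIP` to
   match the `DPP_CLIP` maximum-3'UTR-length distribution: greedy
   nearest-neighbor matching without replacement on `log10(length + 1)`,
   targets processed in seeded random order, ties broken by gene id. The
   log scale reflects the heavy right tail of 3'UTR lengths; the
   reported quality metric (target vs matched median) mirrors the one
   number such matching is judged by. With an adversarial pool the match
   still returns a full-size set and simply reports a poor median gap —
   silent failure would be worse than a visibly bad match.

Feature comparisons between the sets use the Mann-Whitney test with
mid-ranks, exact by full enumeration when the pooled sample size is at
most 12 without ties, otherwise the normal approximation with tie and
continuity correction.

# Feature definitions

* **Maximum 3'UTR length** (`max_utr3`): per gene, the longest exonic
  3'UTR over its transcripts; all region lengths are strand-aware and
  exclude introns, and `utr5 + cds + utr3` always equals the mature
  length. The longest-3'UTR transcript is also the designated
  representative isoform for site mapping.
* **m6A sites** (`m6a_counts`): sites are matched to transcripts by
  exonic genomic position (intronic sites never count) and each gene
  reports its maximally modified transcript.
* **ARE** (`are_scan`): at least one AUUUA pentamer whose enclosing
  13-nt window (4-nt flanks, shifted inward at sequence edges) has an
  AU fraction >= 10/13. This scanner is this package's documented
  surrogate for a curated ARE database lookup; a precomputed ARE column
  can be supplied instead via `feature_table()`'s inputs. Overlapping
  pentamers are counted individually; T and U are interchangeable.
* **miRNA consensus** (`consensus_pairs`): a miRNA-gene pair counts when
  predicted by >= 2 *distinct* databases of the configured eight.
  `expressed_mirnas` averages replicate CPM per cell line and keeps
  miRNAs passing the CPM threshold (default 100) in >= 4 cell lines.
  The source description of this filter reads "< 100 CPM", which
  contradicts its purpose of selecting *expressed* miRNAs; the package
  defaults to `>=` and exposes `direction = "lt"` so the literal reading
  is also runnable. Neither reading is asserted as the original intent.
* **Meta-gene profile** (`aggregate_profile`): 30 bins per region,
  ordered 5'UTR, CDS, 3'UTR in transcript orientation; a site's bin is
  `region_offset + floor(30 * r)` with `r` its relative position in the
  region. Peaks are represented by their midpoints by default — the
  simplest faithful reading of binned "peak data" frequencies — with
  interval-weighted counting behind `midpoint = FALSE`. Counts are
  pooled over genes before normalizing to sum 1, so transcripts lacking
  a region contribute nothing to it and are not renormalized per gene.

# Enrichment and survival statistics

**Unweighted GSEA.** The exponent-0 running sum steps `+1/N_hit` at set
members and `-1/N_miss` elsewhere; the enrichment score is the signed
extremum of maximal absolute deviation. On an exact magnitude tie between
the positive and negative extremum the negative deviation wins — the
convention of `fgsea::calcGseaStat`, against which the statistic is
cross-checked in the tests. Significance is permutation-based: random
same-size gene sets are drawn from the ranked universe,
`p = (1 + k)/(1 + m)` over the `m` same-sign permutations, and NES
divides the observed score by the mean same-sign null magnitude. This
random-set null is the preranked convention and deliberately *not* a
reimplementation of fgsea's adaptive multilevel algorithm; p-values are
permutation-grade and the BH FDR across sets is labeled an approximation.
Ties in the ranked scores are broken lexicographically by gene id so
rankings are deterministic.

**ORA.** Right-sided hypergeometric tail `P(X >= overlap)` with BH
correction across terms. The TF subsampling null (`subsample_tf_null`)
repeatedly draws `n_draw` genes (default 179) from the NDP pool, runs the
ORA for every annotated TF with the pool as universe, BH-corrects within
the draw, and counts enriched TFs of a designated family (e.g. E2Fs) —
the distribution of that count over (by default) 1,000 draws is the
calibration reference for family enrichment in same-size gene sets. The
hypergeometric ORA over a supplied TF-to-gene annotation replaces a
motif-AUC ranking method here; only the subsampling construction itself
is asserted by the tests.

**Survival.** Samples are split at the gene's median expression; ties at
exactly the median go to "low" so that "high" means strictly elevated
expression (configurable). The log-rank walk accumulates observed and
expected events per group at each distinct event time under the
hypergeometric null, with censored samples at time t still at risk at t;
`chi_sq = sum((O-E)^2/E)` with a chi-square(1) p-value and
`HR = (O_high/E_high)/(O_low/E_low)`. This O/E form — not a Cox fit,
which is out of scope — matches the classic textbook description and is
cross-checked against `survival::survdiff`'s O/E tables in the tests. A
group with zero expected events makes the HR undefined; such cohorts are
flagged and excluded from the pan-cohort median log2 HR.

# What the generator emulates

`simulate_dataset()` plants ground truth for every stage under one seed;
identical `(config, seed)` reproduces every output file byte for byte.

| Parameter | Default | Meaning |
|---|---|---|
| `n_genes` | 1000 | genes on synthetic contigs (~50/contig, 1 kb gaps) |
| `n_planted_down/up/null` | 60 / 12 / 300 | planted conserved classes; remainder are background |
| `n_experiments` | 6 | knockdown DE tables |
| `n_cohorts`, `n_samples_per_cohort` | 31, 200 | tumor cohorts |
| `effect_log2fc` (sd 0.3) | 2 | planted |log2FC| of targets |
| `rho_strength` | 0.9 | latent driver-target coupling; 0 = null |
| `hazard_log2hr` | 1 | planted log2 HR of the prognostic gene |
| `frac_clip_on_targets` | 0.65 | fraction of targets that are CLIP-bound |
| `utr3_lognormal_params` | target (ln 2300, 0.6); null (ln 420, 1.1) | 3'UTR length distributions |
| `db_sensitivity`, `db_fpr` | 0.7, 0.02 | per-database views of the true miRNA matrix |
| `censor_horizon`, `baseline_median_surv` | 1000, 500 days | administrative censoring (~25-30% censored) |

Choices worth explaining:

* **DE tables are drawn directly** (FDR, log2FC per class) rather than
  simulated as counts and refit — the DE model itself is an input to
  this pipeline, not part of it. Background genes are each forced
  significant in one experiment and intermediate in another, so no
  background gene can satisfy any consistency rule; planted recovery is
  then exact by construction and deviations indicate pipeline defects,
  not generator noise.
* **Correlation structure** comes from a latent one-factor model
  (`latent = coupling * z + sqrt(1 - coupling^2) * noise`) with
  expression a monotone exponential transform, which preserves Spearman
  structure while keeping the matrix FPKM-like and non-negative.
* **3'UTR lengths**: the target distribution reproduces a ~2.3 kb
  median; the null sigma of 1.1 gives the heavy right tail real 3'UTR
  length distributions have — which is also what makes a length-matched
  null set constructible at a ~6-10x pool-to-target ratio.
* **m6A counts** are ~Pois(25) on targets and length-coupled
  (~Pois(len/800)) on nulls, so the length-matched control set has an
  intermediate median — emulating the observed coupling of m6A counts
  to 3'UTR length.
* **Peaks** sit at the designated transcript's stop codon +- N(0, 5 nt),
  every bound gene gets >= 1 significant peak, and decoy peaks on
  null/background genes fail the significance filter by construction
  (fold <= 7.5 and p >= 10^-4.5).
* **Survival** hazards can only be planted through one designated
  prognostic gene per run (a single survival time per sample cannot
  carry independent hazards for hundreds of genes); all other genes are
  null for survival, which is exactly what the calibration tests need.

What the generator does **not** emulate: realistic genome composition
beyond planted motifs, read-level noise, correlated DE errors across
experiments, batch structure in cohorts, overlapping genes, or
peak-width/shape realism. Passing tests therefore demonstrate the
pipeline's correctness and calibration on its own definitions, not
robustness to every artifact of real data.

# Verification strategy and problem sizes

The test suite checks every operation against an independent oracle:
interval intersection against a brute-force nested comparison (10^3
peaks x 10^3 genes), the GSEA score against an exhaustive running-sum
evaluation of all 255 subsets of an 8-gene list and against
`fgsea::calcGseaStat(gseaParam = 0)`, Mann-Whitney exact p-values against
full rank-assignment enumeration (n <= 12), the hypergeometric tail
against a 1e5-draw urn simulation, Spearman against an independently
coded mid-rank Pearson (1e-12), the log-rank O/E tables against
`survival::survdiff`, and a hand-walked 4-sample risk table frozen in the
tests. Calibration runs use couplings set to zero: 600 planted-down genes
for the sign-rule rate (expected `2 * P(Bin(31, 0.5) >= 20)`), 500 genes
for the log-rank rejection rate at alpha = 0.05, 250 replicates for GSEA
p-value uniformity, and 400 subsampling draws for the TF family null —
sizes chosen to keep 2-SE bands meaningful while the whole suite runs in
about a minute. Parameter recovery uses the default 31 x 200 cohort
layout, where the planted log2 HR of 1 is recovered within +-0.3 and the
planted correlation sign in >= 30 of 31 cohorts.

# Known limitations

* GSEA p-values are permutation-grade (resolution 1/(n_perm+1)); very
  small p-values require raising `n_perm`.
* The chi-square form `sum((O-E)^2/E)` of the log-rank statistic is
  slightly conservative with heavy event ties; with continuous times and
  administrative censoring it is calibrated (verified in the tests).
* Greedy nearest-neighbor matching is order-dependent; the seeded random
  processing order makes it reproducible, not optimal. Multi-covariate
  or propensity matching is out of scope.
* The ARE scanner is a motif-plus-context rule, not a curated database;
  absolute ARE fractions from the scanner and from database lookups are
  not comparable, only between-set contrasts computed with the same
  instrument.
* `overlap_genes` assigns a peak to *every* overlapping gene; on compact
  synthetic contigs with 1 kb spacing a wide decoy peak near a boundary
  could in principle touch a neighbor, so decoy peaks are kept narrow
  (50 nt) relative to the spacing.
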