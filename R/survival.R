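#' Median-split expression grouping
#'
#' Samples strictly above the gene's median expression form the `high`
#' group; samples at or below the median (including exact ties at the
#' median) are `low`.
#'
#' @param expr named numeric vector of expression values (>= 4 samples).
#' @param ties_to `"low"` (default) or `"high"`: side receiving samples at
#'   exactly the median.
#' @return named character vector of `"high"`/`"low"` per sample.
#' @export
median_split <- function(expr, ties_to = c("low", "high")) {
  ties_to <- match.arg(ties_to)
  stopifnot(length(expr) >= 4)
  if (length(unique(expr)) == 1L)
    stop("all expression values identical; no median split possible")
  med <- stats::median(expr)
  grp <- if (ties_to == "low") ifelse(expr > med, "high", "low")
         else ifelse(expr >= med, "high", "low")
  names(grp) <- names(expr)
  grp
}

#' Log-rank test and O/E hazard ratio for two groups
#'
#' Classic risk-table walk: at each distinct event time the observed and
#' expected events per group are accumulated under the hypergeometric null
#' (censored samples at time t remain at risk for events at t);
#' `chi_sq = sum((O - E)^2 / E)` over the two groups with a chi-square(1)
#' p-value, and `HR = (O_high/E_high) / (O_low/E_low)`. A group with zero
#' expected events yields an `NA` (flagged missing) hazard ratio.
#'
#' @param records data.frame with `time` (> 0), `event` (0/1) and `group`
#'   (`"high"`/`"low"`).
#' @return list with `hr`, `log2_hr`, `chi_sq`, `p_value`, `obs`, `exp`
#'   (named per group).
#' @export
logrank_hr <- function(records) {
  stopifnot(all(c("time", "event", "group") %in% names(records)),
            all(records$time > 0), all(records$event %in% c(0, 1)),
            all(records$group %in% c("high", "low")))
  if (!any(records$event == 1)) stop("no events observed")
  if (length(unique(records$group)) < 2) stop("both groups must be non-empty")
  tt <- sort(unique(records$time[records$event == 1]))
  O <- E <- c(high = 0, low = 0)
  for (t in tt) {
    at_risk <- records$time >= t
    n1 <- sum(at_risk & records$group == "high")
    n0 <- sum(at_risk & records$group == "low")
    d1 <- sum(records$time == t & records$event == 1 & records$group == "high")
    d0 <- sum(records$time == t & records$event == 1 & records$group == "low")
    d <- d1 + d0; n <- n1 + n0
    O <- O + c(d1, d0)
    E <- E + c(d * n1 / n, d * n0 / n)
  }
  chi <- sum((O - E)^2 / E)
  p <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  hr <- if (any(E == 0)) NA_real_ else (O["high"] / E["high"]) / (O["low"] / E["low"])
  list(hr = unname(hr), log2_hr = unname(log2(hr)), chi_sq = chi,
       p_value = p, obs = O, exp = E)
}

#' Per-gene hazard summaries across cohorts
#'
#' Median-splits each gene's expression within each cohort, runs the
#' log-rank walk and collects hazard ratios.
#'
#' @param cohorts list of cohort objects (`cohort_id`, `expression`,
#'   `survival` with `sample_id`, `time`, `event`).
#' @param genes character vector of genes to analyze.
#' @return data.frame with `gene_id`, `cohort_id`, `hr`, `log2_hr`,
#'   `chi_sq`, `p_value` (NA rows where the gene is absent or the split
#'   degenerate).
#' @export
cohort_hazards <- function(cohorts, genes) {
  res <- list()
  for (co in cohorts) {
    surv <- co$survival
    m <- match(surv$sample_id, colnames(co$expression))
    for (g in genes) {
      row <- data.frame(gene_id = g, cohort_id = co$cohort_id,
                        hr = NA_real_, log2_hr = NA_real_,
                        chi_sq = NA_real_, p_value = NA_real_,
                        stringsAsFactors = FALSE)
      if (g %in% rownames(co$expression)) {
        expr <- co$expression[g, m]
        ok <- tryCatch({
          grp <- median_split(expr)
          lr <- logrank_hr(data.frame(time = surv$time, event = surv$event,
                                      group = grp))
          row$hr <- lr$hr; row$log2_hr <- lr$log2_hr
          row$chi_sq <- lr$chi_sq; row$p_value <- lr$p_value
          TRUE
        }, error = function(e) FALSE)
      }
      res[[length(res) + 1L]] <- row
    }
  }
  do.call(rbind, res)
}

#' Median pan-cohort log2 hazard ratio per gene
#'
#' Cohorts with missing (flagged) or non-finite hazard ratios are excluded
#' from each gene's median.
#'
#' @param summaries output of [cohort_hazards()].
#' @return data.frame with `gene_id`, `median_log2_hr`, `n_cohorts`; the
#'   full gene x cohort log2-HR matrix is attached as attribute
#'   `"log2_hr"`.
#' @export
pan_cohort_summary <- function(summaries) {
  genes <- unique(summaries$gene_id)
  cohorts <- unique(summaries$cohort_id)
  mat <- matrix(NA_real_, length(genes), length(cohorts),
                dimnames = list(genes, cohorts))
  mat[cbind(match(summaries$gene_id, genes),
            match(summaries$cohort_id, cohorts))] <- summaries$log2_hr
  med <- apply(mat, 1, function(v) stats::median(v[is.finite(v)]))
  out <- data.frame(gene_id = genes, median_log2_hr = unname(med),
                    n_cohorts = rowSums(is.finite(mat)),
                    stringsAsFactors = FALSE)
  attr(out, "log2_hr") <- mat
  out
}
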