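#' Classify samples as beneficial / non-beneficial for a causal gene
#'
#' For a protective gene (higher expression lengthens survival), samples
#' strictly above the study-wide median are "beneficial"; for a harmful gene
#' the classification is reversed. Samples exactly at the median count as
#' below-median.
#'
#' @param expr log2-scale `expression_matrix` over all study samples.
#' @param gene gene id.
#' @param causal_direction "protective" or "harmful" (sign of the causal
#'   effect on survival).
#' @return character vector ("beneficial"/"non-beneficial") named by sample,
#'   with attribute `degenerate` (TRUE when expression is constant).
#' @export
classify_beneficial <- function(expr, gene, causal_direction) {
  causal_direction <- match.arg(causal_direction, c("protective", "harmful"))
  x <- expr$values[gene, ]
  med <- stats::median(x)
  above <- x > med
  lab <- if (causal_direction == "protective") {
    ifelse(above, "beneficial", "non-beneficial")
  } else {
    ifelse(above, "non-beneficial", "beneficial")
  }
  names(lab) <- colnames(expr$values)
  attr(lab, "degenerate") <- stats::sd(x) == 0
  lab
}

#' CMS enrichment of beneficial / non-beneficial expression
#'
#' Per consensus molecular subtype, the fraction of samples with beneficial
#' expression; a subtype is called enriched for a category when that
#' category's fraction strictly exceeds `threshold` (the "over 70%" rule).
#'
#' @param labels per-sample labels from [classify_beneficial()].
#' @param cms per-sample CMS labels (CMS1..CMS4; NA allowed, ignored).
#' @param threshold enrichment threshold (default 0.70, strict).
#' @return data frame (`cms`, `n`, `frac_beneficial`, `frac_non_beneficial`,
#'   `enriched` in \{"beneficial", "non-beneficial", "none"\}). Subtypes
#'   absent from the data are reported with n = 0 and `enriched` = "none".
#' @export
cms_enrichment <- function(labels, cms, threshold = 0.70) {
  stopifnot(length(labels) == length(cms))
  keep <- !is.na(cms)
  labels <- labels[keep]; cms <- cms[keep]
  subtypes <- paste0("CMS", 1:4)
  rows <- lapply(subtypes, function(s) {
    sel <- cms == s
    n <- sum(sel)
    if (n == 0) {
      message("cms_enrichment: subtype ", s, " absent")
      return(data.frame(cms = s, n = 0L, frac_beneficial = NA_real_,
                        frac_non_beneficial = NA_real_, enriched = "none",
                        stringsAsFactors = FALSE))
    }
    fb <- mean(labels[sel] == "beneficial")
    enr <- if (fb > threshold) "beneficial" else
      if (1 - fb > threshold) "non-beneficial" else "none"
    data.frame(cms = s, n = n, frac_beneficial = fb,
               frac_non_beneficial = 1 - fb, enriched = enr,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Paired tumor/normal differential expression for one gene
#'
#' Two-sided paired t-test on per-pair log2 differences (tumor minus
#' normal); the fold-change is 2 to the mean log2 difference. A Wilcoxon
#' signed-rank variant is available behind `method`. With all differences
#' zero the t statistic is undefined and p is reported as 1. No covariate
#' adjustment is applied.
#'
#' @param paired list with aligned `tumor` and `normal` genes x pairs log2
#'   matrices (as from [simulate_paired_de()]).
#' @param gene gene id.
#' @param method "t" (paired t-test, default) or "wilcoxon".
#' @return list with `fold_change` (tumor over normal), `p`, `n_pairs`,
#'   `mean_log2fc`.
#' @export
paired_de <- function(paired, gene, method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  d <- paired$tumor[gene, ] - paired$normal[gene, ]
  if (length(d) < 2) stop("paired_de: need at least 2 pairs")
  if (stats::sd(d) == 0) {
    p <- 1
  } else if (method == "t") {
    p <- stats::t.test(d)$p.value
  } else {
    p <- stats::wilcox.test(d, exact = FALSE)$p.value
  }
  list(fold_change = 2^mean(d), p = p, n_pairs = length(d),
       mean_log2fc = mean(d))
}

#' Prognostic contribution of biomarkers via a likelihood-ratio test
#'
#' Within one treatment arm, compares Cox models with and without the
#' biomarker expression columns, both adjusted for the covariates; degrees
#' of freedom equal the number of biomarkers added.
#'
#' @param clinical `clinical_table`.
#' @param biomarker_values samples x biomarkers numeric matrix (may have 0
#'   columns) aligned to `clinical` rows.
#' @param arm treatment arm.
#' @param covariates samples x q numeric matrix aligned to `clinical` rows.
#' @return list with `chi2`, `df`, `p`.
#' @export
prognostic_lrt <- function(clinical, biomarker_values, arm, covariates) {
  sel <- clinical$arm == arm
  clin <- clinical[sel, , drop = FALSE]
  bio <- as.matrix(biomarker_values)[sel, , drop = FALSE]
  cov <- as.matrix(covariates)[sel, , drop = FALSE]
  if (is.null(colnames(cov))) colnames(cov) <- paste0("c", seq_len(ncol(cov)))
  if (ncol(bio) && is.null(colnames(bio))) {
    colnames(bio) <- paste0("biomarker", seq_len(ncol(bio)))
  }
  reduced <- fit_cox(clin$os_time, clin$event, cov)
  if (!ncol(bio)) return(list(chi2 = 0, df = 0, p = 1))
  full <- fit_cox(clin$os_time, clin$event, cbind(cov, bio))
  likelihood_ratio_test(full, reduced)
}

#' Kaplan-Meier curves for median-dichotomized expression
#'
#' Splits one gene's expression at the median (computed within the arm by
#' default, or study-wide) into "high" and "low" groups and returns the
#' product-limit curves and group sizes. Ties at the median go to "low".
#'
#' @param expr log2-scale `expression_matrix`.
#' @param gene gene id.
#' @param clinical `clinical_table` aligned to expression samples.
#' @param arm treatment arm.
#' @param median_within "arm" (default) or "study".
#' @return list from [kaplan_meier()] plus `group_sizes`.
#' @export
km_by_median <- function(expr, gene, clinical, arm,
                         median_within = c("arm", "study")) {
  median_within <- match.arg(median_within)
  x_all <- expr$values[gene, clinical$sample_id]
  sel <- clinical$arm == arm
  if (!any(sel)) stop("km_by_median: empty arm subset")
  med <- if (median_within == "arm") stats::median(x_all[sel]) else
    stats::median(x_all)
  grp <- ifelse(x_all[sel] > med, "high", "low")
  if (length(unique(grp)) < 2) {
    stop("km_by_median: degenerate split (constant expression)")
  }
  km <- kaplan_meier(clinical$os_time[sel], clinical$event[sel], grp)
  km$group_sizes <- table(grp)
  km
}
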