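#' Filter genes by expression variability
#'
#' Keeps a gene iff its across-sample standard deviation is at least
#' `sd_min` and its fraction of zero entries is at most `zero_frac_max`
#' (genes with more than 30% zeros are excluded; exactly 30% survives).
#' Operates on raw-scale values; row order is preserved.
#'
#' @param expr raw-scale `expression_matrix`.
#' @param sd_min minimum standard deviation (default 0.5).
#' @param zero_frac_max maximum tolerated fraction of zeros (default 0.30).
#' @return filtered `expression_matrix`.
#' @export
filter_genes <- function(expr, sd_min = 0.5, zero_frac_max = 0.30) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (expr$scale != "raw") stop("filter_genes: expects raw-scale expression")
  v <- expr$values
  sds <- apply(v, 1, stats::sd)
  zf <- rowMeans(v == 0)
  keep <- sds >= sd_min & zf <= zero_frac_max
  if (!any(keep)) stop("filter_genes: no genes survive the variability filter")
  expression_matrix(v[keep, , drop = FALSE], expr$gene_annotation, scale = "raw")
}

#' Upper-quartile normalize and log2-transform expression
#'
#' Each sample's values are divided by that sample's upper quartile (75th
#' percentile of its nonzero values) and rescaled by the global mean of the
#' per-sample upper quartiles, then transformed as log2(x + 1). Samples with
#' more than 50% zero genes are dropped (with a message) before
#' normalization; a sample with all-zero expression is an error.
#'
#' @param expr raw-scale `expression_matrix`.
#' @return log2-scale `expression_matrix`. Attribute `dropped_samples` lists
#'   samples removed by the >50%-zeros rule.
#' @export
normalize_expression <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (expr$scale != "raw") stop("normalize_expression: expects raw-scale expression")
  v <- expr$values
  zf <- colMeans(v == 0)
  if (any(zf == 1)) {
    stop("normalize_expression: sample(s) with all-zero expression: ",
         paste(colnames(v)[zf == 1], collapse = ", "))
  }
  drop <- zf > 0.5
  if (any(drop)) {
    message("normalize_expression: dropping ", sum(drop),
            " sample(s) with >50% zero genes")
    v <- v[, !drop, drop = FALSE]
  }
  uq <- apply(v, 2, function(x) stats::quantile(x[x > 0], 0.75, names = FALSE))
  scaled <- sweep(v, 2, uq, "/") * mean(uq)
  out <- expression_matrix(log2(scaled + 1), expr$gene_annotation, scale = "log2")
  attr(out, "dropped_samples") <- colnames(expr$values)[drop]
  out
}

# Hardy-Weinberg exact test (two-sided, conditional on allele counts),
# enumerating the heterozygote distribution by the standard recurrence.
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  n_minor <- min(n_a, 2 * n - n_a)
  if (n == 0 || n_minor == 0) return(1)
  het_vals <- seq(n_minor %% 2, n_minor, by = 2)
  lp <- vapply(het_vals, function(h) {
    hom_minor <- (n_minor - h) / 2
    hom_major <- n - h - hom_minor
    lgamma(n + 1) - lgamma(h + 1) - lgamma(hom_minor + 1) - lgamma(hom_major + 1) +
      h * log(2) + lgamma(n_minor + 1) + lgamma(2 * n - n_minor + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  obs_het <- n_ab
  min(1, sum(pr[pr <= pr[match(obs_het, het_vals)] * (1 + 1e-12)]))
}

#' Genotype quality control
#'
#' Drops SNPs failing any of: call rate below `snp_call_min`, Hardy-Weinberg
#' exact-test p below `hwe_p_min`, or MAF below `maf_min` (a SNP at exactly
#' the MAF floor is kept). Then drops samples with call rate below
#' `sample_call_min`. Each filter pass is computed once, SNPs before
#' samples, with no iteration. Remaining missing dosages are mean-imputed
#' per SNP (required downstream for matrix algebra).
#'
#' @param geno `genotype_matrix`; dosages may contain NA and must be hard
#'   calls (0/1/2) for the HWE test.
#' @param snp_call_min,hwe_p_min,maf_min,sample_call_min thresholds.
#' @return filtered `genotype_matrix` with attribute `qc_log` (data frame of
#'   removed SNPs/samples and the rule that fired).
#' @export
qc_genotypes <- function(geno, snp_call_min = 0.99, hwe_p_min = 1e-8,
                         maf_min = 0.05, sample_call_min = 0.90) {
  stopifnot(inherits(geno, "genotype_matrix"))
  d <- geno$dosages
  call_rate <- colMeans(!is.na(d))
  f <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  maf[is.nan(maf)] <- 0
  hwe <- apply(d, 2, function(x) {
    x <- x[!is.na(x)]
    hwe_exact_p(sum(x == 0), sum(x == 1), sum(x == 2))
  })
  drop_snp <- call_rate < snp_call_min | hwe < hwe_p_min | maf < maf_min
  rule <- character(ncol(d))
  rule[maf < maf_min] <- "maf"
  rule[hwe < hwe_p_min] <- "hwe"
  rule[call_rate < snp_call_min] <- "call_rate"
  log_snp <- data.frame(id = colnames(d)[drop_snp],
                        type = rep("snp", sum(drop_snp)),
                        rule = rule[drop_snp], stringsAsFactors = FALSE)
  d <- d[, !drop_snp, drop = FALSE]
  samp_cr <- rowMeans(!is.na(d))
  drop_samp <- samp_cr < sample_call_min
  log_samp <- data.frame(id = rownames(d)[drop_samp],
                         type = rep("sample", sum(drop_samp)),
                         rule = rep("call_rate", sum(drop_samp)),
                         stringsAsFactors = FALSE)
  d <- d[!drop_samp, , drop = FALSE]
  for (j in seq_len(ncol(d))) {
    na <- is.na(d[, j])
    if (any(na)) d[na, j] <- mean(d[, j], na.rm = TRUE)
  }
  out <- genotype_matrix(d, geno$snp_annotation)
  attr(out, "qc_log") <- rbind(log_snp, log_samp)
  out
}

#' Filter immune-cell types by enrichment
#'
#' Keeps a cell type iff at most `zero_frac_max` of its scores are zero and
#' its standard deviation is strictly greater than `sd_min`.
#'
#' @param abund samples x cell-types matrix of non-negative fractions.
#' @param zero_frac_max maximum zero fraction (default 0.30, inclusive).
#' @param sd_min standard-deviation threshold (default 0.12, strict).
#' @return filtered matrix (possibly with zero columns).
#' @export
filter_cell_types <- function(abund, zero_frac_max = 0.30, sd_min = 0.12) {
  abund <- as.matrix(abund)
  if (any(abund < 0)) stop("filter_cell_types: abundances must be >= 0")
  keep <- colMeans(abund == 0) <= zero_frac_max &
    apply(abund, 2, stats::sd) > sd_min
  abund[, keep, drop = FALSE]
}

#' Infer genetic sex from chromosome-Y expression
#'
#' 2-means clustering of samples on the chrY gene submatrix; the cluster
#' with the higher mean expression is labelled male. Samples whose inferred
#' label disagrees with the recorded gender are reported.
#'
#' @param expr log2-scale `expression_matrix`.
#' @param chrY_genes character vector of chrY gene ids (>= 2 present).
#' @param recorded_gender optional 0/1 vector (1 = male) aligned to samples.
#' @return list with `label` (per-sample "male"/"female"), `mismatches`
#'   (sample ids, if recorded gender given), `degenerate` (TRUE when the
#'   clusters do not separate).
#' @export
infer_genetic_sex <- function(expr, chrY_genes, recorded_gender = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (expr$scale != "log2") stop("infer_genetic_sex: expects log2-scale expression")
  present <- intersect(chrY_genes, rownames(expr$values))
  if (length(present) < 2) stop("infer_genetic_sex: need at least 2 chrY genes present")
  m <- t(expr$values[present, , drop = FALSE])
  if (all(apply(m, 2, stats::sd) == 0)) {
    return(list(label = rep(NA_character_, nrow(m)), mismatches = character(),
                degenerate = TRUE))
  }
  km <- stats::kmeans(m, centers = 2, nstart = 10)
  male_cl <- which.max(tapply(rowMeans(m), km$cluster, mean))
  lab <- ifelse(km$cluster == male_cl, "male", "female")
  degenerate <- abs(diff(sort(tapply(rowMeans(m), km$cluster, mean)))) < 1e-8
  mism <- character()
  if (!is.null(recorded_gender) && !degenerate) {
    rec <- ifelse(recorded_gender == 1, "male", "female")
    mism <- colnames(expr$values)[lab != rec]
  }
  list(label = stats::setNames(lab, colnames(expr$values)),
       mismatches = mism, degenerate = degenerate)
}

#' Principal components of expression for technical-variation checks
#'
#' Top-k sample scores of the gene-centered log2 matrix. The sign of each
#' component is fixed so that the loading with the largest magnitude is
#' positive.
#'
#' @param expr log2-scale `expression_matrix`.
#' @param k number of components.
#' @return samples x k score matrix with attribute `var_explained`.
#' @export
pca_expression <- function(expr, k) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (expr$scale != "log2") stop("pca_expression: expects log2-scale expression")
  if (k > min(dim(expr$values))) stop("pca_expression: k exceeds matrix rank bound")
  if (k == 0) {
    out <- matrix(numeric(0), ncol(expr$values), 0,
                  dimnames = list(colnames(expr$values), NULL))
    attr(out, "var_explained") <- numeric(0)
    return(out)
  }
  pc <- stats::prcomp(t(expr$values), center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(rot[, j]))
    if (rot[i_max, j] < 0) { rot[, j] <- -rot[, j]; scores[, j] <- -scores[, j] }
  }
  attr(scores, "var_explained") <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  scores
}
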