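#' Enumerate cis gene-SNP pairs
#'
#' All (gene, SNP) pairs on the same chromosome with the SNP within
#' `window` bp of the gene's transcription start site, inclusive at both
#' ends (1 Mb up- and downstream by default).
#'
#' @param gene_annotation data frame with columns `gene`, `chrom`, `tss`.
#' @param snp_annotation data frame with columns `snp`, `chrom`, `pos`.
#' @param window cis window in bp (default 1e6).
#' @return data frame with columns `gene`, `snp`, `distance` (pos - TSS).
#' @export
build_cis_pairs <- function(gene_annotation, snp_annotation, window = 1e6) {
  out <- lapply(seq_len(nrow(gene_annotation)), function(i) {
    g <- gene_annotation[i, ]
    sel <- snp_annotation$chrom == g$chrom &
      abs(snp_annotation$pos - g$tss) <= window
    if (!any(sel)) return(NULL)
    data.frame(gene = g$gene, snp = snp_annotation$snp[sel],
               distance = snp_annotation$pos[sel] - g$tss,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(gene = character(), snp = character(),
                                      distance = numeric())
  rownames(out) <- NULL
  out
}

# Residualize columns of m on the covariate matrix C (with intercept);
# returns residuals. Used for the Frisch-Waugh form of the per-pair OLS.
residualize <- function(m, covariates) {
  qr_c <- qr(covariates)
  if (qr_c$rank < ncol(covariates)) {
    bad <- colnames(covariates)[-seq_len(qr_c$rank)]
    stop("collinear covariates: ", paste(qr_c$pivot[-seq_len(qr_c$rank)],
                                         collapse = ", "),
         if (!is.null(colnames(covariates)))
           paste0(" (", paste(colnames(covariates)[qr_c$pivot[-seq_len(qr_c$rank)]],
                              collapse = ", "), ")"))
  }
  qr.resid(qr_c, m)
}

# covariate matrix with intercept from a plain matrix / NULL
covmat_with_intercept <- function(covariates, n) {
  if (is.null(covariates)) {
    matrix(1, n, 1, dimnames = list(NULL, "(intercept)"))
  } else {
    cbind("(intercept)" = 1, as.matrix(covariates))
  }
}

#' Nominal cis-eQTL scan
#'
#' Per (gene, SNP) pair, ordinary least squares of log2 expression on allele
#' dosage with covariate adjustment (computed in residualized form, exactly
#' equivalent to the full multiple regression): effect per allele, its
#' standard error, and a two-sided t-test p-value. Pairs whose dosage is
#' constant are skipped and listed in the `skipped` attribute.
#'
#' @param expr log2-scale `expression_matrix`.
#' @param geno `genotype_matrix` on the same samples (same column/row order).
#' @param covariates numeric matrix (samples x q) or NULL; an intercept is
#'   always included.
#' @param pairs data frame from [build_cis_pairs()].
#' @return data frame (`gene`, `snp`, `beta`, `se`, `nominal_p`) of class
#'   `eqtl_table`, with attribute `skipped`.
#' @export
nominal_scan <- function(expr, geno, covariates = NULL, pairs) {
  stopifnot(inherits(expr, "expression_matrix"), inherits(geno, "genotype_matrix"))
  if (!identical(colnames(expr$values), rownames(geno$dosages))) {
    stop("nominal_scan: expression and genotype samples differ or are unordered")
  }
  n <- ncol(expr$values)
  C <- covmat_with_intercept(covariates, n)
  q <- ncol(C)
  df <- n - q - 1
  if (df < 1) stop("nominal_scan: not enough samples for covariate set")
  keep_snps <- intersect(unique(pairs$snp), colnames(geno$dosages))
  X <- residualize(geno$dosages[, keep_snps, drop = FALSE], C)
  Y <- residualize(t(expr$values[unique(pairs$gene), , drop = FALSE]), C)
  xss <- colSums(X^2)
  const <- xss < 1e-12
  rows <- vector("list", length(unique(pairs$gene)))
  skipped <- character()
  genes <- unique(pairs$gene)
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    snps <- pairs$snp[pairs$gene == g]
    snps <- snps[snps %in% keep_snps]
    ok <- !const[snps]
    if (any(!ok)) skipped <- c(skipped, paste(g, snps[!ok], sep = ":"))
    snps <- snps[ok]
    if (!length(snps)) next
    y <- Y[, g]
    xy <- colSums(X[, snps, drop = FALSE] * y)
    beta <- xy / xss[snps]
    rss <- sum(y^2) - beta^2 * xss[snps]
    se <- sqrt(pmax(rss, 0) / df / xss[snps])
    tstat <- beta / se
    rows[[gi]] <- data.frame(gene = g, snp = snps, beta = beta, se = se,
                             nominal_p = 2 * stats::pt(-abs(tstat), df),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(gene = character(), snp = character(),
                                      beta = numeric(), se = numeric(),
                                      nominal_p = numeric())
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("eqtl_table", "data.frame")
  out
}

#' Permutation-based gene-level adjusted p-value
#'
#' Freedman-Lane residual permutation: expression residuals (after covariate
#' regression) are permuted across samples and the best cis association
#' statistic is recomputed each time. The adjusted p-value is
#' (1 + #\{permutation best p <= observed best p\}) / (1 + n_perm), honoring
#' the 1/(n_perm + 1) floor. In adaptive mode permutations run in blocks of
#' 100 and stop once 100 exceedances have accrued.
#'
#' @inheritParams nominal_scan
#' @param gene gene id (must have at least one cis SNP in `pairs`).
#' @param n_perm number of permutations (>= 100).
#' @param adaptive stop early after 100 exceedances (default TRUE).
#' @param seed optional permutation seed for bit-reproducibility.
#' @return list with `gene`, `adjusted_p`, `best_snp`, `best_nominal_p`,
#'   `n_perm_used`.
#' @export
permutation_gene_pvalue <- function(expr, geno, covariates = NULL, gene, pairs,
                                    n_perm = 10000, adaptive = TRUE,
                                    seed = NULL) {
  if (n_perm < 100) stop("permutation_gene_pvalue: n_perm must be >= 100")
  snps <- pairs$snp[pairs$gene == gene]
  snps <- intersect(snps, colnames(geno$dosages))
  if (!length(snps)) stop("permutation_gene_pvalue: gene has no cis SNPs")
  n <- ncol(expr$values)
  C <- covmat_with_intercept(covariates, n)
  X <- residualize(geno$dosages[, snps, drop = FALSE], C)
  keep <- colSums(X^2) > 1e-12
  X <- X[, keep, drop = FALSE]
  snps <- snps[keep]
  if (!length(snps)) stop("permutation_gene_pvalue: all cis SNPs constant")
  y <- drop(residualize(cbind(expr$values[gene, ]), C))
  # |t| is monotone in |correlation| of residualized vectors, so the
  # permutation comparison can use squared correlations directly
  Xs <- sweep(X, 2, sqrt(colSums(X^2)), "/")
  ys <- y / sqrt(sum(y^2))
  r_obs <- drop(crossprod(Xs, ys))
  best_r2 <- max(r_obs^2)
  best_snp <- snps[which.max(r_obs^2)]
  df <- n - ncol(C) - 1
  t_obs <- sqrt(best_r2 * df / max(1 - best_r2, 1e-300))
  best_p <- 2 * stats::pt(-t_obs, df)

  if (!is.null(seed)) set.seed(seed)
  exceed <- 0L; used <- 0L
  block <- 100L
  while (used < n_perm) {
    b <- min(block, n_perm - used)
    P <- vapply(seq_len(b), function(i) ys[sample.int(n)], numeric(n))
    r2max <- apply(crossprod(Xs, P)^2, 2, max)
    exceed <- exceed + sum(r2max >= best_r2)
    used <- used + b
    if (adaptive && exceed >= 100L) break
  }
  list(gene = gene, adjusted_p = (1 + exceed) / (1 + used),
       best_snp = best_snp, best_nominal_p = best_p, n_perm_used = used)
}

#' Full cis-eQTL map: nominal scan plus gene-level permutation p-values
#'
#' @inheritParams nominal_scan
#' @param window cis window in bp.
#' @param n_perm permutations per gene.
#' @param adaptive adaptive early stopping.
#' @param seed permutation seed.
#' @return list with `pairs_table` (eqtl_table) and `gene_table` (per gene:
#'   `best_snp`, `best_nominal_p`, `adjusted_p`, `n_perm_used`).
#' @export
eqtl_map <- function(expr, geno, covariates = NULL, window = 1e6,
                     n_perm = 1000, adaptive = TRUE, seed = NULL) {
  pairs <- build_cis_pairs(expr$gene_annotation, geno$snp_annotation, window)
  tab <- nominal_scan(expr, geno, covariates, pairs)
  genes <- unique(tab$gene)
  if (!is.null(seed)) set.seed(seed)
  per_gene <- lapply(genes, function(g) {
    r <- permutation_gene_pvalue(expr, geno, covariates, g, pairs,
                                 n_perm = n_perm, adaptive = adaptive)
    data.frame(gene = g, best_snp = r$best_snp,
               best_nominal_p = r$best_nominal_p,
               adjusted_p = r$adjusted_p, n_perm_used = r$n_perm_used,
               stringsAsFactors = FALSE)
  })
  gene_table <- do.call(rbind, per_gene)
  list(pairs_table = tab, gene_table = gene_table)
}

#' Select eGenes at a gene-level adjusted significance threshold
#'
#' @param gene_table per-gene table from [eqtl_map()].
#' @param alpha threshold; genes with `adjusted_p` strictly below it pass.
#' @return character vector of eGene ids.
#' @export
select_egenes <- function(gene_table, alpha = 0.05) {
  if (!nrow(gene_table)) return(character())
  gene_table$gene[gene_table$adjusted_p < alpha]
}
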