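#' Cluster genes by expression profile
#'
#' k-means on gene rows (samples as features), 25 restarts, best inertia
#' kept. Used to split eGenes into groups small enough for multivariable
#' hazard models without overfitting.
#'
#' @param expr log2-scale `expression_matrix` restricted to the genes of
#'   interest.
#' @param k number of clusters (default 4).
#' @param seed RNG seed for the restarts.
#' @return named integer vector gene -> cluster.
#' @export
cluster_genes <- function(expr, k = 4, seed = 1L) {
  stopifnot(inherits(expr, "expression_matrix"))
  m <- expr$values
  if (k > nrow(m)) stop("cluster_genes: k exceeds number of genes")
  set.seed(seed)
  km <- stats::kmeans(m, centers = k, nstart = 25, iter.max = 50)
  stats::setNames(km$cluster, rownames(m))
}

# Build the hazard-model design: intercept, standardized covariates Z,
# enriched cell abundances E, and the supplied gene columns (centered).
# Collinear gene columns are dropped (logged in attribute "dropped").
hazard_design <- function(clinical, abundance, gene_mat) {
  Z <- clinical_design(clinical)
  E <- as.matrix(abundance)
  X <- cbind("(intercept)" = 1, Z, E)
  dropped <- character()
  if (!is.null(gene_mat) && ncol(gene_mat)) {
    G <- scale(gene_mat, center = TRUE, scale = FALSE)
    full <- cbind(X, G)
    qr_f <- qr(full)
    if (qr_f$rank < ncol(full)) {
      bad <- sort(qr_f$pivot[-seq_len(qr_f$rank)])
      bad_genes <- colnames(full)[bad]
      dropped <- intersect(bad_genes, colnames(G))
      if (length(setdiff(bad_genes, colnames(G)))) {
        stop("hazard_design: covariate block rank-deficient")
      }
      G <- G[, setdiff(colnames(G), dropped), drop = FALSE]
    }
    X <- cbind(X, G)
  }
  attr(X, "dropped") <- dropped
  X
}

#' Screen genes for association with overall survival
#'
#' Within one treatment arm, fits one multivariable additive-hazard model
#' per gene cluster containing all of that cluster's genes (centered log2
#' expression) plus the clinical covariates Z and cell abundances E. Genes
#' whose per-covariate endpoint p-value is strictly below `alpha` pass the
#' screen.
#'
#' @param expr log2-scale `expression_matrix` of candidate genes (eGenes).
#' @param clinical `clinical_table` aligned to the expression samples.
#' @param abundance samples x cell-types matrix (enriched types).
#' @param clusters named gene -> cluster map from [cluster_genes()].
#' @param arm treatment arm to analyse.
#' @param alpha screen threshold (default 0.1, strict).
#' @return data frame (`gene`, `cluster`, `coef`, `z`, `p`, `pass`) with
#'   attribute `dropped` (genes removed for collinearity).
#' @export
screen_gene_os <- function(expr, clinical, abundance, clusters, arm,
                           alpha = 0.1) {
  sel <- clinical$arm == arm
  if (sum(clinical$event[sel]) < 30) {
    stop("screen_gene_os: fewer than 30 events in arm ", arm)
  }
  clin <- clinical[sel, , drop = FALSE]
  ab <- abundance[sel, , drop = FALSE]
  ex <- expr$values[names(clusters), sel, drop = FALSE]
  res <- list(); dropped <- character()
  for (cl in sort(unique(clusters))) {
    genes <- names(clusters)[clusters == cl]
    G <- t(ex[genes, , drop = FALSE])
    X <- hazard_design(clin, ab, G)
    dropped <- c(dropped, attr(X, "dropped"))
    fit <- fit_additive_hazard(clin$os_time, clin$event, X)
    kept <- intersect(genes, names(fit$p))
    res[[as.character(cl)]] <- data.frame(
      gene = kept, cluster = cl,
      coef = fit$cumcoef[fit$k_eval, kept] / fit$tau,
      z = fit$z[kept], p = fit$p[kept],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  out$pass <- out$p < alpha
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Select LD-independent instruments for a gene
#'
#' Candidate SNPs are the gene's cis SNPs with nominal eQTL p < `p_nominal`.
#' They are grouped by average-linkage hierarchical clustering on the
#' distance 1 - r^2 with the tree cut at height 1 - `r2_max`, and one
#' representative per cluster is taken (smallest nominal p; ties broken by
#' genomic position). Representatives are then greedily pruned so that every
#' retained pair satisfies r^2 <= `r2_max`. Instrument weights are the
#' representatives' marginal eQTL effect sizes.
#'
#' @param eqtl `eqtl_table` from [nominal_scan()].
#' @param geno discovery `genotype_matrix`.
#' @param gene gene id.
#' @param p_nominal candidate threshold (default 0.05).
#' @param r2_max maximum pairwise r^2 among selected instruments.
#' @return list of class `instrument_set` (`gene`, `snps`, `weights`,
#'   `source`) or NULL (with a message) when no candidate passes.
#' @export
select_instruments <- function(eqtl, geno, gene, p_nominal = 0.05,
                               r2_max = 0.1) {
  cand <- eqtl[eqtl$gene == gene & eqtl$nominal_p < p_nominal, , drop = FALSE]
  if (!nrow(cand)) {
    message("select_instruments: no candidate SNPs for ", gene, "; gene dropped")
    return(NULL)
  }
  pos <- geno$snp_annotation$pos[match(cand$snp, geno$snp_annotation$snp)]
  ord <- order(cand$nominal_p, pos)
  cand <- cand[ord, , drop = FALSE]; pos <- pos[ord]
  if (nrow(cand) == 1) {
    cl <- 1L
  } else {
    r2 <- stats::cor(geno$dosages[, cand$snp, drop = FALSE])^2
    hc <- stats::hclust(stats::as.dist(1 - r2), method = "average")
    cl <- stats::cutree(hc, h = 1 - r2_max)[cand$snp]
  }
  reps <- cand[!duplicated(cl), , drop = FALSE]  # first = best p per cluster
  # greedy prune: enforce pairwise r2 <= r2_max among representatives
  if (nrow(reps) > 1) {
    r2r <- stats::cor(geno$dosages[, reps$snp, drop = FALSE])^2
    keep <- logical(nrow(reps))
    for (i in seq_len(nrow(reps))) {
      keep[i] <- !any(keep & r2r[i, ] > r2_max)
    }
    reps <- reps[keep, , drop = FALSE]
  }
  structure(list(gene = gene, snps = reps$snp,
                 weights = stats::setNames(reps$beta, reps$snp),
                 nominal_p = stats::setNames(reps$nominal_p, reps$snp),
                 source = "discovery"),
            class = "instrument_set")
}

#' Exclude instruments with direct effects on survival (pleiotropy screen)
#'
#' Per instrument, a Cox proportional-hazards GWAS-style fit of overall
#' survival on allele dosage plus covariates; instruments with Wald
#' p < `p_exclude` are removed as likely pleiotropic.
#'
#' @param instr `instrument_set`.
#' @param geno `genotype_matrix` with the instrument SNPs.
#' @param clinical `clinical_table` aligned to `geno` samples.
#' @param covariates numeric matrix of Cox covariates (e.g. gender, age,
#'   all-RAS, first expression PC); no intercept column.
#' @param p_exclude exclusion threshold (default 1e-4, strict).
#' @return pruned `instrument_set` with attribute `excluded` (SNP ids), or
#'   NULL (message) when every instrument is excluded.
#' @export
check_pleiotropy <- function(instr, geno, clinical, covariates,
                             p_exclude = 1e-4) {
  stopifnot(inherits(instr, "instrument_set"))
  excl <- character()
  for (s in instr$snps) {
    X <- cbind(dosage = geno$dosages[, s], covariates)
    fit <- fit_cox(clinical$os_time, clinical$event, X)
    if (fit$p["dosage"] < p_exclude) excl <- c(excl, s)
  }
  keep <- setdiff(instr$snps, excl)
  if (!length(keep)) {
    message("check_pleiotropy: all instruments of ", instr$gene,
            " excluded; gene dropped")
    return(NULL)
  }
  out <- instr
  out$snps <- keep
  out$weights <- instr$weights[keep]
  out$nominal_p <- instr$nominal_p[keep]
  attr(out, "excluded") <- excl
  out
}

#' Predict gene expression from instruments (one-sample)
#'
#' \eqn{\hat g = Q W}: centered instrument dosages times the marginal eQTL
#' weights. The Pearson correlation with observed expression is recorded;
#' the prediction is usable for the causal test only when it exceeds 0.5.
#'
#' @param geno `genotype_matrix`.
#' @param instr `instrument_set`.
#' @param expr observed log2-scale `expression_matrix` (for the correlation
#'   gate); NULL skips the gate (correlation NA).
#' @param cor_min gate threshold (default 0.5, strict).
#' @return list of class `predicted_expression`: `gene`, `ghat` (named by
#'   sample), `correlation`, `prediction_ok`, `cohort`.
#' @export
predict_expression_onesample <- function(geno, instr, expr = NULL,
                                         cor_min = 0.5) {
  stopifnot(inherits(instr, "instrument_set"))
  missing <- setdiff(instr$snps, colnames(geno$dosages))
  if (length(missing)) {
    stop("predict_expression_onesample: instrument SNPs absent from genotypes: ",
         paste(missing, collapse = ", "))
  }
  Q <- scale(geno$dosages[, instr$snps, drop = FALSE], center = TRUE, scale = FALSE)
  ghat <- drop(Q %*% instr$weights)
  names(ghat) <- rownames(geno$dosages)
  correlation <- NA_real_
  ok <- TRUE
  if (!is.null(expr)) {
    obs <- expr$values[instr$gene, names(ghat)]
    correlation <- if (stats::sd(ghat) > 0) stats::cor(ghat, obs) else NA_real_
    ok <- !is.na(correlation) && correlation > cor_min
  } else if (stats::sd(ghat) == 0) {
    ok <- FALSE
  }
  structure(list(gene = instr$gene, ghat = ghat, correlation = correlation,
                 prediction_ok = ok, n_instruments = length(instr$snps),
                 cohort = "discovery"),
            class = "predicted_expression")
}

#' Predict expression in an outcome-only cohort (two-sample)
#'
#' \eqn{\hat g^* = Q^* (Q^\top Q)^{-1} Q^\top g}: joint least-squares weights
#' estimated on centered discovery dosages and expression, applied to
#' validation dosages centered at the discovery means. A near-singular Gram
#' matrix falls back to a ridge with penalty 1e-8 x trace (logged via
#' message).
#'
#' @param geno_validation,geno_discovery `genotype_matrix` objects sharing
#'   the instrument SNPs.
#' @param expr_discovery log2-scale `expression_matrix` (discovery).
#' @param instr `instrument_set`.
#' @return `predicted_expression` for the validation cohort (no correlation
#'   gate: expression is unobserved there).
#' @export
predict_expression_twosample <- function(geno_validation, geno_discovery,
                                         expr_discovery, instr) {
  stopifnot(inherits(instr, "instrument_set"))
  for (gm in list(geno_validation, geno_discovery)) {
    missing <- setdiff(instr$snps, colnames(gm$dosages))
    if (length(missing)) {
      stop("predict_expression_twosample: instrument SNPs absent: ",
           paste(missing, collapse = ", "))
    }
  }
  Qd <- geno_discovery$dosages[, instr$snps, drop = FALSE]
  mu <- colMeans(Qd)
  Qd <- sweep(Qd, 2, mu)
  g <- expr_discovery$values[instr$gene, rownames(geno_discovery$dosages)]
  g <- g - mean(g)
  Gm <- crossprod(Qd)
  w <- tryCatch(solve(Gm, crossprod(Qd, g)), error = function(e) NULL)
  if (is.null(w) || !all(is.finite(w)) ||
      rcond(Gm) < 1e-12) {
    message("predict_expression_twosample: singular Gram matrix for ",
            instr$gene, "; ridge fallback")
    Gm <- Gm + diag(1e-8 * sum(diag(Gm)), ncol(Gm))
    w <- solve(Gm, crossprod(Qd, g))
  }
  Qv <- sweep(geno_validation$dosages[, instr$snps, drop = FALSE], 2, mu)
  ghat <- drop(Qv %*% w)
  names(ghat) <- rownames(geno_validation$dosages)
  structure(list(gene = instr$gene, ghat = ghat, correlation = NA_real_,
                 prediction_ok = TRUE, weights = drop(w),
                 n_instruments = length(instr$snps), cohort = "validation"),
            class = "predicted_expression")
}

#' Causal test: predicted expression vs overall survival
#'
#' Per treatment arm, one multivariable additive-hazard fit containing every
#' usable predicted expression \eqn{\hat g} (centered) together with the
#' clinical covariates Z and cell abundances E. A gene is flagged causal in
#' an arm when its endpoint p-value is strictly below `alpha`; both arms'
#' p-values are reported for comparison.
#'
#' @param predictions list of `predicted_expression` objects.
#' @param clinical `clinical_table`.
#' @param abundance samples x cell-types matrix.
#' @param arms arms to test (default both).
#' @param alpha causal threshold (default 0.05).
#' @return data frame (`gene`, `arm`, `coef`, `z`, `p`, `causal`,
#'   `correlation`, `n_instruments`); empty when no prediction passes the
#'   gate.
#' @export
causal_test <- function(predictions, clinical, abundance,
                        arms = c("bevacizumab", "cetuximab"), alpha = 0.05) {
  preds <- Filter(function(p) isTRUE(p$prediction_ok), predictions)
  if (!length(preds)) {
    return(data.frame(gene = character(), arm = character(), coef = numeric(),
                      z = numeric(), p = numeric(), causal = logical(),
                      correlation = numeric(), n_instruments = integer()))
  }
  G <- do.call(cbind, lapply(preds, function(p) p$ghat[clinical$sample_id]))
  colnames(G) <- vapply(preds, function(p) p$gene, character(1))
  res <- list()
  for (arm in arms) {
    sel <- clinical$arm == arm
    clin <- clinical[sel, , drop = FALSE]
    X <- hazard_design(clin, abundance[sel, , drop = FALSE],
                       G[sel, , drop = FALSE])
    fit <- fit_additive_hazard(clin$os_time, clin$event, X)
    kept <- intersect(colnames(G), names(fit$p))
    res[[arm]] <- data.frame(
      gene = kept, arm = arm,
      coef = fit$cumcoef[fit$k_eval, kept] / fit$tau,
      z = fit$z[kept], p = fit$p[kept],
      causal = fit$p[kept] < alpha,
      correlation = vapply(preds, function(p) p$correlation, numeric(1))[
        match(kept, colnames(G))],
      n_instruments = vapply(preds, function(p) p$n_instruments,
                             integer(1))[match(kept, colnames(G))],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Run the full Mendelian-randomization pipeline
#'
#' One-sample MR on the discovery cohort (gene clustering, OS screen,
#' instrument selection, pleiotropy exclusion, expression prediction with
#' the correlation gate, arm-specific additive-hazard causal test), followed
#' by two-sample replication on the validation cohort. Emits per-stage
#' counts; when generator truth is supplied, a confusion summary against the
#' planted causal genes is added.
#'
#' @param cohorts list with `discovery` and (optionally) `validation`
#'   cohorts as produced by [make_cohort()] (preprocessed data may be
#'   substituted in the same shapes).
#' @param egenes character vector of eGene ids to analyse (from
#'   [select_egenes()]); when NULL, computed internally via [eqtl_map()].
#' @param alpha_screen,alpha_causal,p_nominal,r2_max,p_pleiotropy stage
#'   thresholds (defaults 0.1, 0.05, 0.05, 0.1, 1e-4).
#' @param cor_min correlation gate for one-sample predictions.
#' @param n_perm permutations for the internal eQTL map when `egenes` is
#'   NULL.
#' @param k_clusters gene clusters for the screen (default 4, reduced when
#'   fewer genes).
#' @param seed RNG seed (clustering restarts, permutations).
#' @param truth optional generator truth record for the audit summary.
#' @return list of class `mr_result`: `results` (MRResult rows: gene, arm,
#'   stage flags, screen/causal statistics), `replication` (two-sample
#'   causal table or NULL), `counts` (per-stage funnel), `audit` (log lines),
#'   `instruments`.
#' @export
run_mr <- function(cohorts, egenes = NULL,
                   alpha_screen = 0.1, alpha_causal = 0.05,
                   p_nominal = 0.05, r2_max = 0.1, p_pleiotropy = 1e-4,
                   cor_min = 0.5, n_perm = 1000, k_clusters = 4,
                   seed = 1L, truth = NULL) {
  disc <- cohorts$discovery
  vali <- cohorts$validation
  expr <- disc$expression
  geno <- disc$genotypes
  clin <- clinical_table(disc$clinical)
  ab <- disc$abundance
  audit <- character()
  set.seed(seed)

  pairs <- build_cis_pairs(expr$gene_annotation, geno$snp_annotation)
  Z <- clinical_design(clin)
  eq_cov <- cbind(Z, ab)
  if (is.null(egenes)) {
    em <- eqtl_map(expr, geno, eq_cov, n_perm = n_perm, seed = seed)
    eq <- em$pairs_table
    egenes <- select_egenes(em$gene_table)
  } else {
    eq <- nominal_scan(expr, geno, eq_cov, pairs)
  }
  audit <- c(audit, sprintf("egenes: %d", length(egenes)))
  if (!length(egenes)) stop("run_mr: no eGenes to analyse")

  expr_eg <- expression_matrix(expr$values[egenes, , drop = FALSE],
                               expr$gene_annotation, scale = "log2")
  k <- min(k_clusters, length(egenes))
  clusters <- cluster_genes(expr_eg, k = k, seed = seed)

  arms <- c("bevacizumab", "cetuximab")
  screens <- lapply(arms, function(a)
    screen_gene_os(expr_eg, clin, ab, clusters, a, alpha = alpha_screen))
  names(screens) <- arms

  pc1 <- pca_expression(expr, 1)
  cox_cov <- cbind(gender = clin$gender,
                   age = (clin$age - mean(clin$age)) / stats::sd(clin$age),
                   ras = clin$all_ras, pc1 = pc1[clin$sample_id, 1])

  results <- list(); instruments <- list(); predictions <- list()
  screened_by_arm <- lapply(screens, function(s) s$gene[s$pass])
  screened_any <- unique(unlist(screened_by_arm))
  audit <- c(audit, sprintf("screened: %d (%s)", length(screened_any),
                            paste(arms, vapply(screened_by_arm, length, 1L),
                                  sep = "=", collapse = ", ")))
  for (g in screened_any) {
    instr <- select_instruments(eq, geno, g, p_nominal = p_nominal,
                                r2_max = r2_max)
    if (is.null(instr)) next
    instr <- check_pleiotropy(instr, geno, clin, cox_cov,
                              p_exclude = p_pleiotropy)
    if (is.null(instr)) next
    instruments[[g]] <- instr
    predictions[[g]] <- predict_expression_onesample(geno, instr, expr,
                                                     cor_min = cor_min)
  }
  audit <- c(audit, sprintf("instrumented: %d", length(instruments)),
             sprintf("prediction_ok: %d",
                     sum(vapply(predictions, function(p) p$prediction_ok,
                                logical(1)))))
  # each arm's causal model contains only that arm's screen survivors
  causal <- do.call(rbind, lapply(arms, function(a) {
    preds_a <- predictions[intersect(screened_by_arm[[a]], names(predictions))]
    causal_test(preds_a, clin, ab, arms = a, alpha = alpha_causal)
  }))

  rows <- list()
  for (g in screened_any) {
    for (a in arms) {
      srow <- screens[[a]][screens[[a]]$gene == g, , drop = FALSE]
      crow <- causal[causal$gene == g & causal$arm == a, , drop = FALSE]
      pred <- predictions[[g]]
      rows[[paste(g, a)]] <- data.frame(
        gene = g, arm = a,
        screened = nrow(srow) > 0 && srow$pass,
        instrumented = !is.null(instruments[[g]]),
        prediction_ok = !is.null(pred) && pred$prediction_ok,
        causal = nrow(crow) > 0 && crow$causal &&
          nrow(srow) > 0 && srow$pass,
        screen_p = if (nrow(srow)) srow$p else NA_real_,
        causal_coef = if (nrow(crow)) crow$coef else NA_real_,
        causal_p = if (nrow(crow)) crow$p else NA_real_,
        correlation = if (!is.null(pred)) pred$correlation else NA_real_,
        n_instruments = if (!is.null(instruments[[g]]))
          length(instruments[[g]]$snps) else 0L,
        stringsAsFactors = FALSE
      )
    }
  }
  results <- do.call(rbind, c(rows, make.row.names = FALSE))
  # stage monotonicity by construction: causal requires screened; predictions
  # exist only for instrumented genes
  results$prediction_ok <- results$prediction_ok & results$instrumented
  results$causal <- results$causal & results$prediction_ok

  replication <- NULL
  if (!is.null(vali) && !is.null(vali$genotypes) && vali$n > 0) {
    causal_genes <- unique(results$gene[results$causal])
    if (length(causal_genes)) {
      preds2 <- lapply(causal_genes, function(g)
        predict_expression_twosample(vali$genotypes, geno, expr,
                                     instruments[[g]]))
      replication <- causal_test(preds2, clinical_table(vali$clinical),
                                 vali$abundance, arms = arms,
                                 alpha = alpha_causal)
      audit <- c(audit, sprintf("replication tested: %d genes",
                                length(causal_genes)))
    } else {
      audit <- c(audit, "replication tested: 0 genes")
    }
  }

  counts <- c(egenes = length(egenes), screened = length(screened_any),
              instrumented = length(instruments),
              prediction_ok = sum(vapply(predictions, function(p)
                p$prediction_ok, logical(1))),
              causal = length(unique(results$gene[results$causal])))
  out <- list(results = results, replication = replication, counts = counts,
              audit = audit, instruments = instruments,
              predictions = predictions, screens = screens)
  if (!is.null(truth) && nrow(truth$causal_genes)) {
    tg <- truth$causal_genes
    hit <- mapply(function(g, a) {
      any(results$gene == g & results$arm == a & results$causal)
    }, tg$gene, tg$arm)
    false_pos <- results$causal &
      !mapply(function(g, a) any(tg$gene == g & tg$arm == a),
              results$gene, results$arm)
    out$confusion <- list(planted = nrow(tg), recovered = sum(hit),
                          false_positive_rows = sum(false_pos))
  }
  class(out) <- "mr_result"
  out
}

#' @export
print.mr_result <- function(x, ...) {
  cat("MR pipeline funnel:\n")
  print(x$counts)
  if (!is.null(x$confusion)) {
    cat(sprintf("planted causal genes recovered: %d/%d\n",
                x$confusion$recovered, x$confusion$planted))
  }
  invisible(x)
}
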