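#' Simulation configuration for synthetic cohorts
#'
#' Defines the generative model the rest of the pipeline assumes: biallelic
#' SNPs in per-gene cis blocks with AR(1)-like LD, expression with planted
#' cis-eQTL effects plus a cell-composition confounder, and survival times
#' from an additive hazard with treatment-specific gene effects and
#' independent uniform censoring.
#'
#' @param n_discovery,n_validation cohort sizes; the discovery cohort carries
#'   expression, the validation cohort only genotypes and clinical outcomes.
#' @param n_genes,n_snps_per_gene number of genes and cis SNPs per gene block.
#' @param maf_range minor-allele-frequency range, within \[0.05, 0.5\].
#' @param ld_rho latent adjacent-SNP correlation within a block, in \[0, 1).
#' @param eqtl_h2 fraction of log2-expression variance explained by the
#'   planted cis SNPs of each eGene.
#' @param n_egenes number of genes given a genetic component (the first
#'   `n_egenes` genes).
#' @param causal_genes data frame with columns `gene` (id), `arm`
#'   ("bevacizumab" or "cetuximab") and `slope` (hazard increment per unit
#'   log2-expression per month); may be empty.
#' @param pleiotropic_snps data frame with columns `snp` (id) and `effect`
#'   (direct additive hazard per allele per month); may be empty.
#' @param confounder_strength loading (sd units) of the standardized
#'   cell-abundance confounder on each gene's expression; the same value
#'   scales its hazard loading (`confounder_strength * 0.01` per month).
#' @param censoring_rate target fraction of censored subjects, in \[0, 1).
#' @param baseline_hazard constant baseline hazard, per month.
#' @param covariate_effects named vector of additive hazard effects (per
#'   month) for `age` (per SD), `gender`, `braf`, `ras`.
#' @param n_cell_types number of immune-cell abundance columns; the first is
#'   the confounder.
#' @param cms_genes ids of the two genes whose expression tilts the CMS
#'   label probabilities.
#' @param cms_strength logit scale of that tilt (0 = labels independent of
#'   expression).
#' @param n_pairs,paired_sd,paired_genes paired tumor/normal design: number
#'   of pairs, residual sd of each log2 measurement, and a data frame with
#'   columns `gene`, `log2fc` of planted fold-changes.
#' @param seed integer RNG seed.
#' @return object of class `sim_config` (validated list).
#' @export
sim_config <- function(n_discovery = 273, n_validation = 602,
                       n_genes = 60, n_snps_per_gene = 5,
                       maf_range = c(0.1, 0.5), ld_rho = 0.9,
                       eqtl_h2 = 0.3, n_egenes = 20,
                       causal_genes = NULL, pleiotropic_snps = NULL,
                       confounder_strength = 0.3, censoring_rate = 0.3,
                       baseline_hazard = 0.025,
                       covariate_effects = c(age = 0.004, gender = 0.002,
                                             braf = 0.012, ras = 0.006),
                       n_cell_types = 5,
                       cms_genes = NULL, cms_strength = 1.5,
                       n_pairs = 24, paired_sd = 1, paired_genes = NULL,
                       seed = 1L) {
  if (is.null(causal_genes)) {
    causal_genes <- data.frame(gene = character(), arm = character(),
                               slope = numeric())
  }
  if (is.null(pleiotropic_snps)) {
    pleiotropic_snps <- data.frame(snp = character(), effect = numeric())
  }
  cfg <- list(
    n_discovery = as.integer(n_discovery), n_validation = as.integer(n_validation),
    n_genes = as.integer(n_genes), n_snps_per_gene = as.integer(n_snps_per_gene),
    maf_range = as.numeric(maf_range), ld_rho = ld_rho, eqtl_h2 = eqtl_h2,
    n_egenes = as.integer(n_egenes), causal_genes = causal_genes,
    pleiotropic_snps = pleiotropic_snps,
    confounder_strength = confounder_strength, censoring_rate = censoring_rate,
    baseline_hazard = baseline_hazard, covariate_effects = covariate_effects,
    n_cell_types = as.integer(n_cell_types),
    cms_genes = cms_genes, cms_strength = cms_strength,
    n_pairs = as.integer(n_pairs), paired_sd = paired_sd,
    paired_genes = paired_genes,
    seed = as.integer(seed) %% .Machine$integer.max
  )
  stopifnot(
    cfg$n_egenes <= cfg$n_genes,
    length(cfg$maf_range) == 2,
    cfg$maf_range[1] >= 0.05, cfg$maf_range[2] <= 0.5,
    cfg$maf_range[1] <= cfg$maf_range[2],
    cfg$ld_rho >= 0, cfg$ld_rho < 1,
    cfg$censoring_rate >= 0, cfg$censoring_rate < 1
  )
  if (cfg$eqtl_h2 >= 1 || cfg$eqtl_h2 < 0) stop("sim_config: eqtl_h2 must lie in [0, 1)")
  if (nrow(cfg$causal_genes)) {
    egene_ids <- sprintf("gene%03d", seq_len(cfg$n_egenes))
    if (!all(cfg$causal_genes$gene %in% egene_ids)) {
      stop("sim_config: causal genes must be eGenes (gene001..gene", cfg$n_egenes, ")")
    }
    stopifnot(all(cfg$causal_genes$arm %in% c("bevacizumab", "cetuximab")))
  }
  if (is.null(cfg$cms_genes)) {
    cfg$cms_genes <- sprintf("gene%03d", seq_len(min(2L, cfg$n_genes)))
  }
  class(cfg) <- "sim_config"
  cfg
}

gene_ids <- function(config) sprintf("gene%03d", seq_len(config$n_genes))

# Fixed genetic architecture shared by the discovery and validation cohorts:
# SNP positions/MAFs, which cis SNPs carry eQTL effects and with what raw
# weights, and the CMS tilt directions. Drawn once per seed so that the two
# cohorts are draws from the same population.
sim_architecture <- function(config) {
  set.seed(config$seed)
  ng <- config$n_genes; ps <- config$n_snps_per_gene
  genes <- gene_ids(config)
  tss <- 2e6 + (seq_len(ng) - 1) * 3e6  # windows (+-1 Mb) never overlap
  gene_annotation <- data.frame(gene = genes, chrom = "1", tss = tss,
                                stringsAsFactors = FALSE)
  snp <- sprintf("%s_snp%d", rep(genes, each = ps), rep(seq_len(ps), ng))
  pos <- rep(tss, each = ps) + rep(seq(-2e4, 2e4, length.out = ps), ng)
  maf <- stats::runif(ng * ps, config$maf_range[1], config$maf_range[2])
  snp_annotation <- data.frame(snp = snp, chrom = "1", pos = round(pos),
                               ref = "A", alt = "B", maf = maf,
                               gene = rep(genes, each = ps),
                               stringsAsFactors = FALSE)
  # planted eQTL weights: one causal lead variant per eGene (mid-block),
  # random sign; magnitude is rescaled to the target h2 at draw time
  beta <- matrix(0, ps, ng, dimnames = list(NULL, genes))
  lead <- ceiling(ps / 2)
  for (g in seq_len(config$n_egenes)) {
    beta[lead, g] <- sample(c(-1, 1), 1)
  }
  cms_w <- matrix(0, 2, 4, dimnames = list(NULL, paste0("CMS", 1:4)))
  cms_w[1, ] <- c(1, 0, 0, -1)   # gene A high -> CMS1, low -> CMS4
  cms_w[2, ] <- c(0, -0.5, 1, 0) # gene B high -> CMS3
  list(gene_annotation = gene_annotation, snp_annotation = snp_annotation,
       eqtl_beta = beta, cms_w = cms_w)
}

#' Simulate genotype dosages with block LD
#'
#' Dosages in \{0, 1, 2\} for SNPs organised in per-gene cis blocks. Each
#' haplotype is a latent AR(1) Gaussian vector thresholded at the
#' allele-frequency quantile (Gaussian copula), so MAF and LD are controlled
#' jointly; a subject's dosage is the sum of two independent haplotypes.
#'
#' @param config a [sim_config()].
#' @param n number of samples (default `config$n_discovery`).
#' @param seed RNG seed (default `config$seed`).
#' @param .arch internal: pre-drawn architecture, to share MAFs and planted
#'   effects across cohorts.
#' @return `genotype_matrix`: list with `dosages` (samples x SNPs),
#'   `snp_annotation`, `sample_ids`.
#' @export
simulate_genotypes <- function(config, n = config$n_discovery,
                               seed = config$seed, .arch = NULL) {
  if (is.null(.arch)) .arch <- sim_architecture(config)
  set.seed(seed)
  if (2 * n * config$maf_range[1] < 5) {
    stop("simulate_genotypes: n too small to realize the MAF floor ",
         config$maf_range[1], " (expected minor-allele count < 5)")
  }
  ps <- config$n_snps_per_gene; ng <- config$n_genes
  rho <- config$ld_rho
  draw_block <- function(maf_block) {
    # two haplotypes per subject, latent AR(1) within the block
    hap <- function() {
      z <- matrix(stats::rnorm(n * ps), n, ps)
      if (ps > 1 && rho > 0) {
        for (j in 2:ps) z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
      }
      sweep(z, 2, stats::qnorm(maf_block), "<") + 0
    }
    hap() + hap()
  }
  dos <- matrix(0L, n, ng * ps)
  for (g in seq_len(ng)) {
    cols <- (g - 1) * ps + seq_len(ps)
    maf_block <- .arch$snp_annotation$maf[cols]
    block <- draw_block(maf_block)
    for (try in seq_len(20)) {
      f <- colMeans(block) / 2
      if (all(pmin(f, 1 - f) >= 0.04)) break
      block <- draw_block(maf_block)
    }
    f <- colMeans(block) / 2
    if (any(pmin(f, 1 - f) < 0.04)) {
      stop("simulate_genotypes: could not realize MAF >= 0.04 at n = ", n)
    }
    dos[, cols] <- block
  }
  colnames(dos) <- .arch$snp_annotation$snp
  rownames(dos) <- sprintf("s%04d", seq_len(n))
  genotype_matrix(dos, .arch$snp_annotation)
}

#' Simulate log2 expression with planted cis-eQTLs and a cell-composition
#' confounder
#'
#' For each eGene, log2 expression is the planted cis genetic component
#' (scaled so its variance is `eqtl_h2`), plus `confounder_strength` times a
#' standardized cell-abundance score, plus Gaussian noise bringing the total
#' variance to 1. Non-eGenes carry no genetic component. A raw-count matrix
#' with per-sample library-size factors is emitted alongside, for exercising
#' upper-quartile normalization.
#'
#' @inheritParams simulate_genotypes
#' @param genotypes `genotype_matrix` from [simulate_genotypes()].
#' @return list with `expression` (log2-scale `expression_matrix`), `raw`
#'   (raw-scale `expression_matrix`), `abundance` (samples x cell types),
#'   `confounder` (standardized score used), `lib_factors`.
#' @export
simulate_expression <- function(genotypes, config, seed = config$seed + 1L,
                                .arch = NULL) {
  if (is.null(.arch)) .arch <- sim_architecture(config)
  if (config$eqtl_h2 >= 1) stop("simulate_expression: eqtl_h2 must be < 1")
  set.seed(seed)
  dos <- genotypes$dosages
  n <- nrow(dos); ng <- config$n_genes; ps <- config$n_snps_per_gene
  genes <- gene_ids(config)

  # cell-type abundances: K fractions, first column is the confounder
  K <- config$n_cell_types
  ab <- matrix(stats::rgamma(n * K, shape = 2, rate = 1), n, K)
  # fractions of a variable immune total, so columns are not constrained to
  # sum to 1 (as for an enriched subset of deconvolution scores)
  ab <- ab / rowSums(ab) * stats::runif(n, 0.6, 1)
  colnames(ab) <- paste0("cell", seq_len(K))
  rownames(ab) <- rownames(dos)
  u <- as.numeric(scale(ab[, 1]))

  cs <- config$confounder_strength
  noise_var <- 1 - config$eqtl_h2 - cs^2
  if (noise_var <= 0) {
    stop("simulate_expression: eqtl_h2 + confounder_strength^2 must be < 1")
  }
  expr <- matrix(0, ng, n, dimnames = list(genes, rownames(dos)))
  mu <- stats::runif(ng, 3, 8)  # baseline log2 abundance per gene
  for (g in seq_len(ng)) {
    gen <- 0
    if (config$eqtl_h2 > 0 && any(.arch$eqtl_beta[, g] != 0)) {
      cols <- (g - 1) * ps + seq_len(ps)
      comp <- drop(dos[, cols] %*% .arch$eqtl_beta[, g])
      v <- stats::var(comp)
      if (v > 0) gen <- (comp - mean(comp)) * sqrt(config$eqtl_h2 / v)
    }
    expr[g, ] <- mu[g] + gen + cs * u + stats::rnorm(n, 0, sqrt(noise_var))
  }
  lib <- exp(stats::rnorm(n, 0, 0.3))
  raw <- sweep(pmax(2^expr - 1, 0), 2, lib, "*")
  ann <- .arch$gene_annotation
  list(
    expression = expression_matrix(expr, ann, scale = "log2"),
    raw = expression_matrix(raw, ann, scale = "raw"),
    abundance = ab, confounder = u, lib_factors = lib
  )
}

# censoring horizon such that the mean censoring probability under
# C ~ U(0, cmax) matches the target
calibrate_censoring <- function(hazard, target) {
  p_cens <- function(cmax) {
    p <- ifelse(hazard > 0, (1 - exp(-hazard * cmax)) / (hazard * cmax), 1)
    mean(p) - target
  }
  stats::uniroot(p_cens, lower = 1e-4, upper = 1e6, tol = 1e-8)$root
}

#' Simulate clinical covariates, CMS labels and additive-hazard survival
#'
#' Event times are drawn from an additive hazard that is constant in time
#' given covariates: baseline + covariate effects (age, gender, BRAF, RAS) +
#' confounder loading + the planted treatment-specific gene slopes on
#' centered log2 expression (+ any planted direct SNP effects). Hazards are
#' floored at 0 (count reported); censoring is independent uniform with the
#' horizon calibrated so the expected censored fraction matches
#' `censoring_rate`. Treatment arms are assigned 1:1; CMS labels follow a
#' multinomial logit tilted by the two designated genes' expression.
#'
#' @inheritParams simulate_genotypes
#' @param expression log2-scale `expression_matrix` (observed for discovery;
#'   latent for validation).
#' @param abundance samples x cell-types matrix from [simulate_expression()].
#' @param genotypes `genotype_matrix`, needed only when direct (pleiotropic)
#'   SNP effects are planted.
#' @return `clinical_table` data frame (os_time in months, event, arm, age,
#'   gender, braf_v600e, all_ras, batch, cms) with attributes
#'   `floored_hazards` (count) and `cens_horizon`.
#' @export
simulate_clinical_survival <- function(expression, abundance, config,
                                       genotypes = NULL,
                                       seed = config$seed + 2L, .arch = NULL) {
  if (is.null(.arch)) .arch <- sim_architecture(config)
  set.seed(seed)
  expr <- expression$values
  n <- ncol(expr)
  ids <- colnames(expr)
  age <- stats::rnorm(n, 60, 10)
  gender <- stats::rbinom(n, 1, 0.5)
  braf <- stats::rbinom(n, 1, 0.08)
  ras <- stats::rbinom(n, 1, 0.25)
  batch <- sample(rep(c("b1", "b2"), length.out = n))
  arm <- sample(rep(c("bevacizumab", "cetuximab"), length.out = n))

  ce <- config$covariate_effects
  h <- config$baseline_hazard +
    ce["age"] * (age - 60) / 10 + ce["gender"] * gender +
    ce["braf"] * braf + ce["ras"] * ras
  u <- as.numeric(scale(abundance[, 1]))
  h <- h + config$confounder_strength * 0.01 * u
  cg <- config$causal_genes
  if (nrow(cg)) {
    for (i in seq_len(nrow(cg))) {
      g <- expr[cg$gene[i], ] - mean(expr[cg$gene[i], ])
      h <- h + ifelse(arm == cg$arm[i], cg$slope[i] * g, 0)
    }
  }
  psnp <- config$pleiotropic_snps
  if (nrow(psnp)) {
    if (is.null(genotypes)) {
      stop("simulate_clinical_survival: pleiotropic SNP effects require genotypes")
    }
    for (i in seq_len(nrow(psnp))) {
      d <- genotypes$dosages[, psnp$snp[i]]
      h <- h + psnp$effect[i] * (d - mean(d))
    }
  }
  n_neg <- sum(h < 0)
  if (n_neg > 0.05 * n) {
    stop("simulate_clinical_survival: hazard negative before flooring for ",
         n_neg, "/", n, " subjects (> 5%); rescale effect sizes")
  }
  h <- pmax(h, 0)
  t_event <- ifelse(h > 0, stats::rexp(n) / h, Inf)
  if (config$censoring_rate > 0) {
    cmax <- calibrate_censoring(h, config$censoring_rate)
    cens <- stats::runif(n, 0, cmax)
  } else {
    cmax <- Inf
    cens <- rep(Inf, n)
  }
  os_time <- pmin(t_event, cens)
  event <- as.integer(t_event <= cens)
  # guard against zero/infinite follow-up
  os_time[!is.finite(os_time)] <- max(os_time[is.finite(os_time)], 1)
  os_time <- pmax(os_time, 1e-6)

  gA <- if (length(config$cms_genes) >= 1) {
    as.numeric(scale(expr[config$cms_genes[1], ]))
  } else rep(0, n)
  gB <- if (length(config$cms_genes) > 1) {
    as.numeric(scale(expr[config$cms_genes[2], ]))
  } else rep(0, n)
  eta <- config$cms_strength * (outer(gA, .arch$cms_w[1, ]) + outer(gB, .arch$cms_w[2, ]))
  pr <- exp(eta - apply(eta, 1, max))
  pr <- pr / rowSums(pr)
  cms <- apply(pr, 1, function(p) sample(colnames(.arch$cms_w), 1, prob = p))

  out <- data.frame(
    sample_id = ids, os_time = os_time, event = event, arm = arm,
    age = age, gender = gender, braf_v600e = braf, all_ras = ras,
    batch = batch, cms = cms, stringsAsFactors = FALSE
  )
  attr(out, "floored_hazards") <- n_neg
  attr(out, "cens_horizon") <- cmax
  class(out) <- c("clinical_table", "data.frame")
  out
}

#' Simulate a paired tumor/normal log2 expression design
#'
#' Each pair has a shared random intercept; planted log2 fold-changes are
#' added to the tumor column. Genes without a planted entry have fold-change
#' zero.
#'
#' @inheritParams simulate_genotypes
#' @return list with `tumor` and `normal` (genes x pairs log2 matrices,
#'   aligned columns), `pair_ids`, `truth` (planted log2 fold-changes).
#' @export
simulate_paired_de <- function(config, seed = config$seed + 3L) {
  set.seed(seed)
  np <- config$n_pairs
  pg <- config$paired_genes
  if (is.null(pg)) pg <- data.frame(gene = character(), log2fc = numeric())
  genes <- unique(c(gene_ids(config)[seq_len(min(10, config$n_genes))], pg$gene))
  fc <- stats::setNames(rep(0, length(genes)), genes)
  fc[pg$gene] <- pg$log2fc
  mu <- stats::runif(length(genes), 3, 8)
  pair_int <- stats::rnorm(np, 0, 1)
  base <- outer(mu, pair_int, "+")
  normal <- base + matrix(stats::rnorm(length(genes) * np, 0, config$paired_sd),
                          length(genes), np)
  tumor <- base + fc + matrix(stats::rnorm(length(genes) * np, 0, config$paired_sd),
                              length(genes), np)
  ids <- sprintf("pair%02d", seq_len(np))
  dimnames(normal) <- dimnames(tumor) <- list(genes, ids)
  list(tumor = tumor, normal = normal, pair_ids = ids, truth = fc)
}

#' Generate matched discovery and validation cohorts
#'
#' Draws one genetic architecture (MAFs, planted eQTL weights, CMS tilt)
#' shared by both cohorts, then simulates genotypes, expression, abundances
#' and survival. The validation cohort's survival is generated from its
#' latent (never returned) expression, mirroring a cohort with genotypes and
#' outcomes but no RNA-seq.
#'
#' @param config a [sim_config()].
#' @return list with elements `discovery` and `validation` (each a `cohort`:
#'   `genotypes`, `expression` (NULL for validation), `abundance`,
#'   `clinical`) and `truth` (architecture, planted causal genes and
#'   pleiotropic SNPs).
#' @export
make_cohort <- function(config) {
  arch <- sim_architecture(config)
  build <- function(n, seed0, keep_expression) {
    if (n == 0) {
      return(list(genotypes = NULL, expression = NULL, abundance = NULL,
                  clinical = NULL, n = 0L))
    }
    geno <- simulate_genotypes(config, n = n, seed = seed0, .arch = arch)
    ex <- simulate_expression(geno, config, seed = seed0 + 1L, .arch = arch)
    clin <- simulate_clinical_survival(ex$expression, ex$abundance, config,
                                       genotypes = geno, seed = seed0 + 2L,
                                       .arch = arch)
    list(genotypes = geno,
         expression = if (keep_expression) ex$expression else NULL,
         raw_expression = if (keep_expression) ex$raw else NULL,
         abundance = ex$abundance, clinical = clin, n = as.integer(n))
  }
  disc <- build(config$n_discovery, config$seed + 10L, TRUE)
  vali <- build(config$n_validation, config$seed + 20L, FALSE)
  disc$tag <- "discovery"; vali$tag <- "validation"
  class(disc) <- class(vali) <- "cohort"
  truth <- list(architecture = arch,
                egenes = gene_ids(config)[seq_len(config$n_egenes)],
                causal_genes = config$causal_genes,
                pleiotropic_snps = config$pleiotropic_snps,
                confounder_strength = config$confounder_strength)
  list(discovery = disc, validation = vali, truth = truth)
}
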