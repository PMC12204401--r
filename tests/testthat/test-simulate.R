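test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_egenes = 100, n_genes = 50))
  expect_error(sim_config(maf_range = c(0.01, 0.5)))
  expect_error(sim_config(eqtl_h2 = 1), "eqtl_h2")
  expect_error(sim_config(censoring_rate = 1))
  expect_error(sim_config(causal_genes = data.frame(
    gene = "gene050", arm = "bevacizumab", slope = 0.01), n_egenes = 10),
    "eGenes")
})

test_that("genotype blocks honor MAF and LD settings", {
  n <- 2000
  cfg0 <- sim_config(n_discovery = n, n_genes = 8, n_egenes = 2, ld_rho = 0, seed = 2)
  g0 <- simulate_genotypes(cfg0, n = n)
  expect_true(all(g0$dosages %in% 0:2))
  # independence case: mean |r| within blocks ~ 0
  ps <- cfg0$n_snps_per_gene
  rs <- unlist(lapply(seq_len(8), function(b) {
    r <- stats::cor(g0$dosages[, (b - 1) * ps + seq_len(ps)])
    abs(r[upper.tri(r)])
  }))
  expect_lt(mean(rs), 3 / sqrt(n))

  cfg9 <- sim_config(n_discovery = n, n_genes = 8, n_egenes = 2, ld_rho = 0.9, seed = 3)
  g9 <- simulate_genotypes(cfg9, n = n)
  adj <- unlist(lapply(seq_len(8), function(b) {
    d <- g9$dosages[, (b - 1) * ps + seq_len(ps)]
    vapply(seq_len(ps - 1), function(j) stats::cor(d[, j], d[, j + 1])^2,
           numeric(1))
  }))
  # latent copula correlation 0.9 -> adjacent-pair r2 = 0.81 > 0.5 before
  # thresholding; after thresholding at the MAF quantiles the expected dosage
  # r2 comes from the bivariate-normal orthant oracle below
  expect_gt(cfg9$ld_rho^2, 0.5)
  oracle_r2 <- local({
    set.seed(99)
    m <- 2e5
    z1 <- stats::rnorm(m)
    z2 <- 0.9 * z1 + sqrt(1 - 0.81) * stats::rnorm(m)
    mean(vapply(seq_len(8 * (ps - 1)), function(k) {
      maf <- stats::runif(2, 0.1, 0.5)
      stats::cor(z1 < stats::qnorm(maf[1]), z2 < stats::qnorm(maf[2]))^2
    }, numeric(1)))
  })
  expect_lt(abs(mean(adj) - oracle_r2), 0.07)
  expect_gt(mean(adj), 0.3)

  cfg5 <- sim_config(n_discovery = n, n_genes = 5, n_egenes = 2, maf_range = c(0.5, 0.5),
                     seed = 4)
  g5 <- simulate_genotypes(cfg5, n = n)
  expect_true(all(colMeans(g5$dosages) > 0.9 & colMeans(g5$dosages) < 1.1))

  expect_true(all(g9$snp_annotation$maf >= 0.04))
  expect_error(simulate_genotypes(sim_config(n_genes = 4, n_egenes = 2, maf_range = c(0.05, 0.1)), n = 20),
               "MAF floor")
})

test_that("expression carries the planted cis heritability and confounding", {
  cfg <- sim_config(n_discovery = 1000, n_genes = 15, n_egenes = 10,
                    eqtl_h2 = 0.3, seed = 5)
  geno <- simulate_genotypes(cfg)
  ex <- simulate_expression(geno, cfg)
  arch <- mrhaz:::sim_architecture(cfg)
  ps <- cfg$n_snps_per_gene
  r2 <- vapply(seq_len(10), function(g) {
    cols <- (g - 1) * ps + seq_len(ps)
    planted <- cols[arch$eqtl_beta[, g] != 0]
    summary(stats::lm(ex$expression$values[g, ] ~
                        geno$dosages[, planted, drop = FALSE]))$r.squared
  }, numeric(1))
  expect_true(all(r2 > 0.2 & r2 < 0.4))
  # non-eGenes have no genetic component
  r2_null <- summary(stats::lm(ex$expression$values[12, ] ~
                                 geno$dosages[, 56:60]))$r.squared
  expect_lt(r2_null, 0.03)
  # confounder off -> expression uncorrelated with the abundance score
  cfg0 <- sim_config(n_discovery = 1000, n_genes = 6, n_egenes = 0,
                     confounder_strength = 0, seed = 6)
  g2 <- simulate_genotypes(cfg0)
  e2 <- simulate_expression(g2, cfg0)
  cors <- abs(apply(e2$expression$values, 1, stats::cor, y = e2$abundance[, 1]))
  expect_lt(mean(cors), 3 / sqrt(1000))
  expect_error(simulate_expression(geno, sim_config(eqtl_h2 = 0.9,
                                                    confounder_strength = 0.5)),
               "must be < 1")
})

test_that("null eQTL architecture gives slope estimates centered at zero", {
  cfg <- sim_config(n_discovery = 800, n_genes = 12, n_egenes = 0, seed = 8)
  geno <- simulate_genotypes(cfg)
  ex <- simulate_expression(geno, cfg)
  sl <- vapply(seq_len(12), function(g) {
    stats::coef(stats::lm(ex$expression$values[g, ] ~
                            geno$dosages[, (g - 1) * 5 + 1]))[2]
  }, numeric(1))
  expect_lt(abs(mean(sl)), 0.05)
})

test_that("marginal regression recovers the lead-SNP sign for nearly all eGenes", {
  cfg <- sim_config(n_discovery = 500, n_genes = 30, n_egenes = 30,
                    eqtl_h2 = 0.3, seed = 9)
  geno <- simulate_genotypes(cfg)
  ex <- simulate_expression(geno, cfg)
  arch <- mrhaz:::sim_architecture(cfg)
  hit <- vapply(seq_len(30), function(g) {
    lead <- (g - 1) * 5 + which(arch$eqtl_beta[, g] != 0)
    b <- stats::coef(stats::lm(ex$expression$values[g, ] ~ geno$dosages[, lead]))[2]
    sign(b) == sign(arch$eqtl_beta[arch$eqtl_beta[, g] != 0, g])
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("survival generation calibrates censoring and respects null effects", {
  cfg <- sim_config(n_discovery = 2000, n_genes = 6, n_egenes = 2,
                    censoring_rate = 0.3, baseline_hazard = 0.1,
                    covariate_effects = c(age = 0, gender = 0, braf = 0, ras = 0),
                    confounder_strength = 0, seed = 10)
  geno <- simulate_genotypes(cfg)
  ex <- simulate_expression(geno, cfg)
  clin <- simulate_clinical_survival(ex$expression, ex$abundance, cfg)
  expect_lt(abs(mean(1 - clin$event) - 0.3), 0.05)

  # censoring off -> every subject has an event
  cfg0 <- sim_config(n_discovery = 500, n_genes = 4, n_egenes = 1,
                     censoring_rate = 0, seed = 11)
  g0 <- simulate_genotypes(cfg0)
  e0 <- simulate_expression(g0, cfg0)
  c0 <- simulate_clinical_survival(e0$expression, e0$abundance, cfg0)
  expect_true(all(c0$event == 1))

  # all effects zero, h0 = 0.1/month -> exponential, KM median ~ log(2)/0.1
  km <- kaplan_meier(clin$os_time, clin$event)
  expect_gt(km$median["all"], 6.0)
  expect_lt(km$median["all"], 7.9)
})

test_that("a treatment-specific slope is recovered in its arm and absent in the other", {
  cfg <- sim_config(n_discovery = 1000, n_genes = 6, n_egenes = 2,
                    causal_genes = data.frame(gene = "gene001",
                                              arm = "bevacizumab",
                                              slope = 0.012),
                    seed = 12)
  co <- make_cohort(cfg)
  d <- co$discovery
  g <- d$expression$values["gene001", ] - mean(d$expression$values["gene001", ])
  for (a in c("bevacizumab", "cetuximab")) {
    sel <- d$clinical$arm == a
    f <- fit_additive_hazard(d$clinical$os_time[sel], d$clinical$event[sel],
                             cbind(intercept = 1, g = g[sel]))
    slope_hat <- f$cumcoef[f$k_eval, "g"] / f$tau
    if (a == "bevacizumab") {
      expect_gt(slope_hat, 0.004)
      expect_lt(f$p["g"], 0.05)
    } else {
      expect_lt(abs(slope_hat), 0.006)
    }
  }
})

test_that("over-strong effects trip the hazard-positivity guard", {
  cfg <- sim_config(n_discovery = 500, n_genes = 4, n_egenes = 2,
                    causal_genes = data.frame(gene = c("gene001", "gene002"),
                                              arm = "bevacizumab",
                                              slope = 0.05),
                    seed = 13)
  geno <- simulate_genotypes(cfg)
  ex <- simulate_expression(geno, cfg)
  expect_error(simulate_clinical_survival(ex$expression, ex$abundance, cfg),
               "rescale")
})

test_that("make_cohort is deterministic and shapes follow the configuration", {
  cfg <- sim_config(n_discovery = 273, n_validation = 602, n_genes = 8,
                    n_egenes = 3, seed = 14)
  a <- make_cohort(cfg)
  b <- make_cohort(cfg)
  expect_identical(a$discovery$genotypes$dosages, b$discovery$genotypes$dosages)
  expect_identical(a$discovery$expression$values, b$discovery$expression$values)
  expect_identical(a$discovery$clinical$os_time, b$discovery$clinical$os_time)
  expect_identical(a$validation$clinical$os_time, b$validation$clinical$os_time)

  expect_equal(nrow(a$discovery$genotypes$dosages), 273)
  expect_equal(ncol(a$discovery$expression$values), 273)
  expect_equal(nrow(a$validation$genotypes$dosages), 602)
  expect_null(a$validation$expression)

  z <- make_cohort(sim_config(n_discovery = 120, n_validation = 0,
                              n_genes = 6, n_egenes = 2, seed = 15))
  expect_equal(z$validation$n, 0L)
  expect_equal(z$discovery$n, 120L)
})

test_that("paired tumor/normal generator plants recoverable fold-changes", {
  cfg <- sim_config(n_genes = 12, n_egenes = 4, n_pairs = 24, paired_sd = 1,
                    paired_genes = data.frame(gene = "gene001",
                                              log2fc = log2(4.56)),
                    seed = 16)
  hits <- vapply(1:20, function(i) {
    p <- simulate_paired_de(cfg, seed = 100 + i)
    fc <- paired_de(p, "gene001")$fold_change
    fc >= 3.2 && fc <= 6.4
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # null genes: p-values roughly uniform over replicates
  ps <- vapply(1:40, function(i) {
    p <- simulate_paired_de(cfg, seed = 300 + i)
    paired_de(p, "gene002")$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)

  # one pair: the generator works, estimation refuses (no df for a t-test)
  p1 <- simulate_paired_de(sim_config(n_genes = 6, n_egenes = 2, n_pairs = 1,
                                      seed = 17))
  expect_equal(ncol(p1$tumor), 1)
  expect_error(paired_de(p1, "gene001"), "2 pairs")
})
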