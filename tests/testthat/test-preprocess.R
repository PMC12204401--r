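test_that("gene filter applies the SD and zero-fraction rules with exact boundaries", {
  # 10 samples; g_zero31 would need fractional zeros, so use 100 samples for
  # the 31%/30% boundary
  m <- matrix(5, 5, 100)
  m[1, ] <- rep(c(0, 5), c(30, 70))          # exactly 30% zeros, SD ~ 2.3: kept
  m[2, ] <- rep(c(0, 5), c(31, 69))          # 31% zeros: removed
  m[3, ] <- 7                                 # constant, SD 0: removed
  m[4, ] <- rep(c(4, 5), 50)                  # SD ~ 0.502: kept
  m[5, ] <- rep(c(4.6, 5.4), 50)              # SD ~ 0.402: removed
  rownames(m) <- paste0("g", 1:5)
  sds <- apply(m, 1, sd)
  expect_true(sds[4] >= 0.5 && sds[5] < 0.5)  # fixture sanity
  out <- filter_genes(em(m, scale = "raw"))
  expect_identical(rownames(out$values), c("g1", "g4"))

  # idempotence
  expect_identical(filter_genes(out)$values, out$values)
  expect_error(filter_genes(em(matrix(1, 2, 10), scale = "raw")), "no genes")
  expect_error(filter_genes(em(matrix(1:10, 2, 5))), "raw-scale")
})

test_that("upper-quartile normalization matches hand computation and is scale-invariant", {
  # 3 genes x 2 samples; nonzero upper quartiles by hand:
  # s1 values {2,4,8} -> uq 6; s2 {1,2,4} -> uq 3; global mean uq 4.5
  m <- matrix(c(2, 4, 8, 1, 2, 4), 3, 2)
  rownames(m) <- paste0("g", 1:3); colnames(m) <- c("s1", "s2")
  out <- normalize_expression(em(m, scale = "raw"))
  expect_equal(out$scale, "log2")
  expect_equal(out$values[, "s1"], log2(c(2, 4, 8) / 6 * 4.5 + 1),
               ignore_attr = TRUE)
  expect_equal(out$values[, "s2"], log2(c(1, 2, 4) / 3 * 4.5 + 1),
               ignore_attr = TRUE)

  # scalar-multiple samples normalize to identical columns
  m2 <- cbind(s1 = c(1, 3, 9, 2), s2 = 7 * c(1, 3, 9, 2))
  rownames(m2) <- paste0("g", 1:4)
  out2 <- normalize_expression(em(m2, scale = "raw"))
  expect_equal(out2$values[, "s1"], out2$values[, "s2"])

  # all-equal matrix -> constant log2(1 + c)
  m3 <- matrix(5, 3, 4, dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  out3 <- normalize_expression(em(m3, scale = "raw"))
  expect_true(all(out3$values == log2(6)))

  # per-sample upper quartiles equalized before log2
  set.seed(1)
  m4 <- matrix(rpois(200, 20) * rep(c(1, 5, 2, 9), each = 50), 10, 20,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:20)))
  out4 <- normalize_expression(em(m4, scale = "raw"))
  lin <- 2^out4$values - 1
  uqs <- apply(lin, 2, function(x) quantile(x[x > 0], 0.75))
  expect_lt(diff(range(uqs)) / mean(uqs), 1e-9)

  # all-zero sample errors; >50%-zero sample dropped
  m5 <- cbind(s1 = c(1, 2, 3, 4), s2 = c(0, 0, 0, 0))
  rownames(m5) <- paste0("g", 1:4)
  expect_error(normalize_expression(em(m5, scale = "raw")), "all-zero")
  m6 <- cbind(s1 = c(1, 2, 3, 4), s2 = c(0, 0, 0, 4), s3 = c(2, 3, 4, 5))
  rownames(m6) <- paste0("g", 1:4)
  expect_message(out6 <- normalize_expression(em(m6, scale = "raw")), "50%")
  expect_identical(colnames(out6$values), c("s1", "s3"))
})

test_that("genotype QC drops SNPs by MAF, HWE and call rate, then samples", {
  n <- 50
  d <- matrix(0, n, 5, dimnames = list(paste0("s", 1:n), paste0("snp", 1:5)))
  d[1:4, 1] <- 1            # 4 minor alleles / 100 -> MAF 0.04: dropped
  d[1:5, 2] <- 1            # MAF 0.05 exactly: kept
  d[, 3] <- 0               # monomorphic: dropped
  d[1:25, 4] <- 2           # (25,0,25): extreme HWE departure: dropped
  d[1:20, 5] <- 1; d[21:30, 5] <- 2   # common, HWE-ish: kept
  out <- qc_genotypes(gm(d))
  expect_identical(colnames(out$dosages), c("snp2", "snp5"))
  log <- attr(out, "qc_log")
  expect_setequal(log$rule[log$id %in% c("snp1", "snp3")], "maf")
  expect_true("hwe" %in% log$rule[log$id == "snp4"])

  # HWE exact p for (25,0,25) against an independent choose()-based oracle
  hwe_oracle <- function(n_aa, n_ab, n_bb) {
    n <- n_aa + n_ab + n_bb; na <- 2 * n_aa + n_ab
    nm <- min(na, 2 * n - na)
    hets <- seq(nm %% 2, nm, by = 2)
    pr <- vapply(hets, function(h) {
      hm <- (nm - h) / 2; hM <- n - h - hm
      exp(lfactorial(n) - lfactorial(h) - lfactorial(hm) - lfactorial(hM) +
            h * log(2) + lfactorial(nm) + lfactorial(2 * n - nm) -
            lfactorial(2 * n))
    }, numeric(1))
    sum(pr[pr <= pr[hets == n_ab] * (1 + 1e-12)])
  }
  expect_lt(hwe_oracle(25, 0, 25), 1e-8)
  expect_equal(mrhaz:::hwe_exact_p(5, 4, 3), hwe_oracle(5, 4, 3),
               tolerance = 1e-12)
  expect_equal(mrhaz:::hwe_exact_p(30, 15, 5), hwe_oracle(30, 15, 5),
               tolerance = 1e-12)

  # sample call-rate filter and mean imputation
  d2 <- matrix(rbinom(200, 2, 0.3), 20, 10,
               dimnames = list(paste0("s", 1:20), paste0("m", 1:10)))
  d2[1, 1:3] <- NA          # sample 1 call rate 0.7 < 0.9: dropped
  d2[5, 1] <- NA            # isolated missing: imputed
  out2 <- qc_genotypes(gm(d2), snp_call_min = 0.5)
  expect_false("s1" %in% rownames(out2$dosages))
  expect_false(anyNA(out2$dosages))

  # idempotence on clean data
  out3 <- qc_genotypes(out)
  expect_identical(out3$dosages, out$dosages)
})

test_that("cell-type filter uses <= 30% zeros and strictly > 0.12 SD", {
  n <- 100
  ab <- cbind(
    keep = runif(n, 0.1, 0.9),                    # SD ~ 0.23, no zeros
    sd_at_threshold = rep(c(0.26, 0.5), n / 2),   # SD 0.1206... careful below
    allzero = rep(0, n),
    zeros31 = c(rep(0, 31), runif(n - 31, 0.5, 1))
  )
  # construct a column whose SD is exactly 0.12: values a, b half-half
  # SD = |a - b| / 2 * sqrt(n/(n-1)) -> pick diff so sample SD == 0.12
  dlt <- 0.12 * 2 / sqrt(n / (n - 1))
  ab[, 2] <- rep(c(0.5, 0.5 + dlt), n / 2)
  expect_equal(sd(ab[, 2]), 0.12)
  out <- filter_cell_types(ab)
  expect_identical(colnames(out), c("keep", "zeros31")[c(TRUE, mean(ab[, 4] == 0) <= 0.3)])
  # 31% zeros column: zero fraction 0.31 > 0.30 -> dropped
  expect_identical(colnames(out), "keep")
  # idempotence
  expect_identical(filter_cell_types(out), out)
})

test_that("genetic sex is inferred from chrY expression and mismatches reported", {
  set.seed(2)
  n <- 60
  male <- rep(c(1, 0), c(25, 35))
  y <- rbind(y1 = male * 6 + rnorm(n, 0, 0.3),
             y2 = male * 5 + rnorm(n, 0, 0.3),
             a1 = rnorm(n, 5))
  ex <- em(y, scale = "log2", chrom = "Y")
  rec <- male
  flip <- c(3, 9, 30, 41, 55)
  rec[flip] <- 1 - rec[flip]
  r <- infer_genetic_sex(ex, c("y1", "y2"), recorded_gender = rec)
  expect_false(r$degenerate)
  expect_setequal(r$mismatches, paste0("s", flip))
  expect_identical(unname(r$label[1:25]), rep("male", 25))

  # degenerate: all samples identical
  flat <- em(matrix(3, 2, 10, dimnames = list(c("y1", "y2"), paste0("s", 1:10))),
             scale = "log2", chrom = "Y")
  rd <- infer_genetic_sex(flat, c("y1", "y2"))
  expect_true(rd$degenerate)
  expect_length(rd$mismatches, 0)

  expect_error(infer_genetic_sex(ex, "y1"), "2 chrY genes")
})

test_that("expression PCA finds planted structure with a fixed sign convention", {
  set.seed(3)
  # rank-1 matrix: PC1 explains ~ all variance
  u <- rnorm(30); v <- rnorm(50)
  m1 <- outer(u, v) + matrix(rnorm(1500, 0, 1e-3), 30, 50)
  rownames(m1) <- paste0("g", 1:30); colnames(m1) <- paste0("s", 1:50)
  s1 <- pca_expression(em(m1), 2)
  expect_gt(attr(s1, "var_explained")[1], 0.99)

  # two batches with a mean shift separate on PC1
  batch <- rep(0:1, each = 30)
  m2 <- matrix(rnorm(40 * 60), 40, 60) + 3 * matrix(batch, 40, 60, byrow = TRUE)
  rownames(m2) <- paste0("g", 1:40); colnames(m2) <- paste0("s", 1:60)
  s2 <- pca_expression(em(m2), 1)
  expect_gt(abs(cor(s2[, 1], batch)), 0.9)

  # k = 0 empty scores; k too large errors
  s0 <- pca_expression(em(m2), 0)
  expect_equal(dim(s0), c(60, 0))
  expect_error(pca_expression(em(m2), 100), "k exceeds")

  # sign convention: largest-magnitude loading positive, reproducible
  s2b <- pca_expression(em(m2), 1)
  expect_identical(s2, s2b)
})
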