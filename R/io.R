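#' Write / read an expression matrix as TSV
#'
#' Dialect: first column `gene_id`, header row of sample ids, tab-separated,
#' no quoting.
#'
#' @param expr `expression_matrix`.
#' @param path output file.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr$values), expr$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @param gene_annotation annotation data frame (or path to a BED-like file
#'   readable by [read_gene_annotation()]) for the loaded matrix.
#' @param scale scale flag of the stored values.
#' @export
read_expression_tsv <- function(path, gene_annotation, scale = "log2") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (is.character(gene_annotation)) {
    gene_annotation <- read_gene_annotation(gene_annotation)
  }
  expression_matrix(m, gene_annotation, scale = scale)
}

#' Write / read gene annotation as BED-like TSV
#'
#' Four columns: chrom, tss, tss, gene_id (1-based inclusive), no header.
#' @param ann data frame with columns `gene`, `chrom`, `tss`.
#' @param path file path.
#' @export
write_gene_annotation <- function(ann, path) {
  utils::write.table(data.frame(ann$chrom, ann$tss, ann$tss, ann$gene),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_annotation
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(gene = df[[4]], chrom = as.character(df[[1]]), tss = df[[2]],
             stringsAsFactors = FALSE)
}

#' Write / read genotype dosages as TSV
#'
#' Layout: first column `sample_id`, one column per SNP. SNP annotation is
#' written to a sidecar `<path>.snps.tsv`.
#'
#' @param geno `genotype_matrix`.
#' @param path file path.
#' @export
write_dosage_tsv <- function(geno, path) {
  df <- data.frame(sample_id = rownames(geno$dosages), geno$dosages,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(geno$snp_annotation, paste0(path, ".snps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @param snp_annotation optional data frame; defaults to the sidecar file.
#' @export
read_dosage_tsv <- function(path, snp_annotation = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (is.null(snp_annotation)) {
    snp_annotation <- utils::read.delim(paste0(path, ".snps.tsv"),
                                        stringsAsFactors = FALSE)
    snp_annotation$chrom <- as.character(snp_annotation$chrom)
  }
  genotype_matrix(m, snp_annotation)
}

#' Write genotypes as a minimal VCF (GT field only)
#'
#' Hard-call dosages only (0/1/2, NA allowed); one ALT allele per site.
#'
#' @param geno `genotype_matrix` with integer dosages.
#' @param path output .vcf path (uncompressed).
#' @export
write_vcf <- function(geno, path) {
  ann <- geno$snp_annotation
  d <- t(geno$dosages)  # SNPs x samples
  gt <- matrix(c("0/0", "0/1", "1/1")[d + 1], nrow(d), ncol(d))
  gt[is.na(d)] <- "./."
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(geno$dosages)),
                     collapse = "\t")), con)
  body <- cbind(ann$chrom, ann$pos, ann$snp, ann$ref, ann$alt, ".", "PASS",
                ".", "GT", gt)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read genotypes from a VCF (GT parsed to dosage)
#'
#' Uses vcfR; counts ALT alleles per genotype, `./.` becomes NA.
#'
#' @param path .vcf or .vcf.gz file.
#' @return `genotype_matrix`.
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(g) {
    if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_integer_)
    sum(strsplit(g, "[/|]")[[1]] == "1")
  }
  d <- apply(gt, c(1, 2), count_alt)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ann <- data.frame(snp = fix$ID, chrom = as.character(fix$CHROM),
                    pos = as.numeric(fix$POS), ref = fix$REF, alt = fix$ALT,
                    stringsAsFactors = FALSE)
  genotype_matrix(t(d), ann)
}

#' Write a clinical table / abundance matrix as TSV
#' @param clinical data frame; `abund` samples x cell-types matrix.
#' @param path file path.
#' @export
write_clinical_tsv <- function(clinical, path) {
  utils::write.table(as.data.frame(clinical), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clinical_tsv
#' @export
read_clinical_tsv <- function(path) {
  clinical_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname write_clinical_tsv
#' @param abund samples x cell-types matrix.
#' @export
write_abundance_tsv <- function(abund, path) {
  df <- data.frame(sample_id = rownames(abund), abund, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clinical_tsv
#' @export
read_abundance_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Assemble a cohort from files, intersecting sample ids
#'
#' Reads expression (optional), genotypes (VCF or dosage TSV), clinical and
#' abundance tables, cross-checks sample identifiers and keeps the
#' intersection; dropped counts are reported via message.
#'
#' @param genotype_path VCF (`.vcf`) or dosage TSV.
#' @param clinical_path clinical TSV.
#' @param abundance_path abundance TSV.
#' @param expression_path expression TSV or NULL (validation-style cohort).
#' @param gene_annotation_path BED-like annotation (needed with expression).
#' @param expression_scale scale flag of the stored expression.
#' @return `cohort` list (genotypes, expression, abundance, clinical, n).
#' @export
load_cohort <- function(genotype_path, clinical_path, abundance_path,
                        expression_path = NULL, gene_annotation_path = NULL,
                        expression_scale = "log2") {
  geno <- if (grepl("\\.vcf(\\.gz)?$", genotype_path)) {
    read_vcf_genotypes(genotype_path)
  } else {
    read_dosage_tsv(genotype_path)
  }
  clinical <- read_clinical_tsv(clinical_path)
  abundance <- read_abundance_tsv(abundance_path)
  expression <- NULL
  ids <- Reduce(intersect, list(rownames(geno$dosages), clinical$sample_id,
                                rownames(abundance)))
  if (!is.null(expression_path)) {
    expression <- read_expression_tsv(expression_path, gene_annotation_path,
                                      scale = expression_scale)
    ids <- intersect(ids, colnames(expression$values))
  }
  if (!length(ids)) stop("load_cohort: no samples shared across inputs")
  n_all <- length(unique(c(rownames(geno$dosages), clinical$sample_id)))
  dropped <- n_all - length(ids)
  if (dropped > 0) {
    message("load_cohort: dropped ", dropped, " sample(s) not shared by all inputs")
  }
  geno <- genotype_matrix(geno$dosages[ids, , drop = FALSE], geno$snp_annotation)
  clinical <- clinical_table(clinical[match(ids, clinical$sample_id), ,
                                      drop = FALSE])
  abundance <- abundance[ids, , drop = FALSE]
  if (!is.null(expression)) {
    expression <- expression_matrix(expression$values[, ids, drop = FALSE],
                                    expression$gene_annotation,
                                    scale = expression$scale)
  }
  structure(list(genotypes = geno, expression = expression,
                 abundance = abundance, clinical = clinical,
                 n = length(ids)), class = "cohort")
}

#' Write a cohort to a directory (TSV + VCF + truth sidecar)
#'
#' @param cohort `cohort` (from [make_cohort()] or [load_cohort()]).
#' @param dir output directory (created).
#' @param truth optional truth record, serialized as JSON sidecar.
#' @export
write_cohort <- function(cohort, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_dosage_tsv(cohort$genotypes, file.path(dir, "dosages.tsv"))
  write_vcf(cohort$genotypes, file.path(dir, "genotypes.vcf"))
  write_clinical_tsv(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_abundance_tsv(cohort$abundance, file.path(dir, "abundance.tsv"))
  if (!is.null(cohort$expression)) {
    write_expression_tsv(cohort$expression, file.path(dir, "expression.tsv"))
    write_gene_annotation(cohort$expression$gene_annotation,
                          file.path(dir, "genes.bed"))
  }
  if (!is.null(truth)) {
    truth$architecture$eqtl_beta <- as.data.frame(truth$architecture$eqtl_beta)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(dir)
}

#' Run the full pipeline end to end
#'
#' simulate (or load) -> preprocess -> eQTL -> one-sample MR -> two-sample
#' replication -> downstream, writing a per-stage report that mirrors the
#' analysis funnel (genes in, eGenes, screened, causal, replicated).
#'
#' @param config a [sim_config()]; the cohorts are generated from it.
#' @param out_dir optional directory for TSV outputs and the report.
#' @param n_perm eQTL permutations.
#' @param stages character vector of stages to run after MR
#'   (subset of "enrich", "lrt", "de"); others are marked skipped.
#' @param seed seed for analysis randomness (clustering, permutations);
#'   defaults to the config seed.
#' @return list with `mr` (mr_result), `report` (character lines),
#'   `enrichment`, `lrt`, `paired` as requested.
#' @export
run_all <- function(config, out_dir = NULL, n_perm = 1000,
                    stages = c("enrich", "lrt", "de"), seed = config$seed) {
  cohorts <- make_cohort(config)
  report <- c(sprintf("cohort: discovery n=%d, validation n=%d",
                      cohorts$discovery$n, cohorts$validation$n),
              sprintf("genes in: %d", config$n_genes))
  mr <- run_mr(cohorts, n_perm = n_perm, seed = seed, truth = cohorts$truth)
  report <- c(report, sprintf("%s: %d", names(mr$counts), mr$counts))
  out <- list(mr = mr, cohorts = cohorts)

  causal_rows <- mr$results[mr$results$causal, , drop = FALSE]
  if (!is.null(mr$replication)) {
    rep_ok <- mr$replication[mr$replication$causal, , drop = FALSE]
    report <- c(report, sprintf("replicated: %d", length(unique(rep_ok$gene))))
    out$replicated <- unique(rep_ok$gene)
  }
  expr <- cohorts$discovery$expression
  clin <- cohorts$discovery$clinical
  if ("enrich" %in% stages && nrow(causal_rows)) {
    enr <- lapply(seq_len(nrow(causal_rows)), function(i) {
      g <- causal_rows$gene[i]
      dir <- if (causal_rows$causal_coef[i] > 0) "harmful" else "protective"
      lab <- classify_beneficial(expr, g, dir)
      cbind(gene = g, direction = dir,
            cms_enrichment(lab[clin$sample_id], clin$cms))
    })
    out$enrichment <- do.call(rbind, enr)
    report <- c(report, sprintf("enrichment: %d gene(s) evaluated",
                                nrow(causal_rows)))
  } else if (!("enrich" %in% stages)) {
    report <- c(report, "enrichment: skipped")
  }
  if ("lrt" %in% stages && nrow(causal_rows)) {
    Z <- clinical_design(clin)
    lrts <- lapply(unique(causal_rows$arm), function(a) {
      genes <- causal_rows$gene[causal_rows$arm == a]
      bio <- t(expr$values[genes, clin$sample_id, drop = FALSE])
      r <- prognostic_lrt(clin, bio, a, cbind(Z, cohorts$discovery$abundance))
      data.frame(arm = a, chi2 = r$chi2, df = r$df, p = r$p)
    })
    out$lrt <- do.call(rbind, lrts)
    report <- c(report, sprintf("prognostic LRT: %s chi2=%.2f (df=%d, p=%.3g)",
                                out$lrt$arm, out$lrt$chi2, out$lrt$df, out$lrt$p))
  } else if (!("lrt" %in% stages)) {
    report <- c(report, "prognostic LRT: skipped")
  }
  if ("de" %in% stages) {
    paired <- simulate_paired_de(config)
    de_genes <- if (nrow(causal_rows)) unique(causal_rows$gene) else
      rownames(paired$tumor)[1]
    de_genes <- intersect(de_genes, rownames(paired$tumor))
    out$paired <- do.call(rbind, lapply(de_genes, function(g) {
      r <- paired_de(paired, g)
      data.frame(gene = g, fold_change = r$fold_change, p = r$p)
    }))
    report <- c(report, sprintf("paired DE: %d gene(s) tested",
                                length(de_genes)))
  } else {
    report <- c(report, "paired DE: skipped")
  }
  out$report <- report
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(report, file.path(out_dir, "report.txt"))
    utils::write.table(mr$results, file.path(out_dir, "mr_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(mr$replication)) {
      utils::write.table(mr$replication, file.path(out_dir, "replication.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(out$enrichment)) {
      utils::write.table(out$enrichment, file.path(out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(mr$audit, file.path(out_dir, "audit.json"),
                         auto_unbox = TRUE)
  }
  out
}
#' Write / read a simulation configuration (lossless round-trip)
#'
#' Serializes every field of a [sim_config()] (including planted causal
#' genes, pleiotropic SNPs and paired-design settings) as human-editable
#' JSON; reading re-validates through `sim_config()`.
#'
#' @param config a `sim_config`.
#' @param path file path (.json).
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$covariate_effects <- as.list(x$covariate_effects)  # keep names in JSON
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$maf_range <- as.numeric(x$maf_range)
  x$covariate_effects <- unlist(x$covariate_effects)
  if (is.null(x$causal_genes) || length(x$causal_genes) == 0) {
    x$causal_genes <- NULL
  } else {
    x$causal_genes <- as.data.frame(x$causal_genes)
  }
  if (is.null(x$pleiotropic_snps) || length(x$pleiotropic_snps) == 0) {
    x$pleiotropic_snps <- NULL
  } else {
    x$pleiotropic_snps <- as.data.frame(x$pleiotropic_snps)
  }
  if (!is.null(x$paired_genes) && length(x$paired_genes)) {
    x$paired_genes <- as.data.frame(x$paired_genes)
  } else {
    x$paired_genes <- NULL
  }
  do.call(sim_config, x)
}
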