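#' Expression matrix container
#'
#' Genes x samples values plus per-gene annotation (chromosome and TSS) and a
#' scale flag. Scale transitions are one-way: raw -> uq_normalized -> log2.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids).
#' @param gene_annotation data frame with columns `gene`, `chrom`, `tss`
#'   (1-based), covering every row of `values`.
#' @param scale one of "raw", "uq_normalized", "log2".
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, gene_annotation,
                              scale = c("raw", "uq_normalized", "log2")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression_matrix: values needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop("expression_matrix: duplicate gene ids")
  if (anyDuplicated(colnames(values))) stop("expression_matrix: duplicate sample ids")
  if (!all(rownames(values) %in% gene_annotation$gene)) {
    stop("expression_matrix: annotation does not cover every gene")
  }
  gene_annotation <- gene_annotation[match(rownames(values), gene_annotation$gene), ,
                                     drop = FALSE]
  if (scale == "raw" && any(values < 0)) {
    stop("expression_matrix: raw values must be non-negative")
  }
  structure(list(values = values, gene_annotation = gene_annotation,
                 sample_ids = colnames(values), scale = scale),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples, scale = %s\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' Genotype dosage container
#'
#' Samples x SNPs dosages in \[0, 2\] (possibly missing before QC) plus SNP
#' annotation (chromosome, 1-based position, alleles, MAF).
#'
#' @param dosages numeric matrix, samples in rows, SNPs in columns (named).
#' @param snp_annotation data frame with columns `snp`, `chrom`, `pos`,
#'   `ref`, `alt` and optionally `maf` (recomputed from dosages if absent).
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, snp_annotation) {
  dosages <- as.matrix(dosages)
  if (is.null(colnames(dosages)) || is.null(rownames(dosages))) {
    stop("genotype_matrix: dosages needs SNP colnames and sample rownames")
  }
  if (!all(colnames(dosages) %in% snp_annotation$snp)) {
    stop("genotype_matrix: annotation does not cover every SNP")
  }
  snp_annotation <- snp_annotation[match(colnames(dosages), snp_annotation$snp), ,
                                   drop = FALSE]
  if (any(snp_annotation$pos <= 0)) stop("genotype_matrix: positions must be positive")
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("genotype_matrix: dosages must lie in [0, 2]")
  f <- colMeans(dosages, na.rm = TRUE) / 2
  snp_annotation$maf <- pmin(f, 1 - f)
  structure(list(dosages = dosages, snp_annotation = snp_annotation,
                 sample_ids = rownames(dosages)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' Validate a clinical table
#'
#' Checks the per-sample survival/covariate table the pipeline expects:
#' `sample_id`, `os_time` (> 0, months), `event` (0/1), `arm`
#' ("bevacizumab"/"cetuximab", non-missing), `age`, `gender`, `braf_v600e`,
#' `all_ras`, `batch`, optional `cms`.
#'
#' @param df data frame.
#' @return the validated data frame with class `clinical_table` prepended.
#' @export
clinical_table <- function(df) {
  need <- c("sample_id", "os_time", "event", "arm", "age", "gender",
            "braf_v600e", "all_ras", "batch")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("clinical_table: missing columns: ", paste(miss, collapse = ", "))
  if (any(df$os_time <= 0)) stop("clinical_table: os_time must be > 0")
  if (!all(df$event %in% c(0, 1))) stop("clinical_table: event must be 0/1")
  if (anyNA(df$arm)) stop("clinical_table: arm must be non-missing")
  if (!inherits(df, "clinical_table")) class(df) <- c("clinical_table", class(df))
  df
}

#' Standardized clinical covariate design Z for the hazard models
#'
#' Columns: age (centered, per SD), gender, BRAF V600E, all-RAS.
#'
#' @param clinical `clinical_table`.
#' @return numeric matrix with one row per sample.
#' @export
clinical_design <- function(clinical) {
  cbind(age = (clinical$age - mean(clinical$age)) / max(stats::sd(clinical$age), 1e-12),
        gender = clinical$gender,
        braf = clinical$braf_v600e,
        ras = clinical$all_ras)
}
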