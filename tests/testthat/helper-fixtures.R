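# Small in-code fixtures shared across test files.

# expression_matrix from a plain matrix, with dummy annotation on chr 1
em <- function(m, scale = "log2", chrom = "1") {
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  ann <- data.frame(gene = rownames(m), chrom = chrom,
                    tss = seq_len(nrow(m)) * 1e4, stringsAsFactors = FALSE)
  expression_matrix(m, ann, scale = scale)
}

# genotype_matrix from a plain dosage matrix (samples x SNPs)
gm <- function(d, pos = NULL, chrom = "1") {
  if (is.null(colnames(d))) colnames(d) <- paste0("snp", seq_len(ncol(d)))
  if (is.null(rownames(d))) rownames(d) <- paste0("s", seq_len(nrow(d)))
  if (is.null(pos)) pos <- seq_len(ncol(d)) * 100
  ann <- data.frame(snp = colnames(d), chrom = chrom, pos = pos,
                    ref = "A", alt = "B", stringsAsFactors = FALSE)
  genotype_matrix(d, ann)
}

# minimal valid clinical table for n samples
ct <- function(n, time = NULL, event = NULL, arm = NULL, seed = 1) {
  set.seed(seed)
  clinical_table(data.frame(
    sample_id = paste0("s", seq_len(n)),
    os_time = if (is.null(time)) stats::rexp(n, 0.05) + 0.1 else time,
    event = if (is.null(event)) stats::rbinom(n, 1, 0.7) else event,
    arm = if (is.null(arm)) rep_len(c("bevacizumab", "cetuximab"), n) else arm,
    age = stats::rnorm(n, 60, 10), gender = stats::rbinom(n, 1, 0.5),
    braf_v600e = stats::rbinom(n, 1, 0.1), all_ras = stats::rbinom(n, 1, 0.3),
    batch = rep_len(c("b1", "b2"), n), cms = rep_len(paste0("CMS", 1:4), n),
    stringsAsFactors = FALSE
  ))
}

# Nelson-Aalen cumulative hazard by hand (oracle for additive-hazard tests)
nelson_aalen <- function(time, event) {
  ev <- sort(unique(time[event == 1]))
  vapply(ev, function(t) {
    sum(vapply(ev[ev <= t], function(s) {
      sum(time == s & event == 1) / sum(time >= s)
    }, numeric(1)))
  }, numeric(1))
}
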