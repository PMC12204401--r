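#!/usr/bin/env Rscript
# Stage 3 — cis-eQTL mapping on the discovery cohort.
#
# Linear per-pair scans inside the +-1 Mb cis window, covariate-adjusted
# (clinical covariates + cell abundances), with permutation gene-level
# adjusted p-values; eGenes pass adjusted p < .05. Reads the cohort written
# by 01_simulate.R.

library(mrhaz)

d <- load_cohort("results/cohort/discovery/dosages.tsv",
                 "results/cohort/discovery/clinical.tsv",
                 "results/cohort/discovery/abundance.tsv",
                 "results/cohort/discovery/expression.tsv",
                 "results/cohort/discovery/genes.bed")

covs <- cbind(clinical_design(d$clinical), d$abundance)
em <- eqtl_map(d$expression, d$genotypes, covs, n_perm = 1000, seed = 20260929L)
egenes <- select_egenes(em$gene_table)

dir.create("results", showWarnings = FALSE)
write.table(em$pairs_table, "results/eqtl_pairs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(em$gene_table, "results/eqtl_genes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("%d/%d genes have a cis-eQTL at gene-level adjusted p < .05",
                length(egenes), nrow(em$gene_table)))
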