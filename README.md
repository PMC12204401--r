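# mrhaz

Mendelian randomization for treatment-specific survival with additive
hazards.

`mrhaz` asks whether a tumor gene's expression *causally* shortens or
lengthens overall survival (OS) under a specific therapy, using germline
cis-regulatory variants as instrumental variables. It was built for a
two-arm metastatic colorectal cancer setting (bevacizumab vs cetuximab, each
plus chemotherapy): a discovery cohort with germline genotypes, tumor
RNA-seq and OS, and a validation cohort with genotypes and OS only. Because
such cohorts are access-controlled, the package includes a synthetic-cohort
generator that reproduces the statistical structure the analysis assumes —
cis blocks with LD, planted eQTL effects, cell-composition confounding, and
additive-hazard survival with treatment-specific gene effects — so the whole
pipeline runs, and is tested, offline.

## The method

The outcome model is the Aalen additive hazard with time-varying
coefficients,

    h(t | X) = h0(t) + γ(t)ᵀZ + θ(t)ᵀE + β(t)ᵀG,

with clinical covariates Z (age, gender, BRAF V600E, all-RAS), enriched
immune-cell abundances E, and gene expressions G. Cumulative coefficients
are estimated by least-squares increments at event times; per-covariate
tests use the cumulative effect at the 0.75 quantile of event times.

The pipeline:

1. **cis-eQTL mapping** — per gene–SNP pair within ±1 Mb of the TSS,
   covariate-adjusted OLS; gene-level adjusted p-values by Freedman–Lane
   residual permutation; eGenes at adjusted p < .05.
2. **OS screen** — eGenes k-means-clustered into 4 groups; one
   multivariable additive-hazard fit per cluster and arm; screen at p < .1.
3. **Instruments** — cis SNPs at nominal p < .05, hierarchically clustered
   on 1 − r², one representative per cluster, pairwise r² ≤ 0.1; weights =
   marginal eQTL betas.
4. **Pleiotropy screen** — Cox GWAS-style fit per instrument; exclusion at
   p < 1e-4.
5. **One-sample MR** — predicted expression ĝ = QW must correlate > 0.5
   with observed expression; arm-specific additive-hazard causal test at
   p < .05.
6. **Two-sample replication** — ĝ* = Q*(QᵀQ)⁻¹Qᵀg transported to the
   validation cohort; treatment-specific additive-hazard test.
7. **Downstream** — CMS subtype enrichment of beneficial/non-beneficial
   expression (strict >70% rule), prognostic likelihood-ratio tests, paired
   tumor/normal differential expression, median-split Kaplan–Meier curves.

## Worked example

Simulate a discovery/validation pair with one causal gene planted in the
bevacizumab arm, then run the full MR pipeline:

```r
library(mrhaz)

cfg <- sim_config(
  n_discovery = 1200, n_validation = 600, n_genes = 12, n_egenes = 12,
  causal_genes = data.frame(gene = "gene003", arm = "bevacizumab",
                            slope = 0.012),
  seed = 1
)
co <- make_cohort(cfg)
mr <- run_mr(co, n_perm = 1000, seed = 1, truth = co$truth)
print(mr)
subset(mr$results, causal,
       select = c(gene, arm, causal_coef, causal_p, correlation))
subset(mr$replication, arm == "bevacizumab",
       select = c(gene, arm, coef, p, causal))
```

```
MR pipeline funnel:
       egenes      screened  instrumented prediction_ok        causal 
           12             3             3             3             1 
planted causal genes recovered: 1/1
     gene         arm causal_coef    causal_p correlation
1 gene003 bevacizumab 0.009657712 0.001715733   0.5545343
     gene         arm       coef            p causal
1 gene003 bevacizumab 0.01725373 0.0005358293   TRUE
```

Reading: all 12 genes have a cis-eQTL; 3 pass the OS screen in some arm,
survive instrument selection and the pleiotropy screen, and clear the 0.5
correlation gate (the planted gene's prediction correlates 0.55 with its
observed expression, near the sqrt(h2) = 0.55 ceiling). Exactly the planted
gene is called causal, in the correct arm, with an estimated hazard slope
of 0.0097 per unit log2 expression per month (truth: 0.012). The two-sample
stage re-tests it in the validation cohort from genotypes alone and
replicates the call (p = 0.0005).

The `analysis/` directory holds the same workflow as numbered stage scripts
(`01_simulate.R` … `05_downstream.R`) writing tables under `results/`.

## Layout

- `R/` — simulator, preprocessing filters, eQTL mapping, survival models
  (Aalen additive hazards authored here; Cox/KM via `survival`), MR
  pipeline, downstream analyses, TSV/VCF IO.
- `vignettes/mrhaz-methods.Rmd` — model, assumptions, design decisions,
  calibration of the simulation scenarios, limitations.
- `tests/testthat/` — unit, property and simulation-based acceptance tests.
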