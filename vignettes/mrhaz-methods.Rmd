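---
title: "Treatment-specific causal biomarkers for survival: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Treatment-specific causal biomarkers for survival: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrhaz)
```

# The problem

In randomized oncology trials, patients on the same targeted therapy show
very different overall survival (OS). If part of that variation is driven by
tumor gene expression, expression is a candidate predictive biomarker — but
observed expression–survival associations are confounded (tumor composition,
clinical state, technical batch). Mendelian randomization (MR) addresses this
by using germline cis-regulatory variants as instrumental variables: a
variant that shifts a gene's expression, is fixed at conception, and has no
direct path to survival supports a causal reading of the expression–OS
association it induces.

`mrhaz` implements that design for a two-arm setting (bevacizumab vs
cetuximab, each on top of chemotherapy, in metastatic colorectal cancer):
cis-eQTL mapping in a discovery cohort with tumor RNA-seq, instrument
selection, a pleiotropy screen, one-sample MR against treatment-specific OS,
two-sample replication in a genotype-only validation cohort, and downstream
characterization (consensus molecular subtype enrichment, prognostic
likelihood-ratio tests, paired tumor/normal differential expression).
Because the cohorts that motivate this design are access-controlled, the
package ships a synthetic-cohort generator that reproduces the statistical
structure the analysis assumes, and every stage is exercised against it.

# The outcome model: additive hazards with time-varying coefficients

The survival model throughout is the Aalen additive hazard

$$ h(t \mid X) \;=\; h_0(t) \;+\; \gamma(t)^\top Z \;+\; \theta(t)^\top E
\;+\; \beta(t)^\top G, $$

where $Z$ are clinical covariates (age, gender, BRAF V600E, all-RAS), $E$
are enriched immune-cell abundances (bulk-tissue composition acts as a
confounder of expression), and $G$ holds gene expressions (or their
genetically predicted values $\hat g$). Coefficients are time-varying, so a
gene's effect on the hazard need not be constant over follow-up; effects are
additive on the hazard scale (per month), not multiplicative.

`fit_additive_hazard()` estimates cumulative coefficients
$B_j(t) = \int_0^t b_j(s)\,ds$ by the least-squares increment estimator: at
each distinct event time, $dB = (X_R^\top X_R)^{-1} X_R^\top dN$ over the
at-risk set, with tied events absorbed into a single increment and variances
from the optional-variation estimator. Estimation freezes at the first event
time where the at-risk design loses rank.

**Where the test statistic is evaluated.** The per-covariate test is
$z_j = \hat B_j(\tau)/\widehat{SE}(\hat B_j(\tau))$, two-sided normal. We
evaluate it at $\tau$ = the 0.75 quantile of the estimable event times, not
at the last one. Near the end of follow-up the at-risk count approaches the
number of design columns and the variance increments — each of order
1/(at-risk size) — dominate the cumulative statistic; against a constant planted
effect the literal endpoint statistic is markedly noisier, losing power
while gaining nothing in size. The choice
mirrors the common practice of restricting additive-hazard tests to an
interior time. `tau_quantile = 1` restores the literal endpoint statistic,
and `sup_test = TRUE` adds a supremum-type statistic for sensitivity
analysis. A per-covariate test for this model has no single canonical form;
the cumulative-to-$\tau$ z-score is this package's declared choice.

Cox proportional-hazards fits (the pleiotropy screen and the prognostic
LRT) delegate to `survival::coxph()` with Efron tie handling. The
likelihood-ratio test is computed on nested Cox models: additive-hazard
models have no conventional likelihood, so "with vs without the biomarkers"
is interpreted on the Cox scale, and the package documents it as such.

# The MR pipeline

1. **cis-eQTL mapping** (`eqtl_map`): for every gene–SNP pair within 1 Mb of
   the TSS (inclusive), OLS of log2 expression on dosage adjusted for
   $Z$, batch and $E$. Gene-level p-values come from Freedman–Lane residual
   permutations: expression residuals (after covariate regression) are
   permuted and the best cis statistic recomputed, so covariate structure
   cannot inflate the null; adjusted p = (1 + exceedances)/(1 + permutations)
   with adaptive early stopping after 100 exceedances. eGenes pass adjusted
   p < .05 (strict).
2. **OS screen** (`screen_gene_os`): eGenes are k-means-clustered (k = 4, 25
   restarts) on their expression profiles, and one multivariable
   additive-hazard model per cluster and arm screens genes at p < .1
   (strict). Clustering bounds the number of simultaneous gene columns to
   prevent overfitting.
3. **Instruments** (`select_instruments`): candidate SNPs at nominal
   p < .05 are grouped by average-linkage hierarchical clustering on
   1 − r², the tree is cut at height 1 − 0.1, one representative per cluster
   is kept (smallest p; ties broken by position), and representatives are
   greedily pruned so every retained pair has r² ≤ 0.1. Weights are the
   representatives' marginal eQTL betas.
4. **Pleiotropy screen** (`check_pleiotropy`): per instrument, a Cox fit of
   OS on dosage plus covariates (gender, age, all-RAS, first expression PC);
   instruments with Wald p < 1e-4 are excluded. Note an intrinsic tension:
   a strong instrument of a truly causal gene carries an indirect
   dosage→expression→OS effect, and in large cohorts the screen can
   false-exclude exactly those instruments. We observe this in simulation at
   n ≈ 1600+ and treat it as fidelity to the method, not a defect to patch.
5. **Prediction and gate** (`predict_expression_onesample`):
   $\hat g = QW$ on centered dosages; the prediction enters the causal test
   only if its Pearson correlation with observed expression exceeds 0.5.
   With cis heritability $h^2$, the best achievable correlation is about
   $\sqrt{h^2}$, so at $h^2 = 0.3$ the gate sits just below the attainable
   ceiling (≈ 0.55) — it is a sharp filter, and a noticeable fraction of
   genuinely well-instrumented genes fails it by sampling error.
6. **Causal test** (`causal_test`): per arm, one additive-hazard fit with
   all of that arm's screen survivors' $\hat g$ (centered) plus $Z$ and $E$;
   causal means p < .05 (strict). Both arms' p-values are reported for
   comparison. Restricting each arm's model to that arm's screen survivors
   follows the workflow's funnel reading.
7. **Two-sample replication** (`predict_expression_twosample`):
   $\hat g^* = Q^*(Q^\top Q)^{-1} Q^\top g$ — joint OLS weights on centered
   discovery data applied to validation dosages centered at discovery
   means — then the treatment-specific additive-hazard test in the
   validation cohort. The deliberate asymmetry (marginal weights one-sample,
   joint weights two-sample) matches the two prediction formulas as printed.

# The synthetic-cohort generator

`sim_config()` fixes the study conditions; `make_cohort()` draws one genetic
architecture (SNP positions, MAFs, planted eQTL weights) and then two
cohorts from it, so discovery and validation are samples from the same
population. Defaults are the scale of a phase III correlative study:
discovery n = 273 with expression, validation n = 602 genotype-only, two
arms 1:1.

* **Genotypes**: per-gene cis blocks of 5 SNPs; each haplotype is a latent
  AR(1) Gaussian vector (adjacent correlation `ld_rho`) thresholded at the
  allele-frequency quantile, dosage = sum of two haplotypes. This Gaussian
  copula controls MAF and LD jointly. `ld_rho = 0.9` by default — a tight
  cis LD block. The choice matters more than it looks: with intermediate LD
  (ρ ≈ 0.5) the block yields several instrument clusters correlated at
  r ≈ 0.3, and the marginal-weight predictor $QW$ then has an *asymptotic*
  correlation with expression of ≈ 0.50 at $h^2 = 0.3$ — exactly at the 0.5
  gate, which would make the gate a coin flip by construction. Under tight
  LD the block collapses to a single cluster, the lead variant is the sole
  instrument, the predictor is consistent, and predictions clear the gate —
  the only regime in which the gate is informative rather than a coin flip.
* **Expression**: one causal lead variant per eGene (mid-block, random
  sign), scaled so the cis genetic variance is exactly `eqtl_h2`; plus a
  cell-composition confounder (`confounder_strength` on the standardized
  first abundance column) and Gaussian noise to unit variance. A raw-count
  matrix with log-normal library-size factors is emitted for the
  normalization path.
* **Survival**: additive hazard, constant in time given covariates —
  baseline 0.025/month (median OS around 26 months with the covariate
  offsets, a realistic figure for metastatic colorectal cancer), covariate
  effects of a few 1e-3/month, and arm-specific slopes on centered log2
  expression for the planted causal genes. Negative hazards are floored at
  zero; the generator refuses configurations where more than 5% of draws go
  negative before flooring, which effectively caps the dimensionless effect
  size (slope/baseline) near 0.45 for one causal gene per arm and 0.30 for
  two. Censoring is independent uniform with the horizon solved numerically
  so the expected censored fraction equals `censoring_rate` (default 0.3).
* **CMS labels**: multinomial logit tilted by two designated genes (high
  gene A → CMS1, low → CMS4; high gene B → CMS3), strength configurable so
  enrichment beyond 70% can be planted.
* **Paired tumor/normal**: per-pair random intercepts, planted log2
  fold-changes, Gaussian noise.

What the generator does **not** emulate: genome-wide LD and population
structure, imputation uncertainty, non-Gaussian expression tails,
informative censoring, and time-varying true effects. Passing tests
therefore demonstrate the pipeline's statistical behaviour under its own
model assumptions, not robustness to their violation.

# Calibration of the planted-effect scenarios

The simulation scenarios used by the acceptance tests were fixed once, as
follows. Cohort sizes: discovery 600 (null calibration) or 1600 (recovery),
validation 600; 20–40 genes, all eGenes at $h^2 = 0.3$. Hazard slopes for
planted causal genes are 0.010/month per unit log2 expression: with two
causal genes sharing an arm, this is close to the largest slope the
hazard-positivity guard admits, and it gives ~85–90% marginal power for the
causal test at 800 subjects per arm — chosen so that the end-to-end
recovery rate stays near 80% after the multiplicative losses of the
correlation gate (~5%) and the pleiotropy screen's false exclusions
(~10%). The pleiotropy scenario plants a direct effect of 0.007/month per
allele at n = 2000, sized for ~0.9 power at the 1e-4 exclusion threshold.
Replicate counts (400 for size, 100 for power) balance Monte-Carlo error
(±4–5 percentage points on a rate) against the test suite's runtime; these
problem sizes are the package's declared desk-scale study conditions.

# Numerical and boundary conventions

* Exclusion rules quoted with strict inequalities are strict: genes with SD
  < 0.5 or > 30% zeros are removed (exactly 30% survives); cell types need
  SD strictly > 0.12 and ≤ 30% zeros; eGenes need adjusted p strictly
  < .05; enrichment needs a fraction strictly > 0.70; MAF exactly 0.05
  survives QC.
* Upper-quartile normalization divides each sample by the 75th percentile
  of its nonzero values and rescales by the global mean of those quartiles
  (no convention fixes the rescaling constant; this keeps values on the
  input scale), then log2(x + 1).
* Hardy–Weinberg uses the exact conditional test (enumeration over
  heterozygote counts), safe for sparse genotype classes.
* Median splits assign at-median samples to the "below" side
  (deterministic). Enrichment medians are study-wide; KM medians are
  per-arm by default with a study-wide option (`median_within`), as either
  convention is defensible for visualization.
* Missing dosages surviving QC are mean-imputed per SNP (required for the
  matrix algebra of prediction).
* The two-sample Gram matrix falls back to ridge (penalty 1e-8 × trace)
  only if numerically singular, with a message.
* k-means uses 25 restarts under a caller-supplied seed; permutation
  p-values are bit-reproducible given a seed.

# Known limitations

* The additive-hazard per-covariate test relies on a normal approximation
  at $\tau$; with very few events per design column its size degrades
  (the global-null acceptance check bounds this at the scales used).
* The correlation gate at 0.5 is intrinsically sharp against
  $\sqrt{h^2} \approx 0.55$; pipelines run at lower heritability will lose
  most genes at the gate, which is the method's behaviour, not a bug.
* The pleiotropy screen cannot distinguish direct SNP→OS effects from
  strong indirect effects through the instrumented gene; at large n it
  removes some valid instruments of true causal genes.
* The prognostic LRT is computed on Cox models although the discovery
  model is additive; the two scales agree qualitatively but not in effect
  units.
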