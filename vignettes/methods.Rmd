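---
title: "Inferring stage-dependent TF activity from matched multi-omics profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring stage-dependent TF activity from matched multi-omics profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfactivity)
```

## The problem

Tumors sampled at early and late clinical stages differ in the expression of
hundreds of genes. Three mechanisms can produce such stage-dependent
alterations: a change in a gene's DNA copy number (dosage), a change in its
promoter methylation (repression), and a change in the *activity* of the
transcription factors (TFs) that bind it. The first two are directly
measurable per gene and per sample; TF activity is not — it is largely set
post-transcriptionally and post-translationally, so a TF's own mRNA level is
a poor proxy. This package infers TF activity changes from their footprint
on target-gene expression, after accounting for the measurable genomic and
epigenomic contributions.

## The model

For gene $i$ and sample $j$, with $y_{ij}$ the log2 mRNA expression,
$C_{ij}$ the linear copy-number estimate, $M_{ij}$ the methylation beta
value, $S_j \in \{0, 1\}$ the late-stage indicator and
$B_{fi} \in \{0, 1\}$ the binding incidence of TF $f$ on gene $i$:

$$ y_{ij} \;=\; \beta_i^{CN}\, C_{ij} \;+\; \beta_i^{Me}\, M_{ij}
   \;+\; \sum_f \beta_f\, S_j\, B_{fi} \;+\; \varepsilon_{ij} . $$

Each gene has its own dosage slope $\beta_i^{CN}$ (expected positive) and
methylation slope $\beta_i^{Me}$ (expected negative); the TF coefficients
$\beta_f$ are *shared* across genes and quantify the average shift in a
TF's targets in late-stage relative to early-stage samples, in log2
expression units. The model is fit by least squares over all
$n = n_{genes} \times n_{samples}$ stacked observations. There is no
intercept and no per-gene baseline term: the model is implemented exactly
as written (the covariate terms absorb baselines only partially), with an
optional per-gene centering flag that is off by default.

### Why the fit is cheap: arrowhead structure

The normal equations decompose into independent $2 \times 2$ per-gene
blocks (the two covariate slopes) coupled only through the $n_{TF}$ shared
columns — an arrowhead matrix. `fit_integrative()` eliminates each gene
block in closed form, assembles the $n_{TF} \times n_{TF}$ Schur
complement $\Sigma = B\,\mathrm{diag}(n_{IV} - w_i)\,B^\top$, solves for
$\beta_f$, and back-substitutes the per-gene slopes. The full design
matrix is never materialized; a cohort-scale problem (thousands of genes,
hundreds of samples) fits in well under a second. Standard errors come
from $\hat\sigma^2 \Sigma^{-1}$ for the TF coefficients and from the
corresponding diagonal blocks of the inverse normal matrix for the
per-gene slopes, with $\hat\sigma^2 = SSE/(n - p)$ and a normal reference
for p-values ($n - p$ is huge, so the $t$ and normal references coincide).
Ridge adds $\lambda I$ inside the same solver; lasso is delegated to
`glmnet` on the sparse design (no intercept, no standardization), since
the L1 path is not where this package adds value. A gene whose copy number
and methylation are both constant across samples has a singular block; the
default behavior is a per-block ridge fallback ($10^{-8}$ scaled) with a
warning, or an error in strict mode.

## Surrounding pipeline

* **Gene filter.** Only genes bound by strictly more than `min_tfs`
  (default 5) TFs enter the model; genes with few annotated regulators
  carry little information about shared activity terms. TF entries with
  identical target sets are merged up front (`merge_duplicate_tfs()`),
  because identical columns make their coefficients unidentifiable.
* **Differential expression** (`de_test()`): per-gene pooled-variance
  two-sample t-test on log2 expression with Benjamini–Hochberg adjustment;
  a gene is called at linear fold change $> 2$ (i.e. $|\log_2 FC| > 1$,
  strict) and FDR $< 0.001$ (strict). This is an ordinary t-test, not a
  moderated (empirical-Bayes) one: at the intended sample sizes
  (dozens per group) variance moderation changes little, and the plain
  test has a closed-form oracle the test suite exploits.
* **Correlation profiling** (`per_gene_correlation()`): per-gene Pearson
  correlation between a covariate layer and expression across all samples
  pooled (a single $r$ per gene), with $p$ from the $t$ transform.
  Distribution comparisons between a gene set and its complement use the
  two-sample Kolmogorov–Smirnov test; the complement, rather than the full
  gene universe, is the reference so the two samples are independent.
* **Cross-validated evaluation** (`crossval()`): samples are partitioned
  into $k$ stage-stratified folds and genes into $k$ folds. "Held-out
  patients and genes" is under-specified as a protocol, so the package
  uses the strictest reading that still permits prediction: TF
  coefficients are estimated without ever seeing held-out genes; held-out
  genes' covariate slopes are then estimated on training samples with the
  TF terms fixed (one 2-parameter regression per gene); predictions are
  issued only for held-out genes on held-out samples. An alternative
  `holdout = "samples"` mode (all genes, held-out samples only) is
  available. Performance is the per-gene Spearman correlation over
  held-out samples, aggregated by mean and median. Two baselines mirror
  the model comparison: a TF-only fit (covariate columns removed) and a
  randomized baseline that permutes the whole expression grid before
  training. The grid-wide permutation (rather than within-gene) is the
  default because it most directly randomizes "expression abundances";
  within-gene permutation is available as a flag.
* **TF selection** (`infer_tf_activity()`): BH across the TF family only,
  selection at FDR $< 0.001$ and $|\beta_f| > 0.5$ (both strict).
  "Effect size" is interpreted as $|\beta_f|$ itself — the average log2
  shift of a target gene attributable to the TF.
* **Attribution** (`attribute_genes()`): a DE gene is *explained by* a
  covariate mechanism when its coefficient is individually significant
  (default $p < 0.01$), the coefficient times the covariate's observed
  stage shift agrees in sign with the gene's fold change, **and** that
  contribution exceeds `min_contribution` (default 0.25 log2 units) in
  magnitude. The magnitude clause is this package's own addition to the
  sign rule: a significant slope multiplied by a noise-level covariate
  shift has a random sign and would otherwise flag roughly half of all
  genes. A gene is explained by TF activity when a selected TF binds it
  with matching sign; those TFs are reported as supporting evidence.
  `attribution_summary()` tabulates the seven Venn regions and the
  unexplained remainder.

## The synthetic world

`simulate_dataset()` generates matched matrices with exactly the model's
generative structure plus Gaussian noise, and a ground-truth record for
recovery tests. Choices the data do not dictate were fixed once:

* $C_{ij} \sim N(2, 0.4)$ truncated at 0 — a diploid baseline with
  moderate dosage variation; $M_{ij} \sim \mathrm{Beta}(2, 5)$ — a
  right-skewed beta-value marginal typical of promoter methylation. The
  downstream mathematics is distribution-agnostic, so these are
  plausibility choices, not tuning knobs.
* Defaults emulate the cohort scale the model was designed around:
  stage-IV fraction 0.31 (55 of 178 samples), per-gene dosage slopes
  $N(0.5, 0.2)$ (positive), methylation slopes $N(-1, 0.4)$ (negative),
  2000 genes × 200 samples × 50 TFs with 10 active TFs at
  $|\beta_f| = 1$ and alternating signs (both directions exercised),
  residual sd 0.5.
* The binding incidence is a random bipartite graph with a configurable
  mean target-set size; columns are redrawn (bounded) until every gene
  exceeds the `min_tfs` rule, so simulated data pass the pipeline's gene
  filter by construction.
* Optional stage-gated shifts of the CNV or methylation covariate for a
  chosen gene subset plant single-mechanism DE genes; defaults are zero,
  leaving the base world untouched. These exist so attribution can be
  tested against a known mechanism.

What a green test does **not** establish: the generator draws independent
Gaussian noise and independent covariates, so it cannot expose violations
of the linear-additivity assumption (combinatorial TF logic, saturation),
correlated noise across genes, probe-level methylation artifacts, or
binding-annotation errors — all of which real cohorts contain. Recovery
results on synthetic data are a correctness check of the estimator, not
evidence about biology.

## Numerical choices

* Strict inequalities at every published threshold (FC, FDR, effect
  size, TF-count filter), so boundary values are excluded.
* Gene and sample order after alignment is lexicographic with fixed
  (C-locale) collation; identical seeds give bit-identical results
  end-to-end, including pipeline artifacts.
* BH adjustment is implemented as the step-up definition and checked
  against a brute-force oracle; KS statistics are delegated to
  `stats::ks.test` with the D statistic verified against an
  empirical-CDF-gap oracle. One-sided KS alternatives use set semantics
  ("less" = the set's values tend to be smaller), mapped internally onto
  R's CDF convention.
* Degenerate inputs: zero-variance genes yield defined fallbacks
  (`p = 1` for a no-signal DE gene, an undefined marker in correlation
  profiles) rather than errors; singular gene blocks fall back to a tiny
  ridge with a warning.

## Known limitations

* TF activity is identified only through stage-gated target shifts; TFs
  whose activity changes within a stage, or that act on genes outside the
  annotation, are invisible.
* Binding incidence is binary; site counts or chromatin-informed weights
  are out of scope.
* The moderated-variance machinery of dedicated DE packages is not
  reproduced; with very few samples per group the plain t-test loses
  power relative to those tools.
* Per-gene methylation must already be collapsed to one value per gene;
  multiple rows per gene are rejected rather than averaged, since no
  collapsing rule is universally right.
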