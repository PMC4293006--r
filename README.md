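# tfactivity

Inference of stage-dependent **transcription factor (TF) activity changes**
from matched tumor multi-omics profiles: log2 mRNA expression, DNA copy
number, and promoter methylation, plus a clinical early/late stage label
per sample and TF–target binding sets (GMT).

TF activity is mostly set post-transcriptionally, so it cannot be read off
a TF's own mRNA. This package infers it from the footprint a TF leaves on
its *targets*, after first crediting each gene's measurable genomic and
epigenomic drivers. For gene *i* and sample *j*:

```
y_ij = beta_i^CN * C_ij + beta_i^Me * M_ij + sum_f beta_f * S_j * B_fi + e_ij
```

where `y` is log2 expression, `C` copy number, `M` methylation beta value,
`S_j` the late-stage indicator, and `B_fi` the binary binding incidence.
The per-gene slopes `beta_i^CN`, `beta_i^Me` capture dosage and repression
effects; the shared `beta_f` is the activity change of TF *f* (log2 shift
of its targets in late vs. early stage). The least-squares problem has an
**arrowhead** normal-equation structure — independent 2×2 per-gene blocks
coupled only through the TF columns — which `fit_integrative()` solves
exactly by block elimination and a TF-space Schur complement, without ever
materializing the design matrix.

Around the model, the package provides the full analysis pipeline:

| stage | function(s) |
|---|---|
| read/align TSV matrices, clinical table, GMT sets | `read_omics_matrix`, `read_clinical`, `read_gmt`, `align_dataset` |
| merge duplicate TFs, filter genes by TF count | `merge_duplicate_tfs`, `filter_genes_by_tf_count` |
| synthetic data with ground truth | `simulation_params`, `simulate_dataset`, `permute_expression` |
| stage-dependent differential expression | `de_test`, `filter_de`, `bh_adjust` |
| CNV/methylation–expression correlation profiling | `per_gene_correlation`, `summarize_correlations`, `compare_distributions` |
| structured model fit (OLS / ridge / lasso) + TF table | `build_design`, `fit_integrative`, `fit_tf_only`, `infer_tf_activity`, `residual_diagnostics` |
| cross-validated prediction vs. baselines | `crossval`, `stage_change_correlation`, `target_shift_test` |
| per-gene mechanism attribution (Venn dissection) | `attribute_genes`, `attribution_summary` |
| end-to-end pipeline + CLI | `run_pipeline`, `inst/cli/tfactivity.R` |

## Worked example

Simulate a cohort with 4 active TFs planted at |activity change| = 1,
recover them, and compare models:

```r
library(tfactivity)

sim <- simulate_dataset(simulation_params(
  n_genes = 500, n_samples = 120, n_tfs = 20, targets_per_tf = 200,
  n_active_tfs = 4, active_beta_magnitude = 1.0, noise_sd = 0.5, seed = 42))

fit <- fit_integrative(sim$dataset, sim$map)
#> ModelFit (integrative, ols): 60000 obs, 1020 coef, SSE = 1.485e+04

head(infer_tf_activity(fit), 6)
#>      tf        beta          se   p_value       fdr selected
#> 1 TF002  1.00167989 0.008693342 0.0000000 0.0000000     TRUE
#> 2 TF004 -1.00208444 0.008878130 0.0000000 0.0000000     TRUE
#> 3 TF011  1.00904361 0.008854544 0.0000000 0.0000000     TRUE
#> 4 TF016 -0.98676667 0.008728120 0.0000000 0.0000000     TRUE
#> 5 TF012 -0.01262455 0.008887398 0.1554622 0.5358401    FALSE
#> 6 TF018  0.01205586 0.008744969 0.1680166 0.5358401    FALSE

sim$truth$active_tfs
#> [1] "TF002" "TF004" "TF011" "TF016"
```

The four planted TFs are recovered at their true magnitudes
(selection: FDR < 0.001 and |beta| > 0.5, both strict) and all
null TFs are rejected. Differential expression and cross-validated
prediction (held-out patients *and* genes):

```r
table(de_test(sim$dataset)$status)
#> down   ns   up
#>   86  327   87

crossval(sim$dataset, sim$map, k = 5, seed = 42)
#> CVReport (integrative, k = 5): mean Spearman = 0.5914, median = 0.6492 (0 gene(s) NA)
crossval(sim$dataset, sim$map, k = 5, seed = 42, model = "tf_only")
#> CVReport (tf_only, k = 5): mean Spearman = 0.3632, median = 0.5351 (0 gene(s) NA)
```

The integrative model predicts held-out expression better than the
TF-only baseline because it also credits each gene's copy-number and
methylation dosage. Finally, mechanism attribution of the DE genes —
in this simulation every alteration is TF-driven, and the Venn
dissection says exactly that:

```r
de  <- de_test(sim$dataset)
rec <- attribute_genes(fit, infer_tf_activity(fit), de, sim$dataset, sim$map)
attribution_summary(rec)$regions
#>    cnv_only   meth_only     tf_only    cnv_meth      cnv_tf     meth_tf cnv_meth_tf
#>           0           0         173           0           0           0           0
```

## Command line

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "tfactivity.R", package = "tfactivity"))') \
  run-all --config config.txt --outdir out/
```

Subcommands: `simulate`, `de`, `correlate`, `fit`, `crossval`, `dissect`,
`run-all`, plus `--version`. The config is plain `key = value` text; all
thresholds default to the published analysis (FC > 2, DE FDR < 0.001,
correlation alpha 0.01, TF FDR < 0.001 with |effect| > 0.5, > 5 binding
TFs per gene, k = 10 folds). Reruns with an identical config reproduce
all artifacts bit-identically.

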