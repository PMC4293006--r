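#' Stratified fold assignment
#'
#' Assigns items to `k` folds, keeping the per-level proportions of
#' `strata` balanced (every fold receives at least one item of each level
#' when arithmetically possible). Reproducible under a fixed seed;
#' the assignment is a partition (each item in exactly one fold).
#'
#' @param strata factor/character vector of stratum labels (one per item).
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return integer vector of fold ids in `1..k`, same length as `strata`.
#' @export
stratified_folds <- function(strata, k, seed) {
  stopifnot(k >= 2)
  set.seed(seed)
  folds <- integer(length(strata))
  for (lv in unique(as.character(strata))) {
    idx <- which(as.character(strata) == lv)
    if (length(idx) < k)
      stopf("stratum '%s' has %d item(s), fewer than k = %d folds",
            lv, length(idx), k)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

## unstratified partition into k folds
plain_folds <- function(n, k, seed) {
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

## per-gene 2-parameter least squares of (y - stage-gated TF offset) on
## (C, M) over a fixed sample set, vectorized over genes
refit_gene_blocks <- function(Y, C, M, s_ind, tshift) {
  yt <- Y - outer(tshift, s_ind)
  a11 <- rowSums(C * C); a22 <- rowSums(M * M); a12 <- rowSums(C * M)
  q1 <- rowSums(C * yt); q2 <- rowSums(M * yt)
  dt <- a11 * a22 - a12^2
  sing <- dt <= 1e-12 * pmax(a11 * a22, 1)
  if (any(sing)) {
    eps <- 1e-8 * (a11 + a22 + 1)
    a11[sing] <- a11[sing] + eps[sing]
    a22[sing] <- a22[sing] + eps[sing]
    dt <- a11 * a22 - a12^2
  }
  list(beta_cn = (a22 * q1 - a12 * q2) / dt,
       beta_me = (a11 * q2 - a12 * q1) / dt)
}

#' Cross-validated prediction of expression
#'
#' k-fold cross-validation over held-out patients and genes: samples are
#' partitioned into `k` stage-stratified folds and genes into `k` folds;
#' in round `t` the model is trained on training genes x training samples
#' (TF activity coefficients never see held-out genes), each held-out
#' gene's copy-number/methylation slopes are then estimated on training
#' samples with the TF coefficients fixed, and predictions are issued for
#' held-out genes on held-out samples only. Performance is the Spearman
#' rank correlation between predicted and observed expression, computed per
#' gene over its held-out samples and aggregated by mean and median.
#'
#' `model = "tf_only"` trains the TF-only baseline (predictions are the
#' stage-gated TF shift alone); `model = "random"` first permutes the
#' expression grid with [permute_expression()] and then runs the
#' integrative protocol. `holdout = "samples"` is a simpler alternative
#' protocol: only samples are held out and all genes are predicted for
#' them.
#'
#' @param dataset an [omics_dataset()].
#' @param map a [tf_target_map()] aligned to the dataset's genes.
#' @param k number of folds (default 10).
#' @param seed integer seed controlling fold assignment (and the
#'   permutation for `model = "random"`).
#' @param model `"integrative"`, `"tf_only"` or `"random"`.
#' @param holdout `"genes_and_samples"` (default) or `"samples"`.
#' @return an object of class `CVReport`: list with `per_gene`
#'   (`data.frame`: `gene_id`, `fold`, `spearman`), `mean_spearman`,
#'   `median_spearman`, `n_na`, `predicted` (genes x samples matrix, `NA`
#'   where never predicted), `model`, `k`, `seed`.
#' @export
crossval <- function(dataset, map, k = 10L, seed = 1L,
                     model = c("integrative", "tf_only", "random"),
                     holdout = c("genes_and_samples", "samples")) {
  model <- match.arg(model)
  holdout <- match.arg(holdout)
  stopifnot(k >= 2)
  work <- dataset
  if (model == "random")
    work <- permute_expression(dataset, seed = seed)
  genes <- dataset_genes(work)
  samples <- dataset_samples(work)
  ng <- length(genes); ns <- length(samples)
  sfolds <- stratified_folds(work$stage, k, seed)
  gfolds <- if (holdout == "genes_and_samples")
    plain_folds(ng, k, seed + 1L) else rep(0L, ng)
  s_all <- stage_indicator(work)
  pred_mat <- matrix(NA_real_, ng, ns, dimnames = list(genes, samples))
  rows <- vector("list", k)

  for (t in seq_len(k)) {
    te_s <- sfolds == t; tr_s <- !te_s
    if (length(unique(work$stage[te_s])) < 2L || length(unique(work$stage[tr_s])) < 2L)
      stopf("fold %d contains a single stage; reduce k or rebalance", t)
    if (holdout == "genes_and_samples") {
      te_g <- gfolds == t; tr_g <- !te_g
    } else {
      te_g <- rep(TRUE, ng); tr_g <- rep(TRUE, ng)
    }
    tr_map <- restrict_map(map, genes[tr_g])
    tr_ds <- subset_dataset(work, genes = genes[tr_g], samples = samples[tr_s],
                            min_per_stage = 1L)
    tfit <- if (model == "tf_only") fit_tf_only(tr_ds, tr_map)
            else fit_integrative(tr_ds, tr_map, method = "ols")
    ## TF shift for held-out genes (TFs dropped during restriction count 0)
    beta_tf_full <- stats::setNames(rep(0, length(map$tf_ids)), map$tf_ids)
    beta_tf_full[names(tfit$beta_tf)] <- tfit$beta_tf
    tshift_all <- as.numeric(Matrix::crossprod(map$incidence, beta_tf_full))
    names(tshift_all) <- genes

    te_genes <- genes[te_g]
    if (model == "tf_only") {
      pred <- outer(tshift_all[te_genes], s_all[te_s])
    } else {
      cf <- refit_gene_blocks(
        work$expression[te_genes, tr_s, drop = FALSE],
        work$cnv[te_genes, tr_s, drop = FALSE],
        work$methylation[te_genes, tr_s, drop = FALSE],
        s_all[tr_s], tshift_all[te_genes])
      pred <- work$cnv[te_genes, te_s, drop = FALSE] * cf$beta_cn +
        work$methylation[te_genes, te_s, drop = FALSE] * cf$beta_me +
        outer(tshift_all[te_genes], s_all[te_s])
    }
    pred_mat[te_genes, te_s] <- pred
    obs <- work$expression[te_genes, te_s, drop = FALSE]
    rho <- vapply(seq_along(te_genes),
                  function(i) spearman(pred[i, ], obs[i, ]), numeric(1))
    rows[[t]] <- data.frame(gene_id = te_genes, fold = t, spearman = rho,
                            stringsAsFactors = FALSE)
  }
  per_gene <- do.call(rbind, rows)
  rownames(per_gene) <- NULL
  res <- list(
    per_gene = per_gene,
    mean_spearman = mean(per_gene$spearman, na.rm = TRUE),
    median_spearman = stats::median(per_gene$spearman, na.rm = TRUE),
    n_na = sum(is.na(per_gene$spearman)),
    predicted = pred_mat,
    model = model, k = as.integer(k), seed = as.integer(seed),
    holdout = holdout,
    sample_folds = sfolds, gene_folds = gfolds
  )
  class(res) <- "CVReport"
  res
}

#' @export
print.CVReport <- function(x, ...) {
  cat(sprintf(
    "CVReport (%s, k = %d): mean Spearman = %.4f, median = %.4f (%d gene(s) NA)\n",
    x$model, x$k, x$mean_spearman, x$median_spearman, x$n_na))
  invisible(x)
}

#' Correlation of predicted with observed stage-dependent changes
#'
#' Per-gene predicted log2 fold change (mean predicted expression in stage
#' IV minus stage I, over the samples where a prediction exists) against
#' the observed log2 fold change, summarized by Spearman correlation over a
#' designated gene set.
#'
#' @param predicted genes x samples matrix of predictions (`NA` allowed),
#'   e.g. the `predicted` element of a [crossval()] report.
#' @param dataset the [omics_dataset()] the predictions refer to.
#' @param gene_set character vector of gene ids (>= 3).
#' @return list with `spearman`, `n_genes`, and the per-gene `predicted_fc`
#'   and `observed_fc` vectors.
#' @export
stage_change_correlation <- function(predicted, dataset, gene_set) {
  gene_set <- unique(gene_set)
  if (length(gene_set) < 3L)
    stopf("gene_set must contain at least 3 genes (got %d)", length(gene_set))
  missing <- setdiff(gene_set, rownames(predicted))
  if (length(missing))
    stopf("gene_set genes absent from predictions: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  iv <- dataset$stage == "IV"
  pred_fc <- rowMeans(predicted[gene_set, iv, drop = FALSE], na.rm = TRUE) -
    rowMeans(predicted[gene_set, !iv, drop = FALSE], na.rm = TRUE)
  obs_fc <- observed_log2_fc(dataset)[gene_set]
  ok <- is.finite(pred_fc) & is.finite(obs_fc)
  if (sum(ok) < 3L)
    stopf("fewer than 3 genes with both predicted and observed fold changes")
  list(spearman = spearman(pred_fc[ok], obs_fc[ok]),
       n_genes = sum(ok),
       predicted_fc = pred_fc, observed_fc = obs_fc)
}

#' Are a TF's targets more stage-shifted than non-targets?
#'
#' One-sided two-sample Kolmogorov-Smirnov test comparing per-gene
#' stage-dependent expression changes of a target set against all other
#' genes, testing whether targets are more changed. By default the absolute
#' log2 fold change is compared; `signed = TRUE` compares the signed fold
#' change instead (alternative: targets shifted upwards).
#'
#' @param dataset an [omics_dataset()] with stage labels.
#' @param target_set nonempty character vector of gene ids; must be a
#'   strict subset of the dataset's genes.
#' @param signed compare signed instead of absolute fold changes.
#' @return list with `statistic` (KS D), `p_value`, `n_targets`,
#'   `n_non_targets`.
#' @export
target_shift_test <- function(dataset, target_set, signed = FALSE) {
  target_set <- unique(target_set)
  if (!length(target_set)) stopf("target_set is empty")
  genes <- dataset_genes(dataset)
  unknown <- setdiff(target_set, genes)
  if (length(unknown))
    stopf("target_set contains unknown genes: %s",
          paste(utils::head(unknown, 5), collapse = ", "))
  if (length(target_set) >= length(genes))
    stopf("target_set must be a strict subset of the dataset's genes")
  lfc <- observed_log2_fc(dataset)
  vals <- if (signed) lfc else abs(lfc)
  in_set <- genes %in% target_set
  res <- ks_compare(vals[in_set], vals[!in_set], alternative = "greater")
  list(statistic = res$statistic, p_value = res$p_value,
       n_targets = sum(in_set), n_non_targets = sum(!in_set))
}
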