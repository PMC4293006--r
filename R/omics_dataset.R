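#' Matched multi-omics dataset
#'
#' Container for aligned genes-by-samples matrices of log2 mRNA expression,
#' linear copy-number estimates and methylation beta values, together with a
#' per-sample tumor stage label (`"I"` or `"IV"`). All three matrices share
#' identical gene (row) and sample (column) ordering; downstream model code
#' relies on this and on the absence of missing values.
#'
#' @param expression,cnv,methylation numeric matrices, genes x samples, with
#'   identical `dimnames`. Expression is on the log2 scale; methylation values
#'   must lie in `[0, 1]`.
#' @param stage character or factor of per-sample stage labels (`"I"`/`"IV"`),
#'   either named by sample or in column order.
#' @param min_per_stage minimum number of samples required in each stage
#'   (default 2; fold changes and two-group tests are undefined below that).
#' @return an object of class `OmicsDataset`: a list with elements
#'   `expression`, `cnv`, `methylation` (matrices) and `stage`
#'   (factor with levels `I`, `IV`, named by sample).
#' @export
omics_dataset <- function(expression, cnv, methylation, stage,
                          min_per_stage = 2L) {
  mats <- list(expression = expression, cnv = cnv, methylation = methylation)
  for (nm in names(mats)) {
    m <- mats[[nm]]
    if (!is.matrix(m) || !is.numeric(m))
      stopf("'%s' must be a numeric matrix", nm)
    if (is.null(rownames(m)) || is.null(colnames(m)))
      stopf("'%s' must have gene rownames and sample colnames", nm)
    if (anyNA(m)) stopf("'%s' contains missing values", nm)
  }
  ref <- mats$expression
  for (nm in c("cnv", "methylation")) {
    if (!identical(dimnames(mats[[nm]]), dimnames(ref)))
      stopf("'%s' gene/sample labels differ from 'expression'", nm)
  }
  if (anyDuplicated(rownames(ref))) stopf("duplicate gene ids")
  if (anyDuplicated(colnames(ref))) stopf("duplicate sample ids")
  rng <- range(methylation)
  if (rng[1] < 0 || rng[2] > 1)
    stopf("methylation values must lie in [0, 1] (found range [%g, %g])",
          rng[1], rng[2])
  samples <- colnames(ref)
  if (!is.null(names(stage))) {
    if (!all(samples %in% names(stage)))
      stopf("stage labels missing for samples: %s",
            paste(utils::head(setdiff(samples, names(stage)), 5), collapse = ", "))
    stage <- stage[samples]
  } else if (length(stage) != length(samples)) {
    stopf("stage has length %d but there are %d samples",
          length(stage), length(samples))
  }
  stage <- factor(as.character(stage), levels = c("I", "IV"))
  if (anyNA(stage)) stopf("stage labels must be 'I' or 'IV'")
  names(stage) <- samples
  tab <- table(stage)
  if (any(tab < min_per_stage))
    stopf("need at least %d samples per stage (got I=%d, IV=%d)",
          min_per_stage, tab[["I"]], tab[["IV"]])
  structure(
    list(expression = expression, cnv = cnv, methylation = methylation,
         stage = stage),
    class = "OmicsDataset"
  )
}

#' @export
print.OmicsDataset <- function(x, ...) {
  tab <- table(x$stage)
  cat(sprintf(
    "OmicsDataset: %d genes x %d samples (stage I: %d, stage IV: %d)\n",
    nrow(x$expression), ncol(x$expression), tab[["I"]], tab[["IV"]]))
  invisible(x)
}

#' @export
dim.OmicsDataset <- function(x) dim(x$expression)

#' Gene and sample identifiers of a dataset
#' @param dataset an [omics_dataset()].
#' @return character vector of identifiers, in storage order.
#' @export
dataset_genes <- function(dataset) rownames(dataset$expression)

#' @rdname dataset_genes
#' @export
dataset_samples <- function(dataset) colnames(dataset$expression)

#' Stage-IV indicator vector (S_j)
#' @param dataset an [omics_dataset()].
#' @return numeric 0/1 vector over samples, 1 for stage IV.
#' @export
stage_indicator <- function(dataset) {
  s <- as.numeric(dataset$stage == "IV")
  names(s) <- names(dataset$stage)
  s
}

#' Subset a dataset by genes and/or samples
#'
#' @param dataset an [omics_dataset()].
#' @param genes,samples character vectors of identifiers, or indices; `NULL`
#'   keeps all. Order of the result follows the selection.
#' @param min_per_stage passed through to validation (use 0 to allow
#'   single-stage subsets, e.g. when slicing folds).
#' @return a new `OmicsDataset`.
#' @export
subset_dataset <- function(dataset, genes = NULL, samples = NULL,
                           min_per_stage = 0L) {
  g <- if (is.null(genes)) rownames(dataset$expression) else genes
  s <- if (is.null(samples)) colnames(dataset$expression) else samples
  out <- list(
    expression = dataset$expression[g, s, drop = FALSE],
    cnv = dataset$cnv[g, s, drop = FALSE],
    methylation = dataset$methylation[g, s, drop = FALSE],
    stage = dataset$stage[if (is.character(s)) s else colnames(dataset$expression)[s]]
  )
  omics_dataset(out$expression, out$cnv, out$methylation, out$stage,
                min_per_stage = min_per_stage)
}

## per-gene mean difference of a matrix between stage IV and stage I samples
stage_shift <- function(mat, stage) {
  iv <- stage == "IV"
  rowMeans(mat[, iv, drop = FALSE]) - rowMeans(mat[, !iv, drop = FALSE])
}

#' Per-gene observed log2 fold change (stage IV minus stage I)
#' @param dataset an [omics_dataset()].
#' @return named numeric vector over genes.
#' @export
observed_log2_fc <- function(dataset) {
  stage_shift(dataset$expression, dataset$stage)
}
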