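#' Per-gene correlation between an omics layer and expression
#'
#' Pearson correlation of each gene's copy-number (or methylation) profile
#' with its expression profile across all samples pooled; two-sided p-value
#' from the t transform `t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of
#' freedom. Genes with zero variance in either vector are marked undefined
#' (`NA`) rather than raising an error, and are excluded from summaries.
#'
#' @param dataset an [omics_dataset()] with at least 3 samples.
#' @param layer `"cnv"` or `"methylation"`.
#' @return a `data.frame` of class `CorrelationProfile` with columns
#'   `gene_id`, `r`, `p_value`, `defined`, and attribute `layer`.
#' @export
per_gene_correlation <- function(dataset, layer = c("cnv", "methylation")) {
  layer <- match.arg(layer)
  x <- dataset[[layer]]
  y <- dataset$expression
  n <- ncol(y)
  if (n < 3L) stopf("need >= 3 samples for correlation")
  xc <- x - rowMeans(x)
  yc <- y - rowMeans(y)
  sxx <- rowSums(xc^2)
  syy <- rowSums(yc^2)
  sxy <- rowSums(xc * yc)
  defined <- sxx > 0 & syy > 0
  r <- rep(NA_real_, nrow(y))
  r[defined] <- sxy[defined] / sqrt(sxx[defined] * syy[defined])
  r <- pmin(1, pmax(-1, r))
  tval <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  p[!defined] <- NA_real_
  out <- data.frame(gene_id = rownames(y), r = unname(r),
                    p_value = unname(p), defined = unname(defined),
                    stringsAsFactors = FALSE)
  class(out) <- c("CorrelationProfile", "data.frame")
  attr(out, "layer") <- layer
  attr(out, "n_samples") <- n
  out
}

#' Summarize a correlation profile
#'
#' Counts and fractions of positively and negatively correlated genes, and
#' of those with significant correlations (`p < alpha`), over the genes with
#' a defined correlation. Fractions are relative to the number of evaluated
#' genes.
#'
#' @param profile a [per_gene_correlation()] result.
#' @param alpha significance level in (0, 1); default 0.01.
#' @return list of class `CorrelationSummary` with `n_genes`, `median_r`,
#'   and counts/fractions `positive`, `positive_significant`, `negative`,
#'   `negative_significant`, `zero`.
#' @export
summarize_correlations <- function(profile, alpha = 0.01) {
  stopifnot(alpha > 0, alpha < 1)
  ok <- profile$defined
  if (!any(ok)) stopf("all genes have undefined correlations")
  r <- profile$r[ok]
  p <- profile$p_value[ok]
  n <- length(r)
  cnt <- function(mask) c(count = sum(mask), fraction = sum(mask) / n)
  out <- list(
    n_genes = n,
    median_r = stats::median(r),
    positive = cnt(r > 0),
    positive_significant = cnt(r > 0 & p < alpha),
    negative = cnt(r < 0),
    negative_significant = cnt(r < 0 & p < alpha),
    zero = cnt(r == 0),
    alpha = alpha,
    layer = attr(profile, "layer")
  )
  class(out) <- "CorrelationSummary"
  out
}

#' @export
print.CorrelationSummary <- function(x, ...) {
  cat(sprintf("CorrelationSummary (%s): %d genes, median r = %.3f\n",
              x$layer %||% "?", x$n_genes, x$median_r))
  cat(sprintf("  positive: %d (%.1f%%), significant at alpha=%g: %d (%.1f%%)\n",
              x$positive["count"], 100 * x$positive["fraction"], x$alpha,
              x$positive_significant["count"],
              100 * x$positive_significant["fraction"]))
  cat(sprintf("  negative: %d (%.1f%%), significant: %d (%.1f%%)\n",
              x$negative["count"], 100 * x$negative["fraction"],
              x$negative_significant["count"],
              100 * x$negative_significant["fraction"]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare correlation distributions of a gene set against its complement
#'
#' Two-sample Kolmogorov-Smirnov test between the correlation values of a
#' gene set and those of its complement within the profile. One-sided
#' alternatives follow set semantics: `"less"` means the set's values tend
#' to be smaller than the complement's, `"greater"` the opposite.
#'
#' @param profile a [per_gene_correlation()] result (or any data.frame with
#'   `gene_id`, `r` and `defined` columns).
#' @param gene_set character vector of gene ids; must be nonempty and a
#'   strict subset of the profile's genes.
#' @param alternative `"two_sided"`, `"less"` or `"greater"`.
#' @return list with `statistic` (KS D), `p_value`, `alternative`,
#'   `n_set`, `n_complement`.
#' @export
compare_distributions <- function(profile, gene_set,
                                  alternative = c("two_sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  gene_set <- unique(gene_set)
  if (!length(gene_set)) stopf("gene_set is empty")
  unknown <- setdiff(gene_set, profile$gene_id)
  if (length(unknown))
    stopf("gene_set contains genes absent from the profile: %s",
          paste(utils::head(unknown, 5), collapse = ", "))
  in_set <- profile$gene_id %in% gene_set
  if (all(in_set)) stopf("gene_set must be a strict subset of the profile")
  ok <- profile$defined
  x <- profile$r[in_set & ok]
  y <- profile$r[!in_set & ok]
  res <- ks_compare(x, y, alternative)
  res$n_set <- length(x)
  res$n_complement <- length(y)
  res
}
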