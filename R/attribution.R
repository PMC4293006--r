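#' Attribute a gene's stage-dependent alteration to mechanisms
#'
#' For each differentially expressed gene, decides which of the three
#' modeled mechanisms can explain its stage-dependent expression change:
#'
#' * `explained_by_cnv`: the gene's copy-number coefficient is individually
#'   significant (`p < coef_alpha`), the coefficient times the observed
#'   stage shift of its copy number (mean IV minus mean I) has the same
#'   sign as the gene's log2 fold change, and that contribution exceeds
#'   `min_contribution` in absolute value.
#' * `explained_by_methylation`: symmetric, with the methylation
#'   coefficient and methylation stage shift.
#' * `explained_by_tf`: at least one selected TF (see
#'   [infer_tf_activity()]) binds the gene with `sign(beta_f)` equal to the
#'   sign of the gene's log2 fold change; those TFs are listed as
#'   supporting TFs.
#'
#' A gene with no mechanism flagged is `unexplained`.
#'
#' @param fit an OLS integrative `ModelFit` (needs per-gene standard
#'   errors).
#' @param tf_table a [infer_tf_activity()] table.
#' @param de a [de_test()] result.
#' @param dataset the [omics_dataset()] the fit was computed on.
#' @param map the [tf_target_map()] used in the fit.
#' @param genes genes to attribute; defaults to all DE genes
#'   (`status != "ns"`). Each must be present in the fit.
#' @param coef_alpha per-gene coefficient significance level (default 0.01).
#' @param min_contribution minimum absolute contribution
#'   (`|beta x stage shift|`, log2 units) for a covariate mechanism to
#'   count (default 0.25); guards against sign flags driven by noise-level
#'   covariate shifts.
#' @return `data.frame` of class `AttributionResult`: one row per gene with
#'   flags, supporting TFs (`/`-separated) and the `unexplained` flag.
#' @export
attribute_genes <- function(fit, tf_table, de, dataset, map, genes = NULL,
                            coef_alpha = 0.01, min_contribution = 0.25) {
  if (is.null(fit$se_cn))
    stopf("attribution requires an OLS integrative fit with standard errors")
  if (is.null(genes)) genes <- de$gene_id[de$status != "ns"]
  if (!length(genes)) stopf("no differentially expressed genes to attribute")
  missing <- setdiff(genes, fit$genes)
  if (length(missing))
    stopf("gene(s) absent from fit: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  lfc <- stats::setNames(de$log2_fc, de$gene_id)[genes]
  dir <- sign(lfc)

  cnv_shift <- stage_shift(dataset$cnv, dataset$stage)[genes]
  meth_shift <- stage_shift(dataset$methylation, dataset$stage)[genes]
  b_cn <- fit$beta_cn[genes]; se_cn <- fit$se_cn[genes]
  b_me <- fit$beta_me[genes]; se_me <- fit$se_me[genes]
  p_cn <- 2 * stats::pnorm(-abs(b_cn / pmax(se_cn, .Machine$double.xmin)))
  p_me <- 2 * stats::pnorm(-abs(b_me / pmax(se_me, .Machine$double.xmin)))
  contrib_cn <- b_cn * cnv_shift
  contrib_me <- b_me * meth_shift
  by_cnv <- p_cn < coef_alpha & sign(contrib_cn) == dir &
    abs(contrib_cn) > min_contribution
  by_meth <- p_me < coef_alpha & sign(contrib_me) == dir &
    abs(contrib_me) > min_contribution

  sel <- tf_table[tf_table$selected, , drop = FALSE]
  support <- character(length(genes))
  by_tf <- logical(length(genes))
  if (nrow(sel)) {
    sel_beta <- stats::setNames(sel$beta, sel$tf)
    inc <- map$incidence[sel$tf, , drop = FALSE]
    for (gi in seq_along(genes)) {
      bound <- sel$tf[inc[, genes[gi]] != 0]
      match_sign <- bound[sign(sel_beta[bound]) == dir[gi]]
      if (length(match_sign)) {
        by_tf[gi] <- TRUE
        support[gi] <- paste(match_sign, collapse = "/")
      }
    }
  }
  out <- data.frame(
    gene_id = genes, log2_fc = unname(lfc),
    explained_by_cnv = unname(by_cnv),
    explained_by_methylation = unname(by_meth),
    explained_by_tf = by_tf,
    supporting_tfs = support,
    unexplained = !(unname(by_cnv) | unname(by_meth) | by_tf),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("AttributionResult", "data.frame")
  attr(out, "thresholds") <- c(coef_alpha = coef_alpha,
                               min_contribution = min_contribution)
  out
}

#' Attribute a single gene
#' @inheritParams attribute_genes
#' @param gene a single gene id (must be differentially expressed and in
#'   the fit).
#' @return one-row `AttributionResult`.
#' @export
attribute_gene <- function(gene, fit, tf_table, de, dataset, map,
                           coef_alpha = 0.01, min_contribution = 0.25) {
  stopifnot(length(gene) == 1L)
  st <- de$status[match(gene, de$gene_id)]
  if (is.na(st)) stopf("gene '%s' not present in the DE result", gene)
  if (st == "ns")
    stopf("gene '%s' is not differentially expressed (status 'ns')", gene)
  attribute_genes(fit, tf_table, de, dataset, map, genes = gene,
                  coef_alpha = coef_alpha, min_contribution = min_contribution)
}

#' Venn summary of attribution records
#'
#' Counts of genes in each of the seven regions of the CNV / methylation /
#' TF Venn diagram, plus the unexplained count and the fraction explained.
#'
#' @param records an [attribute_genes()] result.
#' @return list with `regions` (named integer vector: `cnv_only`,
#'   `meth_only`, `tf_only`, `cnv_meth`, `cnv_tf`, `meth_tf`,
#'   `cnv_meth_tf`), `unexplained`, `n_total`, `n_explained`,
#'   `fraction_explained`.
#' @export
attribution_summary <- function(records) {
  if (!nrow(records)) stopf("no attribution records")
  c_ <- records$explained_by_cnv
  m_ <- records$explained_by_methylation
  t_ <- records$explained_by_tf
  regions <- c(
    cnv_only     = sum(c_ & !m_ & !t_),
    meth_only    = sum(!c_ & m_ & !t_),
    tf_only      = sum(!c_ & !m_ & t_),
    cnv_meth     = sum(c_ & m_ & !t_),
    cnv_tf       = sum(c_ & !m_ & t_),
    meth_tf      = sum(!c_ & m_ & t_),
    cnv_meth_tf  = sum(c_ & m_ & t_)
  )
  n_total <- nrow(records)
  n_expl <- sum(!records$unexplained)
  list(regions = regions,
       unexplained = n_total - n_expl,
       n_total = n_total,
       n_explained = n_expl,
       fraction_explained = n_expl / n_total)
}
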