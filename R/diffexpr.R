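#' Stage-dependent differential expression
#'
#' Per-gene two-group comparison of log2 expression between stage IV and
#' stage I samples: log2 fold change (mean IV minus mean I), pooled-variance
#' two-sample t statistic, two-sided p-value on `n - 2` degrees of freedom,
#' and Benjamini-Hochberg FDR across all tested genes. A gene is called
#' `up` when `log2_fc > log2(fc_threshold)` and `fdr < fdr_threshold`
#' (strict inequalities), `down` symmetrically, otherwise `ns`.
#'
#' Degenerate genes with zero variance in both groups and zero fold change
#' are assigned `t = 0`, `p = 1` and counted in a message; zero pooled
#' variance with a nonzero fold change yields an infinite statistic and
#' `p = 0`.
#'
#' @param dataset an [omics_dataset()] with at least two samples per stage.
#' @param fc_threshold linear fold-change threshold used for the status call
#'   (default 2, i.e. `|log2 FC| > 1`).
#' @param fdr_threshold FDR threshold for the status call (default 0.001).
#' @return a `data.frame` of class `DEResult` with columns `gene_id`,
#'   `log2_fc`, `t_stat`, `p_value`, `fdr`, `status`.
#' @export
de_test <- function(dataset, fc_threshold = 2, fdr_threshold = 0.001) {
  stage <- dataset$stage
  iv <- stage == "IV"
  n1 <- sum(!iv); n2 <- sum(iv)
  if (n1 < 2L || n2 < 2L) stopf("need >= 2 samples per stage")
  x1 <- dataset$expression[, !iv, drop = FALSE]
  x2 <- dataset$expression[, iv, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  lfc <- m2 - m1
  ss1 <- rowSums((x1 - m1)^2)
  ss2 <- rowSums((x2 - m2)^2)
  df <- n1 + n2 - 2L
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t_stat <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
  p <- ifelse(is.finite(t_stat),
              2 * stats::pt(-abs(t_stat), df = df),
              0)
  p[se == 0 & lfc == 0] <- 1
  n_degen <- sum(se == 0)
  if (n_degen > 0)
    message(sprintf("de_test: %d gene(s) with zero pooled variance", n_degen))
  fdr <- bh_adjust(p)
  lt <- log2(fc_threshold)
  status <- rep("ns", length(lfc))
  status[lfc > lt & fdr < fdr_threshold] <- "up"
  status[lfc < -lt & fdr < fdr_threshold] <- "down"
  out <- data.frame(gene_id = rownames(dataset$expression),
                    log2_fc = unname(lfc), t_stat = unname(t_stat),
                    p_value = unname(p), fdr = unname(fdr),
                    status = status, stringsAsFactors = FALSE)
  class(out) <- c("DEResult", "data.frame")
  attr(out, "thresholds") <- c(fc = fc_threshold, fdr = fdr_threshold)
  out
}

#' Select up- and down-regulated gene sets
#'
#' Applies the fold-change and FDR filter (strict inequalities on both) to a
#' [de_test()] result, independently of the status column stored there.
#'
#' @param result a `DEResult` from [de_test()].
#' @param fc_threshold linear fold-change threshold (> 0); a gene is up when
#'   `log2_fc > log2(fc_threshold)`.
#' @param fdr_threshold FDR threshold (> 0).
#' @return list with character vectors `up` and `down`.
#' @export
filter_de <- function(result, fc_threshold = 2, fdr_threshold = 0.001) {
  stopifnot(fc_threshold > 0, fdr_threshold > 0)
  lt <- log2(fc_threshold)
  up <- result$gene_id[result$log2_fc > lt & result$fdr < fdr_threshold]
  down <- result$gene_id[result$log2_fc < -lt & result$fdr < fdr_threshold]
  list(up = up, down = down)
}
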