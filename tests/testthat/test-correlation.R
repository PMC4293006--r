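make_corr_dataset <- function(expr, cnv = NULL, meth = NULL, stage = NULL) {
  ns <- ncol(expr)
  if (is.null(cnv)) cnv <- matrix(2, nrow(expr), ns, dimnames = dimnames(expr))
  if (is.null(meth)) meth <- matrix(0.5, nrow(expr), ns, dimnames = dimnames(expr))
  if (is.null(stage)) stage <- rep(c("I", "IV"), length.out = ns)
  omics_dataset(expr, cnv, meth, stage, min_per_stage = 1L)
}

test_that("per-gene Pearson r matches identities and the direct formula", {
  set.seed(1)
  x <- rnorm(6)
  expr <- rbind(ident = x, anti = -x + 3, toy = c(2, 4, 1, 5, 3, 6))
  colnames(expr) <- paste0("s", 1:6)
  cnv <- rbind(ident = x, anti = x, toy = c(1, 2, 3, 4, 5, 6))
  dimnames(cnv) <- dimnames(expr)
  meth <- (cnv - min(cnv)) / diff(range(cnv))
  ds <- make_corr_dataset(expr, cnv, meth)
  prof <- per_gene_correlation(ds, "cnv")
  r <- setNames(prof$r, prof$gene_id)
  expect_equal(r[["ident"]], 1)
  ## expression = -methylation + const -> r = -1 on the methylation layer
  prof_m <- per_gene_correlation(ds, "methylation")
  expect_equal(setNames(prof_m$r, prof_m$gene_id)[["anti"]], -1)
  ## direct covariance / (sd sd) oracle on the 6-sample toy
  a <- expr["toy", ]; b <- cnv["toy", ]
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(r[["toy"]], oracle)
  ## p-value via the t transform
  n <- 6
  tv <- oracle * sqrt((n - 2) / (1 - oracle^2))
  expect_equal(prof$p_value[prof$gene_id == "toy"], 2 * pt(-abs(tv), n - 2))
})

test_that("correlation is affine-invariant and sign-flips under negation", {
  set.seed(2)
  expr <- rand_mat(20, 12)
  cnv <- rand_mat(20, 12); dimnames(cnv) <- dimnames(expr)
  meth <- matrix(runif(240), 20, 12, dimnames = dimnames(expr))
  ds <- make_corr_dataset(expr, cnv, meth)
  base <- per_gene_correlation(ds, "cnv")$r
  ds2 <- make_corr_dataset(3 * expr + 7, cnv, meth)
  expect_equal(per_gene_correlation(ds2, "cnv")$r, base)
  ds3 <- make_corr_dataset(-2 * expr + 1, cnv, meth)
  expect_equal(per_gene_correlation(ds3, "cnv")$r, -base)
})

test_that("constant vectors are marked undefined, not errors", {
  expr <- rbind(flat = rep(1, 5), ok = c(1, 2, 3, 4, 5))
  colnames(expr) <- paste0("s", 1:5)
  cnv <- rbind(flat = 1:5, ok = c(2, 1, 4, 3, 5))
  dimnames(cnv) <- dimnames(expr)
  ds <- make_corr_dataset(expr, cnv)
  prof <- per_gene_correlation(ds, "cnv")
  expect_false(prof$defined[prof$gene_id == "flat"])
  expect_true(is.na(prof$r[prof$gene_id == "flat"]))
  summ <- summarize_correlations(prof)
  expect_equal(summ$n_genes, 1L)
})

test_that("summaries count and partition correctly", {
  prof <- data.frame(gene_id = c("a", "b", "c"),
                     r = c(0.5, 0.5, -0.5),
                     p_value = c(0.001, 0.5, 0.002), defined = TRUE)
  s <- summarize_correlations(prof, alpha = 0.01)
  expect_equal(unname(s$positive["count"]), 2)
  expect_equal(unname(s$positive["fraction"]), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(s$positive_significant["count"]), 1)
  expect_equal(unname(s$negative["count"]), 1)
  ## partition property on random profiles
  set.seed(9)
  prof2 <- data.frame(gene_id = sprintf("g%03d", 1:200),
                      r = runif(200, -1, 1), p_value = runif(200),
                      defined = TRUE)
  s2 <- summarize_correlations(prof2)
  expect_equal(unname(s2$positive["count"] + s2$negative["count"] +
                        s2$zero["count"]), 200)
})

test_that("null gene correlations are significant at about the alpha rate", {
  set.seed(10)
  expr <- rand_mat(1000, 50)
  cnv <- rand_mat(1000, 50); dimnames(cnv) <- dimnames(expr)
  meth <- matrix(runif(50000), 1000, 50, dimnames = dimnames(expr))
  ds <- make_corr_dataset(expr, cnv, meth)
  prof <- per_gene_correlation(ds, "cnv")
  s <- summarize_correlations(prof, alpha = 0.01)
  frac_sig <- unname(s$positive_significant["fraction"] +
                       s$negative_significant["fraction"])
  ## binomial(1000, 0.01): nearly always within [0, 0.025]
  expect_lt(frac_sig, 0.025)
})

test_that("KS distribution comparison matches the brute-force CDF oracle", {
  x <- c(0.1, 0.4, 0.43, 0.9, 0.7)
  y <- c(0.2, 0.35, 0.6, 0.61, 0.5)
  prof <- data.frame(gene_id = sprintf("g%02d", 1:10), r = c(x, y),
                     p_value = 0.5, defined = TRUE)
  res <- compare_distributions(prof, sprintf("g%02d", 1:5), "two_sided")
  expect_equal(res$statistic, ks_d_oracle(x, y))
  ## symmetry of the two-sided statistic in the two samples
  res_flip <- compare_distributions(prof, sprintf("g%02d", 6:10), "two_sided")
  expect_equal(res$statistic, res_flip$statistic)
  expect_equal(res$p_value, res_flip$p_value)
})

test_that("one-sided KS detects a downward-shifted gene set", {
  set.seed(12)
  r_all <- c(rnorm(100, -0.5, 0.3), rnorm(1000, 0, 0.3))
  prof <- data.frame(gene_id = sprintf("g%04d", seq_along(r_all)), r = r_all,
                     p_value = 0.5, defined = TRUE)
  shifted <- sprintf("g%04d", 1:100)
  res <- compare_distributions(prof, shifted, alternative = "less")
  expect_lt(res$p_value, 0.01)
  ## same-distribution null: small D, large p
  null_set <- sprintf("g%04d", sample(101:1100, 100))
  res0 <- compare_distributions(prof, null_set, alternative = "two_sided")
  expect_gt(res0$p_value, 0.01)
  expect_lt(res0$statistic, 0.25)
})

test_that("gene sets covering the whole profile are rejected", {
  prof <- data.frame(gene_id = c("a", "b"), r = c(0.1, 0.2),
                     p_value = 0.5, defined = TRUE)
  expect_error(compare_distributions(prof, c("a", "b")), "strict subset")
  expect_error(compare_distributions(prof, character(0)), "empty")
})
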