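## scenario with disjoint planted mechanisms: genes driven by a CNV stage
## shift, genes driven by a methylation stage shift, and genes driven by
## active TFs; strong effects, low noise
attribution_sim <- function(seed = 1, noise = 0.2) {
  simulate_dataset(simulation_params(
    n_genes = 300, n_samples = 120, n_tfs = 12, targets_per_tf = 120,
    min_tfs_per_gene = 1,
    beta_cn_dist = c(1.2, 0.1), beta_me_dist = c(-2.0, 0.2),
    n_active_tfs = 2, active_beta_magnitude = 1.5, noise_sd = noise,
    n_cnv_shift_genes = 25, cnv_shift = 1.2,
    n_meth_shift_genes = 25, meth_shift = 0.55, seed = seed))
}

fit_and_attribute <- function(sim, de_fdr = 0.01) {
  fit <- fit_integrative(sim$dataset, sim$map)
  tf_tab <- infer_tf_activity(fit)
  de <- de_test(sim$dataset, fc_threshold = 2, fdr_threshold = de_fdr)
  list(fit = fit, tf_tab = tf_tab, de = de,
       rec = attribute_genes(fit, tf_tab, de, sim$dataset, sim$map))
}

test_that("planted single mechanisms are attributed to the right factor", {
  sim <- attribution_sim(seed = 21)
  out <- fit_and_attribute(sim)
  rec <- out$rec
  ## genes whose alteration was generated purely by a CNV shift and that are
  ## not bound by any active TF with a matching sign
  active <- sim$truth$active_tfs
  inc <- as.matrix(sim$map$incidence)
  tf_contrib <- as.numeric(crossprod(inc, sim$truth$beta_tf))
  names(tf_contrib) <- sim$map$gene_ids

  pure_cnv <- setdiff(sim$truth$cnv_shift_genes,
                      c(sim$truth$meth_shift_genes,
                        names(tf_contrib)[abs(tf_contrib) > 0.25]))
  pure_cnv <- intersect(pure_cnv, rec$gene_id)
  expect_gt(length(pure_cnv), 5)
  sub <- rec[rec$gene_id %in% pure_cnv, ]
  expect_gt(mean(sub$explained_by_cnv & !sub$explained_by_methylation), 0.9)

  ## genes driven purely by an active TF get that TF listed
  pure_tf <- setdiff(names(tf_contrib)[abs(tf_contrib) > 1],
                     c(sim$truth$cnv_shift_genes, sim$truth$meth_shift_genes))
  pure_tf <- intersect(pure_tf, rec$gene_id)
  expect_gt(length(pure_tf), 5)
  sub_tf <- rec[rec$gene_id %in% pure_tf, ]
  expect_gt(mean(sub_tf$explained_by_tf), 0.9)
  expect_true(all(nzchar(sub_tf$supporting_tfs[sub_tf$explained_by_tf])))
  listed <- unique(unlist(strsplit(sub_tf$supporting_tfs, "/")))
  expect_true(all(listed %in% active))
})

test_that("a DE gene without a planted mechanism comes out unexplained", {
  ## no active TFs, no covariate stage shifts: inject a spurious expression
  ## shift for one gene directly (a 'forced' DE gene)
  sim <- simulate_dataset(simulation_params(
    n_genes = 100, n_samples = 80, n_tfs = 6, targets_per_tf = 60,
    min_tfs_per_gene = 1, n_active_tfs = 0, noise_sd = 0.2, seed = 22))
  expr <- sim$dataset$expression
  g <- dataset_genes(sim$dataset)[1]
  iv <- sim$dataset$stage == "IV"
  expr[g, iv] <- expr[g, iv] + 1.5
  ds <- omics_dataset(expr, sim$dataset$cnv, sim$dataset$methylation,
                      sim$dataset$stage)
  fit <- fit_integrative(ds, sim$map)
  tf_tab <- infer_tf_activity(fit)
  de <- de_test(ds)
  expect_identical(de$status[de$gene_id == g], "up")
  rec <- attribute_gene(g, fit, tf_tab, de, ds, sim$map)
  expect_true(rec$unexplained)
  ## non-DE genes are refused
  ns_gene <- de$gene_id[de$status == "ns"][1]
  expect_error(attribute_gene(ns_gene, fit, tf_tab, de, ds, sim$map), "ns")
})

test_that("Venn summary counts match brute-force set algebra", {
  rec <- data.frame(
    gene_id = c("a", "b", "c"),
    explained_by_cnv = c(TRUE, FALSE, TRUE),
    explained_by_methylation = c(FALSE, FALSE, FALSE),
    explained_by_tf = c(FALSE, TRUE, TRUE))
  rec$unexplained <- !(rec$explained_by_cnv | rec$explained_by_methylation |
                         rec$explained_by_tf)
  s <- attribution_summary(rec)
  expect_equal(unname(s$regions[c("cnv_only", "tf_only", "cnv_tf")]),
               c(1L, 1L, 1L))
  expect_equal(sum(s$regions), 3)
  expect_equal(s$fraction_explained, 1)

  ## all-unexplained degenerate case
  rec0 <- rec
  rec0[c("explained_by_cnv", "explained_by_methylation", "explained_by_tf")] <- FALSE
  rec0$unexplained <- TRUE
  expect_equal(attribution_summary(rec0)$fraction_explained, 0)

  ## 200 random records: regions equal brute-force enumeration and
  ## partition the explained genes
  set.seed(23)
  rnd <- data.frame(gene_id = sprintf("g%03d", 1:200),
                    explained_by_cnv = runif(200) < 0.4,
                    explained_by_methylation = runif(200) < 0.4,
                    explained_by_tf = runif(200) < 0.4)
  rnd$unexplained <- !(rnd$explained_by_cnv | rnd$explained_by_methylation |
                         rnd$explained_by_tf)
  s2 <- attribution_summary(rnd)
  key <- paste0(rnd$explained_by_cnv + 0, rnd$explained_by_methylation + 0,
                rnd$explained_by_tf + 0)
  brute <- c(cnv_only = sum(key == "100"), meth_only = sum(key == "010"),
             tf_only = sum(key == "001"), cnv_meth = sum(key == "110"),
             cnv_tf = sum(key == "101"), meth_tf = sum(key == "011"),
             cnv_meth_tf = sum(key == "111"))
  expect_equal(s2$regions[names(brute)], brute)
  expect_equal(sum(s2$regions), s2$n_explained)
  expect_equal(s2$n_explained + s2$unexplained, s2$n_total)
})
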