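test_that("design dimensions and nonzero pattern follow the contract", {
  sim <- tiny_sim(seed = 2, ng = 3, ns = 4, nf = 2, noise = 0.1)
  spec <- build_design(sim$dataset, sim$map)
  expect_equal(spec$n_obs, 12L)
  expect_equal(spec$n_coef, 2L + 2L * 3L)
  X <- design_matrix(spec)
  expect_s4_class(X, "dgCMatrix")
  ## brute-force enumeration of the TF-block nonzero pattern:
  ## entry (obs(i,j), tf f) is nonzero iff B_fi * S_j = 1
  B <- as.matrix(sim$map$incidence)
  s <- stage_indicator(sim$dataset)
  ng <- 3
  tf_block <- as.matrix(X[, 2 * ng + seq_len(2), drop = FALSE])
  for (i in 1:3) for (j in 1:4) for (f in 1:2) {
    expect_equal(unname(tf_block[(j - 1) * ng + i, f]),
                 unname(B[f, i] * s[[j]]))
  }
  ## CNV / methylation values land in their gene's column
  expect_equal(unname(X[(2 - 1) * ng + 1, 1]), sim$dataset$cnv[1, 2])
  expect_equal(unname(X[(3 - 1) * ng + 2, ng + 2]),
               sim$dataset$methylation[2, 3])
  ## stage-I rows carry zero TF entries even for bound genes
  stage1 <- which(s == 0)[1]
  expect_true(all(tf_block[(stage1 - 1) * ng + seq_len(ng), ] == 0))
})

test_that("design rejects genes missing from the TF map", {
  sim <- tiny_sim(seed = 2, ng = 10, ns = 6, nf = 3)
  map_small <- restrict_map(sim$map, dataset_genes(sim$dataset)[1:8])
  expect_error(build_design(sim$dataset, map_small), "filter first")
})

test_that("structured OLS equals the dense least-squares oracle", {
  set.seed(100)
  for (seed in 1:6) {
    ng <- sample(10:50, 1)
    sim <- simulate_dataset(simulation_params(
      n_genes = ng, n_samples = sample(8:20, 1),
      n_tfs = sample(3:10, 1), targets_per_tf = ceiling(0.6 * ng),
      min_tfs_per_gene = 1, n_active_tfs = 2, noise_sd = 0.3, seed = seed))
    fit <- fit_integrative(sim$dataset, sim$map)
    oracle <- dense_fit_oracle(sim$dataset, sim$map)
    expect_lt(max(abs(fit$beta_cn - oracle$beta_cn)), 1e-8)
    expect_lt(max(abs(fit$beta_me - oracle$beta_me)), 1e-8)
    expect_lt(max(abs(fit$beta_tf - oracle$beta_tf)), 1e-8)
  }
})

test_that("OLS residuals are orthogonal to every design column", {
  sim <- tiny_sim(seed = 13, ng = 25, ns = 14, nf = 5)
  fit <- fit_integrative(sim$dataset, sim$map)
  spec <- build_design(sim$dataset, sim$map)
  X <- design_matrix(spec)
  xtr <- as.numeric(Matrix::crossprod(X, as.vector(fit$residuals)))
  expect_lt(max(abs(xtr)), 1e-6)
})

test_that("noiseless synthetic data is recovered exactly", {
  sim <- tiny_sim(seed = 5, ng = 40, ns = 24, nf = 6, noise = 0)
  fit <- fit_integrative(sim$dataset, sim$map)
  expect_lt(max(abs(fit$beta_cn - sim$truth$beta_cn)), 1e-8)
  expect_lt(max(abs(fit$beta_me - sim$truth$beta_me)), 1e-8)
  expect_lt(max(abs(fit$beta_tf - sim$truth$beta_tf)), 1e-8)
  expect_lt(fit$sse, 1e-16)
})

test_that("ridge shrinks the coefficient norm monotonically to zero", {
  sim <- tiny_sim(seed = 6, ng = 20, ns = 12, nf = 4)
  lambdas <- c(0, 1, 10, 100, 1e4, 1e6)
  norms <- vapply(lambdas, function(lam) {
    f <- fit_integrative(sim$dataset, sim$map, method = "ridge", lambda = lam)
    sqrt(sum(f$beta_cn^2) + sum(f$beta_me^2) + sum(f$beta_tf^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[length(norms)], 1e-2)
})

test_that("lasso on the sparse design recovers strong signals", {
  sim <- tiny_sim(seed = 61, ng = 30, ns = 20, nf = 5, noise = 0.2)
  fit <- fit_integrative(sim$dataset, sim$map, method = "lasso", lambda = 1e-4)
  expect_identical(fit$method, "lasso")
  expect_gt(cor(fit$beta_tf, sim$truth$beta_tf), 0.9)
  expect_gt(cor(fit$beta_cn, sim$truth$beta_cn), 0.9)
  ## no valid standard errors -> TF inference must refuse
  expect_error(infer_tf_activity(fit), "OLS")
})

test_that("TF-only model is nested and closes the simple shift case", {
  ## one TF binding every gene, no covariate effects, noiseless shift delta
  delta <- 0.8
  ng <- 5; ns <- 8
  genes <- paste0("g", 1:ng); samples <- paste0("s", 1:ns)
  stage <- rep(c("I", "IV"), each = 4)
  expr <- outer(rep(delta, ng), as.numeric(stage == "IV"))
  dimnames(expr) <- list(genes, samples)
  ds <- make_expr_dataset(expr, stage)
  inc <- matrix(1, 1, ng, dimnames = list("TF1", genes))
  fit <- fit_tf_only(ds, tf_target_map(inc))
  expect_equal(unname(fit$beta_tf), delta, tolerance = 1e-10)

  ## nested models: integrative SSE <= TF-only SSE on data with real
  ## CNV/methylation effects
  sim <- tiny_sim(seed = 7, ng = 30, ns = 20, nf = 5)
  fi <- fit_integrative(sim$dataset, sim$map)
  ft <- fit_tf_only(sim$dataset, sim$map)
  expect_lte(fi$sse, ft$sse)
})

test_that("TF-only and integrative activity estimates agree when covariate
           effects are truly zero", {
  sim <- simulate_dataset(simulation_params(
    n_genes = 200, n_samples = 60, n_tfs = 8, targets_per_tf = 120,
    min_tfs_per_gene = 2, beta_cn_dist = c(0, 0), beta_me_dist = c(0, 0),
    n_active_tfs = 4, active_beta_magnitude = 1, noise_sd = 0.3, seed = 8))
  fi <- fit_integrative(sim$dataset, sim$map)
  ft <- fit_tf_only(sim$dataset, sim$map)
  expect_true(all(abs(fi$beta_tf - ft$beta_tf) < 2 * (fi$se_tf + ft$se_tf)))
})

test_that("scaling expression scales every coefficient linearly", {
  sim <- tiny_sim(seed = 14, ng = 20, ns = 12, nf = 4)
  fit1 <- fit_integrative(sim$dataset, sim$map)
  ds2 <- omics_dataset(2 * sim$dataset$expression, sim$dataset$cnv,
                       sim$dataset$methylation, sim$dataset$stage)
  fit2 <- fit_integrative(ds2, sim$map)
  expect_equal(fit2$beta_cn, 2 * fit1$beta_cn, tolerance = 1e-10)
  expect_equal(fit2$beta_me, 2 * fit1$beta_me, tolerance = 1e-10)
  expect_equal(fit2$beta_tf, 2 * fit1$beta_tf, tolerance = 1e-10)
})

test_that("singular per-gene blocks fall back to ridge with a warning", {
  sim <- tiny_sim(seed = 15, ng = 10, ns = 8, nf = 3)
  cnv <- sim$dataset$cnv; meth <- sim$dataset$methylation
  cnv[1, ] <- 2; meth[1, ] <- 0.5   # constant covariates: singular 2x2 block
  ds <- omics_dataset(sim$dataset$expression, cnv, meth, sim$dataset$stage)
  expect_warning(fit_integrative(ds, sim$map), "singular")
  expect_error(fit_integrative(ds, sim$map, strict = TRUE), "singular")
})

test_that("TF selection thresholds are strict and p-values well-formed", {
  fit <- structure(list(
    beta_tf = c(T1 = 0.5, T2 = 0.50001, T3 = -1.2, T4 = 0.01),
    se_tf = c(T1 = 0.01, T2 = 0.01, T3 = 0.01, T4 = 0.01),
    method = "ols", model = "integrative"), class = "ModelFit")
  tab <- infer_tf_activity(fit, fdr_threshold = 0.001, effect_threshold = 0.5)
  sel <- setNames(tab$selected, tab$tf)
  expect_false(sel[["T1"]])   # |beta| == 0.5 exactly: not selected
  expect_true(sel[["T2"]])
  expect_true(sel[["T3"]])
  expect_false(sel[["T4"]])
  expect_equal(tab$fdr, bh_oracle(tab$p_value))
})

test_that("residual diagnostics report correct moments", {
  make_fit <- function(r) structure(
    list(residuals = matrix(r, nrow = 1), fitted = matrix(seq_along(r), nrow = 1),
         sse = sum(r^2)), class = "ModelFit")
  ## mirrored sample is exactly symmetric -> skewness 0
  set.seed(20)
  x <- rnorm(500)
  d <- residual_diagnostics(make_fit(c(x, -x)))
  expect_equal(d$skewness, 0, tolerance = 1e-12)
  ## large normal sample: both moments near 0
  z <- rnorm(1e5)
  dz <- residual_diagnostics(make_fit(z))
  expect_lt(abs(dz$skewness), 0.05)
  expect_lt(abs(dz$kurtosis), 0.05)
  ## exponential residuals: skewness approx 2 (closed-form moment)
  e <- rexp(2e5)
  de <- residual_diagnostics(make_fit(e))
  expect_equal(de$skewness, 2, tolerance = 0.1)
  ## binned residual-vs-fitted summary covers all observations
  expect_equal(sum(dz$bins$n), 1e5)
})
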