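#' Design of the integrative stage regression
#'
#' Describes (without materializing) the stacked regression in which every
#' observation is one (gene i, sample j) pair of log2 expression, and the
#' coefficients are a copy-number slope and a methylation slope per gene
#' plus one shared activity-change term per TF, active only in rows where
#' sample j is stage IV and TF f binds gene i:
#' \deqn{y_{ij} = \beta_i^{CN} C_{ij} + \beta_i^{Me} M_{ij} +
#'   \sum_f \beta_f S_j B_{fi}}
#' The normal equations have an arrowhead structure: independent 2x2
#' per-gene blocks coupled only through the TF columns, which
#' [fit_integrative()] exploits. `n_obs = n_genes * n_samples`;
#' `n_coef = n_tfs + 2 * n_genes`.
#'
#' @param dataset an [omics_dataset()].
#' @param map a [tf_target_map()] whose genes equal the dataset's genes, in
#'   order (use [filter_genes_by_tf_count()] / [restrict_map()] first).
#' @return an object of class `DesignSpec`: list with `n_obs`, `n_coef`,
#'   `n_genes`, `n_samples`, `n_tfs`, id vectors, and references to the
#'   dataset and map. The design matrix itself is only materialized (in
#'   sparse form) by [design_matrix()].
#' @export
build_design <- function(dataset, map) {
  genes <- dataset_genes(dataset)
  if (!identical(genes, map$gene_ids)) {
    missing <- setdiff(genes, map$gene_ids)
    if (length(missing))
      stopf("gene(s) in dataset absent from TF map (filter first): %s",
            paste(utils::head(missing, 5), collapse = ", "))
    stopf("dataset and TF map genes must be identical and in the same order")
  }
  ng <- length(genes)
  ns <- length(dataset_samples(dataset))
  nf <- length(map$tf_ids)
  structure(
    list(n_obs = ng * ns, n_coef = nf + 2L * ng,
         n_genes = ng, n_samples = ns, n_tfs = nf,
         genes = genes, samples = dataset_samples(dataset),
         tfs = map$tf_ids, dataset = dataset, map = map),
    class = "DesignSpec")
}

#' @export
print.DesignSpec <- function(x, ...) {
  cat(sprintf(
    paste0("DesignSpec: %d observations (%d genes x %d samples), ",
           "%d coefficients (%d TFs + 2 x %d gene slopes)\n"),
    x$n_obs, x$n_genes, x$n_samples, x$n_coef, x$n_tfs, x$n_genes))
  invisible(x)
}

#' Materialize the sparse design matrix of a [build_design()] spec
#'
#' Rows are ordered sample-major (sample j outer, gene i inner), matching
#' `as.vector(expression)`; columns are `cn_<gene>`, then `me_<gene>`, then
#' `tf_<tf>`. Intended for small problems (dense oracles, lasso); the
#' structured solver never calls it.
#'
#' @param spec a `DesignSpec`.
#' @param tf_only drop the per-gene CNV/methylation columns.
#' @return a `dgCMatrix` of dimension `n_obs x n_coef`.
#' @export
design_matrix <- function(spec, tf_only = FALSE) {
  ds <- spec$dataset; map <- spec$map
  ng <- spec$n_genes; ns <- spec$n_samples; nf <- spec$n_tfs
  s_ind <- stage_indicator(ds)
  obs <- function(j, i) (j - 1L) * ng + i   # row index of (gene i, sample j)
  all_i <- rep(seq_len(ng), times = ns)
  all_j <- rep(seq_len(ns), each = ng)
  edges <- Matrix::summary(map$incidence)
  iv <- which(s_ind == 1)
  tf_rows <- as.vector(outer(edges$j, (iv - 1L) * ng, "+"))
  tf_cols <- rep(edges$i, times = length(iv))
  if (tf_only) {
    i_idx <- tf_rows
    j_idx <- tf_cols
    x_val <- rep(1, length(tf_rows))
    ncol_total <- nf
    cn <- character(0); me <- character(0)
  } else {
    i_idx <- c(obs(all_j, all_i), obs(all_j, all_i), tf_rows)
    j_idx <- c(all_i, ng + all_i, 2L * ng + tf_cols)
    x_val <- c(as.vector(ds$cnv), as.vector(ds$methylation),
               rep(1, length(tf_rows)))
    ncol_total <- 2L * ng + nf
    cn <- paste0("cn_", spec$genes); me <- paste0("me_", spec$genes)
  }
  Matrix::sparseMatrix(
    i = i_idx, j = j_idx, x = x_val,
    dims = c(spec$n_obs, ncol_total),
    dimnames = list(NULL, c(cn, me, paste0("tf_", spec$tfs))))
}

#' Stacked response vector matching [design_matrix()] row order
#' @param spec a `DesignSpec`.
#' @return numeric vector of length `n_obs`.
#' @export
design_response <- function(spec) as.vector(spec$dataset$expression)

## exact normal-equation solve exploiting the arrowhead structure:
## eliminate each gene's 2x2 block, form the TF-space Schur complement
## S = B diag(n_IV - w_i) B' + lambda I, solve for beta_tf, back-substitute.
## All per-gene quantities are vectorized over genes.
arrowhead_solve <- function(Y, C, M, s_ind, B, lambda = 0, strict = FALSE) {
  ng <- nrow(Y); ns <- ncol(Y); nf <- nrow(B)
  iv <- s_ind == 1
  n_iv <- sum(iv)
  a11 <- rowSums(C * C) + lambda
  a22 <- rowSums(M * M) + lambda
  a12 <- rowSums(C * M)
  u1 <- rowSums(C[, iv, drop = FALSE])
  u2 <- rowSums(M[, iv, drop = FALSE])
  q1 <- rowSums(C * Y)
  q2 <- rowSums(M * Y)
  yS <- rowSums(Y[, iv, drop = FALSE])
  dt <- a11 * a22 - a12^2
  sing <- dt <= 1e-12 * pmax(a11 * a22, 1)
  if (any(sing)) {
    if (strict)
      stopf("%d singular per-gene block(s) (constant CNV and methylation)",
            sum(sing))
    warnf("%d singular per-gene block(s); applying ridge fallback (1e-8)",
          sum(sing))
    eps <- 1e-8 * (a11 + a22 + 1)
    a11[sing] <- a11[sing] + eps[sing]
    a22[sing] <- a22[sing] + eps[sing]
    dt <- a11 * a22 - a12^2
  }
  w <- (a22 * u1^2 - 2 * a12 * u1 * u2 + a11 * u2^2) / dt
  z <- (a22 * u1 * q1 - a12 * (u1 * q2 + u2 * q1) + a11 * u2 * q2) / dt
  d <- n_iv - w
  schur <- as.matrix(B %*% Matrix::Diagonal(x = d) %*% Matrix::t(B))
  if (lambda > 0) schur <- schur + diag(lambda, nf)
  rhs <- as.numeric(B %*% (yS - z))
  beta_tf <- tryCatch(solve(schur, rhs), error = function(e) {
    warnf("TF Schur complement singular; adding 1e-8 ridge")
    solve(schur + diag(1e-8 * mean(diag(schur)) + 1e-12, nf), rhs)
  })
  tshift <- as.numeric(Matrix::crossprod(B, beta_tf))
  q1p <- q1 - u1 * tshift
  q2p <- q2 - u2 * tshift
  beta_cn <- (a22 * q1p - a12 * q2p) / dt
  beta_me <- (a11 * q2p - a12 * q1p) / dt
  fitted <- C * beta_cn + M * beta_me + outer(tshift, s_ind)
  resid <- Y - fitted
  list(beta_cn = beta_cn, beta_me = beta_me, beta_tf = beta_tf,
       tshift = tshift,
       fitted = fitted, residuals = resid, sse = sum(resid^2),
       schur = schur, a11 = a11, a22 = a22, a12 = a12, det = dt,
       u1 = u1, u2 = u2, n_singular = sum(sing))
}

#' Fit the integrative copy-number / methylation / TF-activity model
#'
#' Solves the structured least-squares problem of [build_design()] exactly
#' (`method = "ols"`) by per-gene block elimination and a TF-space Schur
#' complement — never materializing the full design. `method = "ridge"`
#' adds `lambda` to the normal-equation diagonal using the same solver;
#' `method = "lasso"` fits an L1-penalized model with \pkg{glmnet} on the
#' sparse design (no intercept, no standardization). For ridge/lasso with
#' `lambda = NULL` the penalty is chosen by 5-fold cross-validation over
#' samples (ridge) or observations (lasso, via `cv.glmnet`).
#'
#' For OLS, standard errors of the TF coefficients come from the inverse
#' Schur complement times the residual variance `SSE / (n - p)`, and
#' per-gene coefficient standard errors from the corresponding blocks of
#' the inverse normal matrix.
#'
#' @param dataset an [omics_dataset()].
#' @param map a [tf_target_map()] aligned to the dataset's genes.
#' @param method `"ols"`, `"ridge"` or `"lasso"`.
#' @param lambda regularization strength (ignored for `"ols"`, which uses 0).
#' @param center subtract per-gene means from expression, CNV and
#'   methylation before fitting (default `FALSE`: the model is fit exactly
#'   as written, without intercepts).
#' @param strict error on singular per-gene blocks instead of applying a
#'   tiny ridge fallback.
#' @return an object of class `ModelFit`: list with named vectors
#'   `beta_cn`, `beta_me`, `beta_tf`, `se_tf`, `se_cn`, `se_me` (OLS only),
#'   matrices `fitted` and `residuals`, scalars `sse`, `sigma2`, `n_obs`,
#'   `n_coef`, and tags `method`, `model`, `lambda`.
#' @export
fit_integrative <- function(dataset, map, method = c("ols", "ridge", "lasso"),
                            lambda = NULL, center = FALSE, strict = FALSE) {
  method <- match.arg(method)
  spec <- build_design(dataset, map)
  if (spec$n_coef >= spec$n_obs && method == "ols")
    stopf("design not solvable by OLS: p = %d >= n = %d",
          spec$n_coef, spec$n_obs)
  Y <- dataset$expression; C <- dataset$cnv; M <- dataset$methylation
  if (center) {
    Y <- Y - rowMeans(Y); C <- C - rowMeans(C); M <- M - rowMeans(M)
  }
  s_ind <- stage_indicator(dataset)
  B <- map$incidence
  if (method == "lasso") {
    return(fit_lasso(spec, Y, lambda, center))
  }
  if (method == "ridge" && is.null(lambda))
    lambda <- choose_ridge_lambda(Y, C, M, s_ind, dataset$stage, B)
  if (method == "ols") lambda <- 0
  sol <- arrowhead_solve(Y, C, M, s_ind, B, lambda = lambda, strict = strict)
  fit <- list(
    beta_cn = stats::setNames(sol$beta_cn, spec$genes),
    beta_me = stats::setNames(sol$beta_me, spec$genes),
    beta_tf = stats::setNames(sol$beta_tf, spec$tfs),
    tf_shift = stats::setNames(sol$tshift, spec$genes),
    fitted = sol$fitted, residuals = sol$residuals, sse = sol$sse,
    n_obs = spec$n_obs, n_coef = spec$n_coef,
    method = method, model = "integrative", lambda = lambda,
    genes = spec$genes, tfs = spec$tfs
  )
  if (method == "ols") {
    sigma2 <- sol$sse / (spec$n_obs - spec$n_coef)
    schur_inv <- solve(sol$schur)
    se_tf <- sqrt(pmax(0, sigma2 * diag(schur_inv)))
    ## gene-block diagonal of the inverse normal matrix:
    ## D^-1 + (D^-1 u)(b' S^-1 b)(D^-1 u)'
    G <- schur_inv %*% as.matrix(B)
    g <- colSums(as.matrix(B) * G)
    p1 <- (sol$a22 * sol$u1 - sol$a12 * sol$u2) / sol$det
    p2 <- (sol$a11 * sol$u2 - sol$a12 * sol$u1) / sol$det
    fit$sigma2 <- sigma2
    fit$se_tf <- stats::setNames(se_tf, spec$tfs)
    fit$se_cn <- stats::setNames(sqrt(pmax(0, sigma2 * (sol$a22 / sol$det + p1^2 * g))),
                                 spec$genes)
    fit$se_me <- stats::setNames(sqrt(pmax(0, sigma2 * (sol$a11 / sol$det + p2^2 * g))),
                                 spec$genes)
  }
  class(fit) <- "ModelFit"
  fit
}

## 5-fold sample-stratified CV over a log-spaced grid for the ridge penalty
choose_ridge_lambda <- function(Y, C, M, s_ind, stage, B,
                                grid = 10^seq(-3, 3, length.out = 13)) {
  ns <- ncol(Y)
  folds <- stratified_folds(stage, k = 5L, seed = 1L)
  errs <- vapply(grid, function(lam) {
    tot <- 0
    for (f in seq_len(5L)) {
      tr <- folds != f; te <- folds == f
      sol <- arrowhead_solve(Y[, tr, drop = FALSE], C[, tr, drop = FALSE],
                             M[, tr, drop = FALSE], s_ind[tr], B, lambda = lam)
      pred <- C[, te, drop = FALSE] * sol$beta_cn +
        M[, te, drop = FALSE] * sol$beta_me +
        outer(as.numeric(Matrix::crossprod(B, sol$beta_tf)), s_ind[te])
      tot <- tot + sum((Y[, te, drop = FALSE] - pred)^2)
    }
    tot
  }, numeric(1))
  grid[which.min(errs)]
}

## L1 fit on the materialized sparse design via glmnet
fit_lasso <- function(spec, Y, lambda, center) {
  X <- design_matrix(spec)
  y <- as.vector(Y)
  if (is.null(lambda)) {
    cvfit <- glmnet::cv.glmnet(X, y, alpha = 1, intercept = FALSE,
                               standardize = FALSE, nfolds = 5)
    lambda <- cvfit$lambda.min
  }
  gfit <- glmnet::glmnet(X, y, alpha = 1, intercept = FALSE,
                         standardize = FALSE, lambda = lambda)
  coefs <- as.numeric(gfit$beta)
  ng <- spec$n_genes
  pred <- as.numeric(X %*% coefs)
  resid <- matrix(y - pred, nrow = ng)
  fit <- list(
    beta_cn = stats::setNames(coefs[seq_len(ng)], spec$genes),
    beta_me = stats::setNames(coefs[ng + seq_len(ng)], spec$genes),
    beta_tf = stats::setNames(coefs[2L * ng + seq_len(spec$n_tfs)], spec$tfs),
    tf_shift = stats::setNames(
      as.numeric(Matrix::crossprod(spec$map$incidence,
                                   coefs[2L * ng + seq_len(spec$n_tfs)])),
      spec$genes),
    fitted = matrix(pred, nrow = ng, dimnames = dimnames(spec$dataset$expression)),
    residuals = resid, sse = sum(resid^2),
    n_obs = spec$n_obs, n_coef = spec$n_coef,
    method = "lasso", model = "integrative", lambda = lambda,
    genes = spec$genes, tfs = spec$tfs
  )
  class(fit) <- "ModelFit"
  fit
}

#' Fit the TF-only baseline model
#'
#' Same design with the per-gene copy-number and methylation columns
#' removed: expression is explained by stage-gated TF activity terms alone.
#'
#' @inheritParams fit_integrative
#' @param lambda ridge penalty added to the TF normal matrix (default 0).
#' @return a `ModelFit` with `beta_cn`/`beta_me` absent and
#'   `model = "tf_only"`.
#' @export
fit_tf_only <- function(dataset, map, lambda = 0) {
  spec <- build_design(dataset, map)
  Y <- dataset$expression
  s_ind <- stage_indicator(dataset)
  B <- map$incidence
  n_iv <- sum(s_ind)
  yS <- rowSums(Y[, s_ind == 1, drop = FALSE])
  A <- n_iv * as.matrix(Matrix::tcrossprod(B))
  if (lambda > 0) A <- A + diag(lambda, spec$n_tfs)
  rhs <- as.numeric(B %*% yS)
  beta_tf <- tryCatch(solve(A, rhs), error = function(e) {
    warnf("TF normal matrix singular; adding 1e-8 ridge")
    solve(A + diag(1e-8 * mean(diag(A)) + 1e-12, spec$n_tfs), rhs)
  })
  tshift <- as.numeric(Matrix::crossprod(B, beta_tf))
  fitted <- outer(tshift, s_ind)
  resid <- Y - fitted
  sse <- sum(resid^2)
  sigma2 <- sse / (spec$n_obs - spec$n_tfs)
  se_tf <- sqrt(pmax(0, sigma2 * diag(solve(A))))
  fit <- list(
    beta_tf = stats::setNames(beta_tf, spec$tfs),
    tf_shift = stats::setNames(tshift, spec$genes),
    se_tf = stats::setNames(se_tf, spec$tfs),
    fitted = fitted, residuals = resid, sse = sse, sigma2 = sigma2,
    n_obs = spec$n_obs, n_coef = spec$n_tfs,
    method = "ols", model = "tf_only", lambda = lambda,
    genes = spec$genes, tfs = spec$tfs
  )
  class(fit) <- "ModelFit"
  fit
}

#' @export
print.ModelFit <- function(x, ...) {
  cat(sprintf("ModelFit (%s, %s): %d obs, %d coef, SSE = %.4g\n",
              x$model, x$method, x$n_obs, x$n_coef, x$sse))
  invisible(x)
}

#' Predict expression from a fitted model for (possibly new) samples
#'
#' Uses the fitted per-gene slopes and the stage-gated per-gene TF shift
#' (`sum_f beta_f B_fi`, stored in the fit) on a dataset over the same
#' genes; for a TF-only fit only the stage-gated term contributes.
#'
#' @param fit a `ModelFit`.
#' @param dataset an [omics_dataset()] over the same genes, in order.
#' @return matrix of predicted log2 expression, genes x samples.
#' @export
predict_expression <- function(fit, dataset) {
  stopifnot(identical(fit$genes, dataset_genes(dataset)))
  s_ind <- stage_indicator(dataset)
  pred <- outer(fit$tf_shift, s_ind)
  if (!is.null(fit$beta_cn))
    pred <- pred + dataset$cnv * fit$beta_cn + dataset$methylation * fit$beta_me
  dimnames(pred) <- dimnames(dataset$expression)
  pred
}

#' TF activity-change table with multiplicity-adjusted selection
#'
#' Two-sided p-values for each TF activity coefficient from the normal
#' approximation `beta / se`, Benjamini-Hochberg adjustment across the TF
#' family only, and a selected flag for `fdr < fdr_threshold` and
#' `|beta| > effect_threshold` (both strict).
#'
#' @param fit an OLS `ModelFit` (integrative or TF-only); regularized fits
#'   have no valid standard errors and are rejected.
#' @param fdr_threshold default 0.001.
#' @param effect_threshold default 0.5 (absolute activity change, log2
#'   expression units).
#' @return `data.frame` of class `TFActivityTable` with columns `tf`,
#'   `beta`, `se`, `p_value`, `fdr`, `selected`.
#' @export
infer_tf_activity <- function(fit, fdr_threshold = 0.001,
                              effect_threshold = 0.5) {
  if (!identical(fit$method, "ols") || is.null(fit$se_tf))
    stopf("TF inference requires an OLS fit with standard errors (method '%s')",
          fit$method)
  z <- fit$beta_tf / fit$se_tf
  p <- 2 * stats::pnorm(-abs(z))
  fdr <- bh_adjust(p)
  out <- data.frame(tf = names(fit$beta_tf), beta = unname(fit$beta_tf),
                    se = unname(fit$se_tf), p_value = unname(p),
                    fdr = unname(fdr),
                    selected = unname(fdr < fdr_threshold &
                                        abs(fit$beta_tf) > effect_threshold),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, method = "radix"), ]
  rownames(out) <- NULL
  class(out) <- c("TFActivityTable", "data.frame")
  attr(out, "thresholds") <- c(fdr = fdr_threshold, effect = effect_threshold)
  out
}

#' Residual diagnostics of a fitted model
#'
#' Sample skewness and excess kurtosis of the residuals, and binned
#' residual-vs-fitted means (equal-width bins over the fitted range) for a
#' quick check that residuals scatter around zero with no trend.
#'
#' @param fit a `ModelFit`.
#' @param n_bins number of fitted-value bins (default 10).
#' @return list with `skewness`, `kurtosis` (excess), `sse`, and `bins`
#'   (`data.frame` with `fitted_mid`, `mean_residual`, `n`).
#' @export
residual_diagnostics <- function(fit, n_bins = 10L) {
  r <- as.vector(fit$residuals)
  f <- as.vector(fit$fitted)
  brks <- seq(min(f), max(f), length.out = n_bins + 1L)
  if (brks[1] == brks[n_bins + 1L]) brks <- brks[1] + c(-0.5, 0.5)
  idx <- cut(f, brks, include.lowest = TRUE, labels = FALSE)
  mids <- (brks[-1] + brks[-length(brks)]) / 2
  mr <- tapply(r, factor(idx, levels = seq_along(mids)), mean)
  nn <- tapply(r, factor(idx, levels = seq_along(mids)), length)
  bins <- data.frame(fitted_mid = mids,
                     mean_residual = as.numeric(mr),
                     n = ifelse(is.na(nn), 0L, as.integer(nn)))
  list(skewness = sample_skewness(r), kurtosis = sample_kurtosis(r),
       sse = fit$sse, bins = bins)
}
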