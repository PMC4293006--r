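## Independent oracles and small fixture builders shared across test files.

## brute-force BH step-up: sort ascending, p * m / rank, cumulative min from
## the largest rank down, cap at 1
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

## brute-force two-sample KS D: max empirical-CDF gap over pooled points
ks_d_oracle <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  fx <- vapply(pts, function(t) mean(x <= t), numeric(1))
  fy <- vapply(pts, function(t) mean(y <= t), numeric(1))
  max(abs(fx - fy))
}

## dense least-squares oracle on the materialized design
dense_fit_oracle <- function(dataset, map) {
  spec <- build_design(dataset, map)
  X <- as.matrix(design_matrix(spec))
  y <- design_response(spec)
  cf <- qr.coef(qr(X), y)
  ng <- spec$n_genes
  list(beta_cn = unname(cf[seq_len(ng)]),
       beta_me = unname(cf[ng + seq_len(ng)]),
       beta_tf = unname(cf[2 * ng + seq_len(spec$n_tfs)]))
}

## matched-matrix dataset from an expression matrix alone (neutral CNV and
## methylation layers), for tests that only exercise expression logic
make_expr_dataset <- function(expr, stage) {
  cnv <- matrix(2, nrow(expr), ncol(expr), dimnames = dimnames(expr))
  meth <- matrix(0.5, nrow(expr), ncol(expr), dimnames = dimnames(expr))
  omics_dataset(expr, cnv, meth, stage)
}

## small labeled random matrix
rand_mat <- function(ng, ns, prefix_g = "g", prefix_s = "s", fn = rnorm) {
  matrix(fn(ng * ns), ng, ns,
         dimnames = list(sprintf("%s%03d", prefix_g, seq_len(ng)),
                         sprintf("%s%03d", prefix_s, seq_len(ns))))
}

## quick small simulation used by several files
tiny_sim <- function(seed = 1, ng = 30, ns = 16, nf = 6, noise = 0.3, ...) {
  simulate_dataset(simulation_params(
    n_genes = ng, n_samples = ns, n_tfs = nf,
    targets_per_tf = ceiling(0.5 * ng), min_tfs_per_gene = 1L,
    n_active_tfs = min(3L, nf), noise_sd = noise, seed = seed, ...))
}
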