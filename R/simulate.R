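#' Simulation parameters for matched multi-omics data
#'
#' Describes the generative world used by [simulate_dataset()]: per-gene
#' copy-number and methylation dosage effects, a random bipartite TF-target
#' map, a subset of TFs whose activity shifts in stage IV, and Gaussian
#' residual noise. Defaults are the scenario used throughout the package's
#' recovery tests: 2000 genes x 200 samples, 50 TFs of which 10 are active
#' with |activity change| 1.0, residual sd 0.5, and a stage-IV fraction of
#' 0.31 (55/178, the stage composition of the cohort the model was designed
#' around).
#'
#' @param n_genes,n_samples,n_tfs positive integers.
#' @param frac_stage_iv fraction of samples labeled stage IV, in (0, 1).
#' @param targets_per_tf mean target-set size of a TF (expected number of
#'   genes per TF). Default `0.25 * n_genes`, giving a mean of
#'   `0.25 * n_tfs` binding TFs per gene.
#' @param beta_cn_dist length-2 numeric `(mean, sd)` of per-gene CNV
#'   coefficients; default `c(0.5, 0.2)` (positive dosage effect).
#' @param beta_me_dist length-2 numeric `(mean, sd)` of per-gene methylation
#'   coefficients; default `c(-1, 0.4)` (methylation represses).
#' @param n_active_tfs number of TFs with nonzero activity change.
#' @param active_beta_magnitude absolute activity change of active TFs
#'   (signs alternate +/-).
#' @param noise_sd residual standard deviation (>= 0).
#' @param min_tfs_per_gene every gene is guaranteed strictly more than this
#'   many binding TFs (default 5, matching the model's gene filter); set to
#'   0 to disable for tiny examples.
#' @param n_cnv_shift_genes,cnv_shift,n_meth_shift_genes,meth_shift optional
#'   planted single-mechanism genes: for the chosen genes the CNV
#'   (respectively methylation) covariate itself is shifted by the given
#'   amount in stage-IV samples (clipped to the covariate's support), so
#'   their expression alteration is driven by that covariate. Defaults 0.
#' @param seed integer RNG seed; the same seed yields bit-identical output.
#' @return a validated list of class `SimulationParams`.
#' @export
simulation_params <- function(n_genes = 2000L, n_samples = 200L, n_tfs = 50L,
                              frac_stage_iv = 0.31,
                              targets_per_tf = ceiling(0.25 * n_genes),
                              beta_cn_dist = c(0.5, 0.2),
                              beta_me_dist = c(-1, 0.4),
                              n_active_tfs = min(10L, n_tfs),
                              active_beta_magnitude = 1.0,
                              noise_sd = 0.5,
                              min_tfs_per_gene = 5L,
                              n_cnv_shift_genes = 0L, cnv_shift = 0,
                              n_meth_shift_genes = 0L, meth_shift = 0,
                              seed = 1L) {
  p <- list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
            n_tfs = as.integer(n_tfs), frac_stage_iv = frac_stage_iv,
            targets_per_tf = targets_per_tf,
            beta_cn_dist = beta_cn_dist, beta_me_dist = beta_me_dist,
            n_active_tfs = as.integer(n_active_tfs),
            active_beta_magnitude = active_beta_magnitude,
            noise_sd = noise_sd,
            min_tfs_per_gene = as.integer(min_tfs_per_gene),
            n_cnv_shift_genes = as.integer(n_cnv_shift_genes),
            cnv_shift = cnv_shift,
            n_meth_shift_genes = as.integer(n_meth_shift_genes),
            meth_shift = meth_shift,
            seed = as.integer(seed))
  stopifnot(p$n_genes > 0, p$n_samples >= 4, p$n_tfs > 0,
            p$frac_stage_iv > 0, p$frac_stage_iv < 1,
            p$targets_per_tf > 0, p$targets_per_tf <= p$n_genes,
            length(p$beta_cn_dist) == 2, length(p$beta_me_dist) == 2,
            p$n_active_tfs >= 0, p$n_active_tfs <= p$n_tfs,
            p$noise_sd >= 0, p$min_tfs_per_gene >= 0,
            p$n_cnv_shift_genes >= 0, p$n_cnv_shift_genes <= p$n_genes,
            p$n_meth_shift_genes >= 0, p$n_meth_shift_genes <= p$n_genes)
  if (p$min_tfs_per_gene >= p$n_tfs)
    stopf("min_tfs_per_gene (%d) must be below n_tfs (%d)",
          p$min_tfs_per_gene, p$n_tfs)
  class(p) <- "SimulationParams"
  p
}

## random binary incidence with mean gene degree targets_per_tf * n_tfs /
## n_genes; deficient genes are re-drawn column-wise until every gene has
## strictly more than min_tf binding TFs (bounded number of redraws)
simulate_incidence <- function(n_tfs, n_genes, targets_per_tf, min_tf,
                               tf_ids, gene_ids, max_redraws = 200L) {
  p_edge <- min(0.95, targets_per_tf / n_genes)
  if (min_tf > 0) {
    expected <- p_edge * n_tfs
    if (expected <= min_tf)
      stopf(paste0("infeasible degree constraint: mean TFs per gene %.2f ",
                   "<= required minimum %d; increase targets_per_tf"),
            expected, min_tf)
  }
  inc <- matrix(stats::rbinom(n_tfs * n_genes, 1L, p_edge),
                nrow = n_tfs, ncol = n_genes,
                dimnames = list(tf_ids, gene_ids))
  for (it in seq_len(max_redraws)) {
    deficient <- which(colSums(inc) <= min_tf)
    if (!length(deficient)) break
    inc[, deficient] <- stats::rbinom(n_tfs * length(deficient), 1L, p_edge)
    if (it == max_redraws)
      stopf("degree constraint not met after %d redraws", max_redraws)
  }
  ## a TF with no targets, or two TFs with identical target columns, would
  ## violate the map invariants; redraw the offending rows
  for (it in seq_len(max_redraws)) {
    key <- apply(inc, 1, paste, collapse = "")
    bad <- which(rowSums(inc) == 0 | duplicated(key))
    if (!length(bad)) break
    inc[bad, ] <- stats::rbinom(length(bad) * n_genes, 1L, p_edge)
    if (it == max_redraws)
      stopf("could not draw distinct nonempty TF target sets")
  }
  inc
}

#' Simulate a matched multi-omics dataset with known ground truth
#'
#' Generates copy number `C ~ Normal(2, 0.4)` truncated at 0 (diploid
#' baseline), methylation `M ~ Beta(2, 5)`, a random TF-target incidence,
#' stage labels, and expression
#' `y_ij = beta_cn_i C_ij + beta_me_i M_ij + sum_f beta_f S_j B_fi + eps_ij`
#' with `eps ~ Normal(0, noise_sd^2)`. Active TFs are chosen uniformly and
#' their activity changes alternate in sign. With `noise_sd = 0` the
#' expression matrix satisfies the linear model exactly.
#'
#' @param params a [simulation_params()] object.
#' @return list with `dataset` (an [omics_dataset()]), `map`
#'   (a [tf_target_map()]) and `truth` (class `SyntheticTruth`: named
#'   vectors `beta_cn`, `beta_me`, `beta_tf`, the planted shift gene sets,
#'   `noise_sd` and `seed`).
#' @export
simulate_dataset <- function(params = simulation_params()) {
  stopifnot(inherits(params, "SimulationParams"))
  set.seed(params$seed)
  ng <- params$n_genes; ns <- params$n_samples; nf <- params$n_tfs
  gene_ids <- sprintf("g%05d", seq_len(ng))
  sample_ids <- sprintf("s%04d", seq_len(ns))
  tf_ids <- sprintf("TF%03d", seq_len(nf))

  n_iv <- max(2L, min(ns - 2L, round(params$frac_stage_iv * ns)))
  iv_samples <- sample.int(ns, n_iv)
  stage <- rep("I", ns)
  stage[iv_samples] <- "IV"
  names(stage) <- sample_ids
  s_ind <- as.numeric(stage == "IV")

  inc <- simulate_incidence(nf, ng, params$targets_per_tf,
                            params$min_tfs_per_gene, tf_ids, gene_ids)

  cnv <- matrix(pmax(0, stats::rnorm(ng * ns, 2, 0.4)), ng, ns,
                dimnames = list(gene_ids, sample_ids))
  meth <- matrix(stats::rbeta(ng * ns, 2, 5), ng, ns,
                 dimnames = list(gene_ids, sample_ids))

  ## planted stage-gated covariate shifts (single-mechanism genes)
  cnv_shift_genes <- character(0)
  meth_shift_genes <- character(0)
  if (params$n_cnv_shift_genes > 0) {
    cnv_shift_genes <- gene_ids[sample.int(ng, params$n_cnv_shift_genes)]
    cnv[cnv_shift_genes, s_ind == 1] <-
      pmax(0, cnv[cnv_shift_genes, s_ind == 1] + params$cnv_shift)
  }
  if (params$n_meth_shift_genes > 0) {
    meth_shift_genes <- gene_ids[sample.int(ng, params$n_meth_shift_genes)]
    meth[meth_shift_genes, s_ind == 1] <-
      pmin(1, pmax(0, meth[meth_shift_genes, s_ind == 1] + params$meth_shift))
  }

  beta_cn <- stats::rnorm(ng, params$beta_cn_dist[1], params$beta_cn_dist[2])
  beta_me <- stats::rnorm(ng, params$beta_me_dist[1], params$beta_me_dist[2])
  names(beta_cn) <- names(beta_me) <- gene_ids

  beta_tf <- rep(0, nf)
  names(beta_tf) <- tf_ids
  active <- integer(0)
  if (params$n_active_tfs > 0) {
    active <- sort(sample.int(nf, params$n_active_tfs))
    beta_tf[active] <- params$active_beta_magnitude *
      rep_len(c(1, -1), params$n_active_tfs)
  }

  tf_shift <- as.numeric(crossprod(inc, beta_tf))  # per-gene total TF term
  expr <- cnv * beta_cn + meth * beta_me + outer(tf_shift, s_ind)
  if (params$noise_sd > 0)
    expr <- expr + matrix(stats::rnorm(ng * ns, 0, params$noise_sd), ng, ns)
  dimnames(expr) <- list(gene_ids, sample_ids)

  dataset <- omics_dataset(expr, cnv, meth, stage)
  map <- tf_target_map(inc)
  truth <- structure(
    list(beta_cn = beta_cn, beta_me = beta_me, beta_tf = beta_tf,
         active_tfs = tf_ids[active],
         cnv_shift_genes = cnv_shift_genes,
         meth_shift_genes = meth_shift_genes,
         cnv_shift = params$cnv_shift, meth_shift = params$meth_shift,
         noise_sd = params$noise_sd, seed = params$seed),
    class = "SyntheticTruth")
  list(dataset = dataset, map = map, truth = truth)
}

#' Permute expression values as a null baseline
#'
#' Randomizes expression while leaving copy number, methylation and stage
#' labels untouched. By default the permutation is over the full
#' gene-by-sample grid (destroying both gene identity and sample structure);
#' `within_genes = TRUE` instead permutes each gene's values across samples.
#'
#' @param dataset an [omics_dataset()].
#' @param seed integer seed; the same seed reproduces the permutation.
#' @param within_genes logical; permute within each gene row instead of the
#'   whole grid.
#' @return a new [omics_dataset()] with permuted expression.
#' @export
permute_expression <- function(dataset, seed, within_genes = FALSE) {
  set.seed(seed)
  e <- dataset$expression
  if (within_genes) {
    for (i in seq_len(nrow(e))) e[i, ] <- e[i, sample.int(ncol(e))]
  } else {
    e[] <- e[sample.int(length(e))]
  }
  omics_dataset(e, dataset$cnv, dataset$methylation, dataset$stage)
}

#' Write the ground-truth coefficient record as TSV
#' @param truth a `SyntheticTruth` object from [simulate_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  gene <- data.frame(id = names(truth$beta_cn), kind = "gene",
                     beta_cn = truth$beta_cn, beta_me = truth$beta_me,
                     beta_tf = NA_real_)
  tf <- data.frame(id = names(truth$beta_tf), kind = "tf",
                   beta_cn = NA_real_, beta_me = NA_real_,
                   beta_tf = truth$beta_tf)
  utils::write.table(rbind(gene, tf), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
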