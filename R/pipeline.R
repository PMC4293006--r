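## default pipeline configuration: thresholds follow the analysis the
## package implements (FC > 2, DE FDR < 0.001, correlation alpha 0.01,
## TF selection FDR < 0.001 and |effect| > 0.5, > 5 binding TFs per gene,
## 10-fold CV)
pipeline_defaults <- function() {
  list(
    simulate = TRUE,
    dataset_dir = "",
    seed = 1L,
    fc = 2, de_fdr = 0.001, corr_alpha = 0.01,
    tf_fdr = 0.001, tf_effect = 0.5,
    min_tfs = 5L, k = 10L, method = "ols", lambda = NA_real_,
    coef_alpha = 0.01, min_contribution = 0.25,
    cv_models = "integrative,tf_only,random",
    sim_n_genes = 500L, sim_n_samples = 60L, sim_n_tfs = 20L,
    sim_targets_per_tf = NA_real_, sim_frac_stage_iv = 0.31,
    sim_n_active_tfs = 4L, sim_active_beta = 1.0, sim_noise_sd = 0.5
  )
}

#' Read a plain-text `key = value` pipeline configuration
#'
#' One setting per line, `#` starts a comment, unknown keys are rejected.
#' Unset keys take the defaults of the published analysis (fold change > 2,
#' DE FDR < 0.001, correlation alpha 0.01, TF FDR < 0.001 with
#' |effect| > 0.5, gene filter at > 5 TFs, k = 10 folds).
#'
#' @param path config file path, or `NULL` for pure defaults.
#' @param overrides named list applied on top of the file.
#' @return validated named list of class `PipelineConfig`.
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- pipeline_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stopf("config file not found: %s", path)
    lines <- readLines(path, encoding = "UTF-8")
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*)$", ln))[[1]]
      if (length(kv) != 3L) stopf("malformed config line: '%s'", ln)
      key <- kv[2]; val <- trimws(kv[3])
      if (!key %in% names(cfg)) stopf("unknown config key: '%s'", key)
      proto <- cfg[[key]]
      cfg[[key]] <- if (is.logical(proto)) {
        tolower(val) %in% c("true", "1", "yes")
      } else if (is.numeric(proto)) {
        num <- suppressWarnings(as.numeric(val))
        if (is.na(num) && !identical(tolower(val), "na"))
          stopf("config key '%s' expects a number, got '%s'", key, val)
        num
      } else val
    }
  }
  for (key in names(overrides)) {
    if (!key %in% names(cfg)) stopf("unknown config key: '%s'", key)
    cfg[[key]] <- overrides[[key]]
  }
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  chk01 <- function(key) {
    v <- cfg[[key]]
    if (!is.numeric(v) || is.na(v) || v <= 0 || v >= 1)
      stopf("config '%s' must lie in (0, 1), got %s", key, format(cfg[[key]]))
  }
  chk01("de_fdr"); chk01("corr_alpha"); chk01("tf_fdr")
  chk01("sim_frac_stage_iv"); chk01("coef_alpha")
  if (cfg$fc <= 1) stopf("config 'fc' must exceed 1")
  if (cfg$tf_effect < 0) stopf("config 'tf_effect' must be >= 0")
  if (cfg$min_tfs < 0) stopf("config 'min_tfs' must be >= 0")
  if (cfg$k < 2) stopf("config 'k' must be >= 2")
  if (!cfg$method %in% c("ols", "ridge", "lasso"))
    stopf("config 'method' must be ols, ridge or lasso")
  if (is.na(cfg$seed)) stopf("config 'seed' is mandatory")
  cfg$seed <- as.integer(cfg$seed)
  cfg$k <- as.integer(cfg$k)
  cfg$min_tfs <- as.integer(cfg$min_tfs)
  models <- trimws(strsplit(cfg$cv_models, ",")[[1]])
  bad <- setdiff(models, c("integrative", "tf_only", "random", ""))
  if (length(bad)) stopf("unknown cv model(s): %s", paste(bad, collapse = ", "))
  if (!cfg$simulate && !nzchar(cfg$dataset_dir))
    stopf("config: either simulate = true or dataset_dir must be set")
  class(cfg) <- c("PipelineConfig", "list")
  cfg
}

config_hash <- function(cfg) {
  keys <- lex_sort(names(unclass(cfg)))
  txt <- paste(vapply(keys, function(k) {
    sprintf("%s=%s", k, paste(format(cfg[[k]], digits = 15), collapse = ","))
  }, ""), collapse = "\n")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulation (or dataset loading), the gene filter,
#' differential expression, CNV and methylation correlation profiling, the
#' integrative model fit with TF activity inference and residual
#' diagnostics, cross-validated prediction for the configured model
#' variants, and per-gene mechanism attribution. All artifacts are written
#' under `outdir` as TSV/JSON, stamped with the configuration hash and
#' seed (`run_info.json`); a rerun with an identical configuration
#' reproduces them bit-identically.
#'
#' @param config a `PipelineConfig` (see [read_pipeline_config()]) or a
#'   path to a config file.
#' @param outdir output directory (created).
#' @return invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(config, outdir) {
  cfg <- if (inherits(config, "PipelineConfig")) config
         else read_pipeline_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage_names <- character(0)
  run_stage <- function(name, expr) {
    message(sprintf("[pipeline] stage: %s", name))
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  truth <- NULL
  loaded <- run_stage("data", {
    if (cfg$simulate) {
      tpt <- cfg$sim_targets_per_tf
      if (is.na(tpt)) tpt <- ceiling(0.45 * cfg$sim_n_genes)
      sim <- simulate_dataset(simulation_params(
        n_genes = cfg$sim_n_genes, n_samples = cfg$sim_n_samples,
        n_tfs = cfg$sim_n_tfs, targets_per_tf = tpt,
        frac_stage_iv = cfg$sim_frac_stage_iv,
        n_active_tfs = cfg$sim_n_active_tfs,
        active_beta_magnitude = cfg$sim_active_beta,
        noise_sd = cfg$sim_noise_sd,
        min_tfs_per_gene = cfg$min_tfs,
        seed = cfg$seed))
      ddir <- file.path(outdir, "dataset")
      write_dataset_dir(sim$dataset, ddir, map = sim$map)
      write_truth(sim$truth, file.path(ddir, "truth.tsv"))
      truth <<- sim$truth
      list(dataset = sim$dataset, map = sim$map)
    } else {
      read_dataset_dir(cfg$dataset_dir)
    }
  })

  flt <- run_stage("filter", {
    filter_genes_by_tf_count(loaded$dataset, loaded$map, cfg$min_tfs)
  })
  ds <- flt$dataset; map <- flt$map
  message(sprintf("[pipeline] thresholds: fc=%g de_fdr=%g corr_alpha=%g tf_fdr=%g tf_effect=%g min_tfs=%d k=%d",
                  cfg$fc, cfg$de_fdr, cfg$corr_alpha, cfg$tf_fdr,
                  cfg$tf_effect, cfg$min_tfs, cfg$k))

  de <- run_stage("de", {
    res <- de_test(ds, fc_threshold = cfg$fc, fdr_threshold = cfg$de_fdr)
    utils::write.table(res, file.path(outdir, "de.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    res
  })

  corr <- run_stage("correlate", {
    out <- list()
    for (layer in c("cnv", "methylation")) {
      prof <- per_gene_correlation(ds, layer)
      utils::write.table(prof, file.path(outdir, sprintf("corr_%s.tsv", layer)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out[[layer]] <- summarize_correlations(prof, alpha = cfg$corr_alpha)
    }
    write_json_out(lapply(out, unclass),
                   file.path(outdir, "correlation_summary.json"))
    out
  })

  fit_res <- run_stage("fit", {
    lam <- if (is.na(cfg$lambda)) NULL else cfg$lambda
    fit <- fit_integrative(ds, map, method = cfg$method, lambda = lam)
    fdir <- file.path(outdir, "fit")
    dir.create(fdir, showWarnings = FALSE)
    tf_tab <- NULL
    if (cfg$method == "ols") {
      tf_tab <- infer_tf_activity(fit, cfg$tf_fdr, cfg$tf_effect)
      utils::write.table(tf_tab, file.path(fdir, "tf_activity.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    gc_df <- data.frame(gene_id = fit$genes,
                        beta_cn = unname(fit$beta_cn),
                        beta_me = unname(fit$beta_me))
    utils::write.table(gc_df, file.path(fdir, "gene_coefficients.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    diag <- residual_diagnostics(fit)
    write_json_out(list(sse = diag$sse, skewness = diag$skewness,
                        kurtosis = diag$kurtosis, bins = diag$bins),
                   file.path(fdir, "diagnostics.json"))
    list(fit = fit, tf_table = tf_tab)
  })

  cv_models <- trimws(strsplit(cfg$cv_models, ",")[[1]])
  cv_models <- cv_models[nzchar(cv_models)]
  cv <- run_stage("crossval", {
    reports <- lapply(cv_models, function(m)
      crossval(ds, map, k = cfg$k, seed = cfg$seed, model = m))
    names(reports) <- cv_models
    write_json_out(lapply(reports, function(r)
      list(model = r$model, k = r$k, seed = r$seed,
           mean_spearman = r$mean_spearman,
           median_spearman = r$median_spearman, n_na = r$n_na)),
      file.path(outdir, "cv_report.json"))
    reports
  })

  attrib <- NULL
  if (!is.null(fit_res$tf_table) && any(de$status != "ns")) {
    attrib <- run_stage("dissect", {
      rec <- attribute_genes(fit_res$fit, fit_res$tf_table, de, ds, map,
                             coef_alpha = cfg$coef_alpha,
                             min_contribution = cfg$min_contribution)
      utils::write.table(rec, file.path(outdir, "attribution.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      summ <- attribution_summary(rec)
      write_json_out(list(regions = as.list(summ$regions),
                          unexplained = summ$unexplained,
                          n_total = summ$n_total,
                          n_explained = summ$n_explained,
                          fraction_explained = summ$fraction_explained),
                     file.path(outdir, "attribution_summary.json"))
      rec
    })
  }

  write_json_out(list(config_hash = config_hash(cfg), seed = cfg$seed,
                      package_version = as.character(utils::packageVersion("tfactivity")),
                      config = unclass(cfg)),
                 file.path(outdir, "run_info.json"))
  invisible(list(dataset = ds, map = map, truth = truth, de = de,
                 correlation = corr, fit = fit_res$fit,
                 tf_table = fit_res$tf_table, cv = cv, attribution = attrib))
}
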