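#' Read a genes-by-samples omics matrix from TSV
#'
#' Expected dialect: UTF-8, tab-delimited, header row of sample identifiers,
#' first column named `gene_id`, `.` decimal point, no thousands separators.
#'
#' @param path path to the TSV file.
#' @param kind one of `"expression"`, `"cnv"`, `"methylation"`; methylation
#'   values are additionally checked to lie in `[0, 1]`.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_omics_matrix <- function(path, kind = c("expression", "cnv", "methylation")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stopf("%s: expected gene_id column plus >=1 sample", path)
  if (names(df)[1L] != "gene_id")
    stopf("%s: first column must be named 'gene_id' (found '%s')",
          path, names(df)[1L])
  genes <- df[[1L]]
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    stopf("%s: duplicate gene id(s): %s (one row per gene is required)",
          path, paste(utils::head(dup, 5), collapse = ", "))
  }
  samples <- names(df)[-1L]
  if (anyDuplicated(samples)) stopf("%s: duplicate sample ids in header", path)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stopf("%s: non-numeric value '%s' for gene %s, sample %s",
          path, vals[bad[1L, 1L], bad[1L, 2L]],
          genes[bad[1L, 1L]], samples[bad[1L, 2L]])
  }
  dimnames(num) <- list(genes, samples)
  if (kind == "methylation" && (min(num) < 0 || max(num) > 1))
    stopf("%s: methylation beta values must lie in [0, 1]", path)
  num
}

#' Write a genes-by-samples matrix in the package's TSV dialect
#'
#' Inverse of [read_omics_matrix()]: round-trips values bit-identically via
#' R's full-precision decimal formatting.
#'
#' @param mat numeric matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_omics_matrix <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat),
                   ## 17 significant digits reproduce doubles exactly
                   apply(mat, 2, function(col) sprintf("%.17g", col)),
                   check.names = FALSE)
  names(df) <- c("gene_id", colnames(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a clinical table mapping sample to tumor stage
#'
#' TSV with columns `sample_id` and `stage`; rows whose stage is neither
#' `"I"` nor `"IV"` are dropped with a warning.
#'
#' @param path path to the TSV file.
#' @return named character vector sample_id -> stage.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", stringsAsFactors = FALSE)
  need <- c("sample_id", "stage")
  if (!all(need %in% names(df)))
    stopf("%s: clinical table must have columns %s", path,
          paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stopf("%s: duplicate sample ids", path)
  keep <- df$stage %in% c("I", "IV")
  if (any(!keep))
    warnf("%s: dropping %d sample(s) with stage outside {I, IV}",
          path, sum(!keep))
  stats::setNames(df$stage[keep], df$sample_id[keep])
}

## writer used by the simulator's CLI output
write_clinical <- function(stage, path) {
  df <- data.frame(sample_id = names(stage), stage = as.character(stage))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' line are counted once (set semantics).
#'
#' @param path path to the GMT file.
#' @return named list of character vectors (set name -> unique genes).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stopf("%s: empty GMT file", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stopf("%s: line %d has %d field(s); GMT requires name, description and >=1 gene",
          path, short[1L], lengths(fields)[short[1L]])
  nm <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(nm)) stopf("%s: duplicate set name(s)", path)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of per-set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, desc, genes) {
    paste(c(nm, desc, genes), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Align expression, CNV and methylation matrices with clinical stages
#'
#' Takes the intersection of gene and sample identifiers across the three
#' matrices, drops samples without a stage label, orders genes and samples
#' lexicographically (fixed C collation) and returns a validated dataset.
#' Counts of retained/dropped identifiers are reported via `message()`.
#'
#' @param expression,cnv,methylation labeled numeric matrices
#'   (see [read_omics_matrix()]).
#' @param clinical named character vector sample -> stage
#'   (see [read_clinical()]).
#' @return an [omics_dataset()].
#' @export
align_dataset <- function(expression, cnv, methylation, clinical) {
  genes <- Reduce(intersect, list(rownames(expression), rownames(cnv),
                                  rownames(methylation)))
  samples <- Reduce(intersect, list(colnames(expression), colnames(cnv),
                                    colnames(methylation)))
  n_samp_mat <- length(samples)
  samples <- intersect(samples, names(clinical))
  if (!length(genes) || !length(samples))
    stopf("alignment produced an empty gene or sample set")
  genes <- lex_sort(genes)
  samples <- lex_sort(samples)
  all_genes <- unique(c(rownames(expression), rownames(cnv),
                        rownames(methylation)))
  message(sprintf(
    "align_dataset: retained %d/%d genes and %d samples (%d without stage label dropped)",
    length(genes), length(all_genes), length(samples),
    n_samp_mat - length(samples)))
  omics_dataset(
    expression[genes, samples, drop = FALSE],
    cnv[genes, samples, drop = FALSE],
    methylation[genes, samples, drop = FALSE],
    clinical[samples]
  )
}

#' Keep genes bound by more than `min_tfs` transcription factors
#'
#' Restricts the dataset and the TF map to genes whose number of binding TFs
#' strictly exceeds `min_tfs` (default 5), then removes TFs left without
#' targets. Removed TFs had no targets among the retained genes, so the
#' retained genes' degrees are unchanged and the filter is idempotent.
#'
#' @param dataset an [omics_dataset()].
#' @param map a [tf_target_map()] covering the dataset's genes.
#' @param min_tfs non-negative integer; genes with `degree > min_tfs` are
#'   kept (strict inequality).
#' @return list with elements `dataset` and `map`, both restricted.
#' @export
filter_genes_by_tf_count <- function(dataset, map, min_tfs = 5L) {
  stopifnot(min_tfs >= 0)
  genes <- dataset_genes(dataset)
  cur <- restrict_map(map, genes)
  deg <- tf_degree(cur)
  keep <- names(deg)[deg > min_tfs]
  if (!length(keep))
    stopf("no gene is bound by more than %d TFs", min_tfs)
  cur <- restrict_map(cur, keep)
  ds <- subset_dataset(dataset, genes = keep, min_per_stage = 2L)
  list(dataset = ds, map = cur)
}

#' Read a dataset directory written by [write_dataset_dir()]
#'
#' The directory layout is `expression.tsv`, `cnv.tsv`, `methylation.tsv`,
#' `clinical.tsv` and `tf_sets.gmt`.
#'
#' @param dir directory path.
#' @param min_tfs if not `NULL`, apply [filter_genes_by_tf_count()] with this
#'   threshold after alignment.
#' @return list with `dataset` and `map`.
#' @export
read_dataset_dir <- function(dir, min_tfs = NULL) {
  expr <- read_omics_matrix(file.path(dir, "expression.tsv"), "expression")
  cnv <- read_omics_matrix(file.path(dir, "cnv.tsv"), "cnv")
  meth <- read_omics_matrix(file.path(dir, "methylation.tsv"), "methylation")
  clin <- read_clinical(file.path(dir, "clinical.tsv"))
  ds <- align_dataset(expr, cnv, meth, clin)
  sets <- read_gmt(file.path(dir, "tf_sets.gmt"))
  map <- merge_duplicate_tfs(sets, dataset_genes(ds))
  if (!is.null(min_tfs)) {
    out <- filter_genes_by_tf_count(ds, map, min_tfs)
    return(out)
  }
  list(dataset = ds, map = restrict_map(map, dataset_genes(ds)))
}

#' Write a dataset (and optionally its TF map) as a directory of text files
#' @param dataset an [omics_dataset()].
#' @param dir output directory (created if absent).
#' @param map optional [tf_target_map()]; written as `tf_sets.gmt` with one
#'   line per merged TF entry.
#' @return `dir`, invisibly.
#' @export
write_dataset_dir <- function(dataset, dir, map = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_omics_matrix(dataset$expression, file.path(dir, "expression.tsv"))
  write_omics_matrix(dataset$cnv, file.path(dir, "cnv.tsv"))
  write_omics_matrix(dataset$methylation, file.path(dir, "methylation.tsv"))
  write_clinical(dataset$stage, file.path(dir, "clinical.tsv"))
  if (!is.null(map)) {
    sets <- lapply(map$tf_ids, function(tf) map$gene_ids[map$incidence[tf, ] != 0])
    names(sets) <- map$tf_ids
    write_gmt(sets, file.path(dir, "tf_sets.gmt"))
  }
  invisible(dir)
}
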