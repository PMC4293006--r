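#' TF-target incidence map
#'
#' Binary TF x gene incidence matrix (B_fi = 1 when TF f has a predicted
#' binding site for gene i), with a provenance record listing the source set
#' names merged into each TF entry. Invariants enforced: entries are 0/1,
#' no two TFs share an identical target set, and every TF targets at least
#' one gene of the universe.
#'
#' @param incidence a TF x gene matrix (base or `Matrix` sparse) of 0/1
#'   values, with TF rownames and gene colnames.
#' @param provenance named list mapping each TF id to the character vector of
#'   source set names it was merged from; defaults to the TF ids themselves.
#' @param check_duplicates reject TFs with identical target sets (default
#'   `TRUE`; [restrict_map()] disables it, since restricting a merged map to
#'   a gene subset can legitimately make distinct target sets coincide).
#' @return an object of class `TFTargetMap`: list with `incidence` (sparse
#'   `dgCMatrix`), `tf_ids`, `gene_ids`, `provenance`.
#' @seealso [merge_duplicate_tfs()] to build one from raw GMT sets.
#' @export
tf_target_map <- function(incidence, provenance = NULL,
                          check_duplicates = TRUE) {
  inc <- methods::as(methods::as(Matrix::Matrix(incidence, sparse = TRUE),
                                 "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(inc)) || is.null(colnames(inc)))
    stopf("incidence must have TF rownames and gene colnames")
  vals <- inc@x
  if (length(vals) && !all(vals %in% c(0, 1)))
    stopf("incidence entries must be 0 or 1")
  inc <- Matrix::drop0(inc)
  deg <- Matrix::rowSums(inc)
  if (any(deg == 0))
    stopf("TF(s) with no target in the gene universe: %s",
          paste(utils::head(rownames(inc)[deg == 0], 5), collapse = ", "))
  if (check_duplicates) {
    key <- apply(inc, 1, function(r) paste(which(r != 0), collapse = ","))
    if (anyDuplicated(key))
      stopf("TFs with identical target sets must be merged first: %s",
            paste(utils::head(rownames(inc)[duplicated(key)], 5), collapse = ", "))
  }
  if (is.null(provenance)) {
    provenance <- as.list(rownames(inc))
    names(provenance) <- rownames(inc)
  }
  structure(
    list(incidence = inc, tf_ids = rownames(inc), gene_ids = colnames(inc),
         provenance = provenance),
    class = "TFTargetMap"
  )
}

#' @export
print.TFTargetMap <- function(x, ...) {
  cat(sprintf("TFTargetMap: %d TFs x %d genes, %d binding edges\n",
              length(x$tf_ids), length(x$gene_ids),
              length(x$incidence@x)))
  invisible(x)
}

#' Number of binding TFs per gene
#' @param map a [tf_target_map()].
#' @return named integer vector over genes.
#' @export
tf_degree <- function(map) {
  d <- Matrix::colSums(map$incidence)
  stats::setNames(as.integer(d), map$gene_ids)
}

#' Merge TFs with identical target sets into a single map
#'
#' Restricts each raw gene set to the supplied gene universe, drops sets left
#' empty, merges sets that become identical (merged id = sorted source names
#' joined by `"/"`), and builds the binary incidence matrix over the
#' universe.
#'
#' @param sets named list of character vectors (TF name -> target genes), as
#'   returned by [read_gmt()].
#' @param gene_universe character vector of genes the incidence is built
#'   against (column order of the result).
#' @return a [tf_target_map()] whose `provenance` records the source set
#'   names behind each merged TF.
#' @export
merge_duplicate_tfs <- function(sets, gene_universe) {
  if (length(sets) == 0L) stopf("no TF sets supplied")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stopf("TF sets must be named")
  if (anyDuplicated(names(sets))) stopf("duplicate TF set names")
  restricted <- lapply(sets, function(g) lex_sort(unique(intersect(g, gene_universe))))
  keep <- lengths(restricted) > 0L
  if (!any(keep)) stopf("no TF set has any target in the gene universe")
  restricted <- restricted[keep]
  key <- vapply(restricted, paste, "", collapse = "\r")
  groups <- split(names(restricted), key)
  merged_ids <- vapply(groups, function(src) paste(lex_sort(src), collapse = "/"), "")
  ord <- order(merged_ids, method = "radix")
  groups <- groups[ord]
  merged_ids <- merged_ids[ord]
  targets <- restricted[vapply(groups, `[`, "", 1L)]
  gi <- seq_along(gene_universe)
  names(gi) <- gene_universe
  rows <- rep.int(seq_along(targets), lengths(targets))
  cols <- gi[unlist(targets, use.names = FALSE)]
  inc <- Matrix::sparseMatrix(
    i = rows, j = cols, x = 1,
    dims = c(length(targets), length(gene_universe)),
    dimnames = list(merged_ids, gene_universe)
  )
  provenance <- groups
  names(provenance) <- merged_ids
  tf_target_map(inc, provenance = provenance)
}

#' Restrict a map to a subset of genes
#'
#' Keeps the given genes (in the given order) and drops TFs left with zero
#' targets. TF identities are preserved; target sets of distinct TFs may
#' coincide after restriction (the fitting code tolerates the resulting
#' collinearity via its ridge fallback).
#'
#' @param map a [tf_target_map()].
#' @param genes character vector of genes to keep (result column order).
#' @return a [tf_target_map()] over `genes`.
#' @export
restrict_map <- function(map, genes) {
  missing <- setdiff(genes, map$gene_ids)
  if (length(missing))
    stopf("genes absent from the TF map: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  inc <- map$incidence[, genes, drop = FALSE]
  deg <- Matrix::rowSums(inc)
  inc <- inc[deg > 0, , drop = FALSE]
  if (nrow(inc) == 0L) stopf("no TF retains a target after restriction")
  tf_target_map(inc, provenance = map$provenance[rownames(inc)],
                check_duplicates = FALSE)
}
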