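# Cell QC, log-normalization and scaling.
#
# Conventions: natural log with pseudo-count 1 and scale factor 1e4;
# sample (n-1) standard deviation everywhere; sd = 0 maps to 0 rather than
# NaN; scaled values clipped to +/- 10 to limit outlier dominance in the
# thresholded analyses downstream.

#' Compute per-cell QC metrics
#'
#' For each cell, the number of detected genes (count > 0) and the
#' mitochondrial percentage `100 * mito counts / total counts`. Cells with a
#' zero total get `pct_mito = 0` with a warning.
#'
#' @param matrix sparse cells x genes count matrix.
#' @param genes gene annotation with columns `gene_id` and `is_mito`.
#' @return Data frame with `cell_id`, `n_genes_detected`, `pct_mito`.
#' @export
compute_cell_qc <- function(matrix, genes) {
  .check_count_matrix(matrix)
  if (!"is_mito" %in% names(genes))
    .stopf("gene annotation must carry an is_mito flag")
  mito <- genes$gene_id[genes$is_mito]
  n_det <- Matrix::rowSums(matrix > 0)
  total <- Matrix::rowSums(matrix)
  mito_tot <- if (length(mito)) {
    Matrix::rowSums(matrix[, colnames(matrix) %in% mito, drop = FALSE])
  } else rep(0, nrow(matrix))
  pct <- ifelse(total > 0, 100 * mito_tot / total, 0)
  if (any(total == 0))
    .warnf("%d cell(s) have zero total counts; pct_mito set to 0",
           sum(total == 0))
  data.frame(cell_id = rownames(matrix), n_genes_detected = as.integer(n_det),
             pct_mito = as.numeric(pct), stringsAsFactors = FALSE)
}

#' Filter cells on QC thresholds
#'
#' Keeps cells with `min_genes <= n_genes_detected <= max_genes` and
#' `pct_mito <= max_pct_mito`. Boundaries are inclusive: the removal rules
#' are strict ("fewer than 200 genes", "more than 2500 genes", "more than 5
#' percent mitochondrial"), so a cell sitting exactly on a threshold is kept.
#' Cell order is preserved and the filter is idempotent.
#'
#' @param matrix sparse cells x genes count matrix.
#' @param qc QC table from [compute_cell_qc()], aligned to `matrix`.
#' @param min_genes,max_genes detected-gene bounds.
#' @param max_pct_mito mitochondrial percentage bound.
#' @return The filtered count matrix (possibly with zero rows, with a
#'   warning).
#' @export
filter_cells <- function(matrix, qc, min_genes = 200, max_genes = 2500,
                         max_pct_mito = 5.0) {
  if (!identical(qc$cell_id, rownames(matrix)))
    .stopf("qc table is not aligned to the matrix cells")
  keep <- qc$n_genes_detected >= min_genes & qc$n_genes_detected <= max_genes &
    qc$pct_mito <= max_pct_mito
  if (!any(keep)) .warnf("all cells removed by QC filters")
  matrix[keep, , drop = FALSE]
}

#' Log-normalize a count matrix
#'
#' `value = ln(1 + count * scale_factor / cell_total)`. Zeros stay zeros and
#' the transform is invariant to uniform scaling of a cell's counts.
#'
#' @param matrix sparse cells x genes count matrix with no zero-total cells
#'   (filter first).
#' @param scale_factor counts-per-scale-factor target, default 1e4.
#' @return Sparse cells x genes matrix of log-normalized values, with the
#'   scale factor recorded in attribute `scale_factor`.
#' @export
log_normalize <- function(matrix, scale_factor = 1e4) {
  .check_count_matrix(matrix)
  total <- Matrix::rowSums(matrix)
  if (any(total == 0))
    .stopf("cell(s) with zero total counts: %s",
           paste(utils::head(rownames(matrix)[total == 0], 3), collapse = ", "))
  y <- .as_dgc(matrix)
  y@x <- log1p(y@x * scale_factor / total[y@i + 1L])
  attr(y, "scale_factor") <- scale_factor
  y
}

#' Z-score genes across cells
#'
#' Per gene: subtract the mean and divide by the sample (n-1) standard
#' deviation over cells; genes with zero variance are set to 0; values are
#' clipped to `[-clip, +clip]`.
#'
#' @param norm log-normalized cells x genes matrix.
#' @param clip clipping bound, default 10.
#' @return Dense cells x genes matrix of scaled values.
#' @export
scale_genes <- function(norm, clip = 10) {
  if (nrow(norm) < 2) .stopf("scale_genes needs at least 2 cells")
  x <- as.matrix(norm)
  mu <- colMeans(x)
  sd <- .col_sds(x)
  out <- sweep(x, 2, mu, "-")
  nz <- sd > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, sd[nz], "/")
  out[, !nz] <- 0
  pmin(pmax(out, -clip), clip)
}

#' Select highly variable genes
#'
#' Ranks genes by the biological component of their variance (a fitted
#' mean-variance trend on log-normalized expression, via scran) and returns
#' the top `n`. Restricting scaling and PCA to these genes is the standard
#' step that keeps uninformative genes from drowning the cluster structure.
#'
#' @param norm log-normalized cells x genes matrix.
#' @param n number of genes to keep.
#' @return Character vector of gene ids, by decreasing biological variance.
#' @export
select_variable_genes <- function(norm, n = 1000) {
  dec <- scran::modelGeneVar(Matrix::t(norm))
  scran::getTopHVGs(dec, n = min(n, ncol(norm)))
}

#' Scaled average expression per cluster
#'
#' Per-cluster mean of log-normalized values, then z-scored across clusters
#' per gene (sample sd; sd = 0 maps to 0). This is the quantity thresholded
#' at > 0 for enhancer-gene and marker-constraint cluster queries.
#'
#' @param norm log-normalized cells x genes matrix.
#' @param clusters per-cell cluster labels (named vector or factor).
#' @return Dense clusters x genes matrix; empty clusters are excluded with a
#'   warning.
#' @export
scaled_average_expression <- function(norm, clusters) {
  cl <- .as_clusters(clusters, rownames(norm))
  empty <- if (is.factor(clusters)) setdiff(levels(clusters), levels(cl))
           else character(0)
  if (length(empty))
    .warnf("excluding cluster(s) with 0 cells: %s",
           paste(empty, collapse = ", "))
  means <- .cluster_means(norm, cl)
  .zscore_cols(means)
}
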