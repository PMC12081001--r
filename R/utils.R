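# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @importFrom methods as is
.as_dgc <- function(x) {
  if (is(x, "dgCMatrix")) return(x)
  as(as(as(x, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

# Validate a cells x genes count matrix: sparse, non-negative integral entries,
# unique dimnames on both axes.
.check_count_matrix <- function(x, what = "count matrix") {
  if (is.null(rownames(x)) || is.null(colnames(x)))
    .stopf("%s must carry cell and gene ids as dimnames", what)
  if (anyDuplicated(rownames(x))) .stopf("%s has duplicate cell ids", what)
  if (anyDuplicated(colnames(x))) .stopf("%s has duplicate gene ids", what)
  v <- if (is(x, "sparseMatrix")) x@x else as.vector(x)
  if (length(v) && (min(v) < 0 || any(v != floor(v))))
    .stopf("%s must contain non-negative integer entries", what)
  invisible(x)
}

# Coerce a per-cell cluster labeling (factor, integer or character vector,
# optionally named by cell id) to a factor aligned to `cell_ids`.
.as_clusters <- function(clusters, cell_ids) {
  if (!is.null(names(clusters))) {
    missing <- setdiff(cell_ids, names(clusters))
    if (length(missing))
      .stopf("cluster assignment missing %d cells (first: %s)",
             length(missing), missing[1])
    clusters <- clusters[cell_ids]
  } else if (length(clusters) != length(cell_ids)) {
    .stopf("cluster assignment length (%d) != number of cells (%d)",
           length(clusters), length(cell_ids))
  }
  if (is.factor(clusters)) droplevels(clusters) else factor(clusters)
}

# Column-wise sample standard deviation of a dense or sparse matrix.
.col_sds <- function(x) {
  n <- nrow(x)
  if (n < 2) return(rep(0, ncol(x)))
  mu <- Matrix::colMeans(x)
  ssq <- Matrix::colSums(x^2)
  v <- (ssq - n * mu^2) / (n - 1)
  sqrt(pmax(v, 0))
}

# z-score columns with the sample-sd convention; sd == 0 columns become 0.
.zscore_cols <- function(m, clip = NULL) {
  mu <- colMeans(m)
  sd <- apply(m, 2, stats::sd)
  sd[is.na(sd)] <- 0   # single observation: no spread
  out <- sweep(m, 2, mu, "-")
  nz <- sd > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, sd[nz], "/")
  out[, !nz] <- 0
  if (!is.null(clip)) out <- pmin(pmax(out, -clip), clip)
  out
}

# Per-cluster mean of a cells x genes matrix -> clusters x genes dense matrix.
.cluster_means <- function(x, clusters) {
  cl <- .as_clusters(clusters, rownames(x))
  ind <- Matrix::sparseMatrix(i = seq_along(cl), j = as.integer(cl),
                              x = 1, dims = c(length(cl), nlevels(cl)))
  sums <- as.matrix(Matrix::crossprod(ind, x))
  m <- sums / as.vector(table(cl))
  rownames(m) <- levels(cl)
  colnames(m) <- colnames(x)
  m
}
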