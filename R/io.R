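# Readers and writers for the on-disk formats the pipeline touches:
# Matrix Market count bundles (10x-style), TSV result tables, JSON reports.
#
# Canonical internal orientation is cells x genes; the on-disk MTX bundle is
# genes x cells (the 10x convention) and conversion happens at the boundary.

#' Write a simulated atlas as a 10x-style Matrix Market bundle
#'
#' Writes `matrix.mtx` (genes x cells, 1-based coordinate format),
#' `features.tsv` (gene id, symbol, type), `barcodes.tsv`, per-cell
#' `metadata.tsv`, the full gene annotation as `genes.tsv`, and the planted
#' ground truth as `truth.json`.
#'
#' @param atlas a `sim_atlas` from [generate_atlas()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the directory path.
#' @export
write_atlas_bundle <- function(atlas, dir) {
  if (!inherits(atlas, "sim_atlas")) .stopf("atlas must be a sim_atlas")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::t(atlas$counts), file.path(dir, "matrix.mtx"))
  feat <- data.frame(atlas$genes$gene_id, atlas$genes$symbol,
                     "Gene Expression")
  utils::write.table(feat, file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(rownames(atlas$counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(atlas$cells, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(atlas$genes, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- atlas$truth
  truth$codes <- lapply(truth$codes, function(m)
    list(cluster = rownames(m), tf = colnames(m), bits = unname(m)))
  jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Read a Matrix Market count bundle
#'
#' Reads `matrix.mtx` + `features.tsv` + `barcodes.tsv` (and, when present,
#' `metadata.tsv` and `genes.tsv`) from a directory. The MTX file may be
#' stored genes x cells (the 10x convention, the default) or cells x genes;
#' the orientation flag says which. 1-based MTX indices are handled by the
#' Matrix Market reader; the returned matrix is always cells x genes.
#'
#' @param dir directory containing the bundle.
#' @param orientation `"genes_by_cells"` (default) or `"cells_by_genes"`:
#'   the orientation of the on-disk matrix.
#' @return A list with `counts` (sparse cells x genes matrix), `genes`
#'   (annotation data frame; role columns when `genes.tsv` is present) and
#'   `cells` (metadata data frame or `NULL`).
#' @export
read_mtx_bundle <- function(dir,
                            orientation = c("genes_by_cells",
                                            "cells_by_genes")) {
  orientation <- match.arg(orientation)
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    .stopf("bundle is missing: %s", paste(basename(missing), collapse = ", "))
  m <- Matrix::readMM(paths[1])
  if (length(m@x) && any(m@x != floor(m@x)))
    .stopf("format error: matrix.mtx has non-integer entries")
  feat <- utils::read.table(paths[2], sep = "\t", header = FALSE,
                            quote = "", comment.char = "",
                            stringsAsFactors = FALSE)
  barcodes <- readLines(paths[3])
  n_genes_disk <- if (orientation == "genes_by_cells") nrow(m) else ncol(m)
  n_cells_disk <- if (orientation == "genes_by_cells") ncol(m) else nrow(m)
  if (nrow(feat) != n_genes_disk)
    .stopf("format error: features.tsv has %d rows but header says %d genes",
           nrow(feat), n_genes_disk)
  if (length(barcodes) != n_cells_disk)
    .stopf("format error: barcodes.tsv has %d lines but header says %d cells",
           length(barcodes), n_cells_disk)
  if (orientation == "genes_by_cells") m <- Matrix::t(m)
  m <- .as_dgc(m)
  dimnames(m) <- list(barcodes, feat[[1]])
  .check_count_matrix(m, "matrix.mtx")
  genes_path <- file.path(dir, "genes.tsv")
  genes <- if (file.exists(genes_path)) {
    utils::read.table(genes_path, sep = "\t", header = TRUE, quote = "",
                      comment.char = "", stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = feat[[1]],
               symbol = if (ncol(feat) >= 2) feat[[2]] else feat[[1]],
               stringsAsFactors = FALSE)
  }
  meta_path <- file.path(dir, "metadata.tsv")
  cells <- if (file.exists(meta_path)) {
    utils::read.table(meta_path, sep = "\t", header = TRUE, quote = "",
                      comment.char = "", stringsAsFactors = FALSE)
  } else NULL
  list(counts = m, genes = genes, cells = cells)
}

# ---- result tables -----------------------------------------------------------

.format_num <- function(x) {
  if (is.double(x)) signif(x, 6) else x
}

.sort_table <- function(df) {
  keys <- intersect(c("cluster", "cluster_id", "gene", "gene_id",
                      "neuropeptide", "combination"), names(df))
  if (length(keys)) df <- df[do.call(order, df[keys]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write result tables to TSV
#'
#' Writes each named object of `objects` to `<dir>/<name>.tsv`. Data frames
#' are written with a header row, numeric columns at 6 significant digits and
#' deterministic row order (cluster id, then gene id, where present).
#' Binary-code objects are written with a leading `cluster` column followed
#' by one 0/1 column per TF; plain matrices (e.g. Jaccard matrices) with a
#' leading `cluster` column and one column per cluster.
#'
#' @param objects named list of data frames, `binary_code` objects and
#'   matrices.
#' @param dir output directory (created if absent).
#' @return Invisibly, the written file paths.
#' @export
write_tables <- function(objects, dir) {
  if (is.null(names(objects)) || any(names(objects) == ""))
    .stopf("objects must be a fully named list")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(objects)) {
    obj <- objects[[nm]]
    path <- file.path(dir, paste0(nm, ".tsv"))
    if (inherits(obj, "binary_code")) {
      df <- data.frame(cluster = rownames(obj$matrix), obj$matrix,
                       check.names = FALSE, stringsAsFactors = FALSE)
    } else if (is.matrix(obj)) {
      df <- data.frame(cluster = rownames(obj), obj,
                       check.names = FALSE, stringsAsFactors = FALSE)
    } else if (is.data.frame(obj)) {
      df <- .sort_table(obj)
      df[] <- lapply(df, .format_num)
    } else {
      .stopf("cannot serialize object '%s' of class %s", nm, class(obj)[1])
    }
    ok <- tryCatch({
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) .stopf("I/O error: cannot write %s", path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a result table written by [write_tables()]
#'
#' @param path TSV file path.
#' @return A data frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Read a binary TF code table written by [write_tables()]
#'
#' @param path TSV file path.
#' @param tf_class TF class label to attach.
#' @return A `binary_code` object.
#' @export
read_binary_code <- function(path, tf_class = "unknown") {
  df <- read_table_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "integer"
  new_binary_code(m, tf_class)
}
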