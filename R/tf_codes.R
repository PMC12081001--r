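# Binarized TF combinatorial-code analysis: per-class uniqueness, Jaccard
# similarity, similarity ordering and shared-code groups.

#' Construct a binary code object
#'
#' @param matrix clusters x TFs matrix with entries in \{0, 1\}.
#' @param tf_class TF class label.
#' @return A `binary_code` object.
#' @export
new_binary_code <- function(matrix, tf_class) {
  if (!all(matrix %in% c(0L, 1L)))
    .stopf("binary code entries must be 0/1")
  storage.mode(matrix) <- "integer"
  structure(list(tf_class = tf_class, matrix = matrix,
                 cluster_ids = rownames(matrix), tf_ids = colnames(matrix)),
            class = "binary_code")
}

#' Binarize TF markers into a combinatorial code
#'
#' For one TF structural class, entry (cluster, TF) is 1 iff the TF is a
#' significant positive marker of the cluster (`p_adj < alpha` in a
#' positive-mode marker table); TFs that are markers of no cluster are
#' retained as all-zero columns so the code matrix always spans the whole
#' class.
#'
#' @param markers positive-mode marker table from [rank_markers()].
#' @param genes gene annotation with a `tf_class` column.
#' @param tf_class the class to binarize.
#' @param alpha adjusted-p cutoff.
#' @param cluster_ids cluster universe; defaults to the clusters present in
#'   the marker table.
#' @return A `binary_code` object (clusters x TFs).
#' @export
binarize_tf_markers <- function(markers, genes, tf_class, alpha = 0.05,
                                cluster_ids = NULL) {
  tfs <- genes$gene_id[genes$tf_class == tf_class]
  if (!length(tfs)) .stopf("no TFs of class '%s' in the annotation", tf_class)
  if (is.null(cluster_ids)) cluster_ids <- sort(unique(markers$cluster))
  cluster_ids <- as.character(cluster_ids)
  m <- matrix(0L, length(cluster_ids), length(tfs),
              dimnames = list(cluster_ids, tfs))
  sig <- markers[markers$gene %in% tfs & markers$p_adj < alpha, , drop = FALSE]
  if (nrow(sig))
    m[cbind(match(as.character(sig$cluster), cluster_ids),
            match(sig$gene, tfs))] <- 1L
  new_binary_code(m, tf_class)
}

.code_keys <- function(code) {
  apply(code$matrix, 1, paste, collapse = "")
}

#' Count clusters with unique TF codes
#'
#' A cluster is unique iff no other cluster has an identical code row;
#' `pct_unique = 100 * n_unique / n_clusters`, reported to one decimal.
#'
#' @param code a `binary_code`.
#' @return List with `n_unique` and `pct_unique`.
#' @export
count_unique_codes <- function(code) {
  keys <- .code_keys(code)
  if (!length(keys)) .stopf("code has no clusters")
  tab <- table(keys)
  n_unique <- sum(keys %in% names(tab)[tab == 1])
  list(n_unique = as.integer(n_unique),
       pct_unique = round(100 * n_unique / length(keys), 1))
}

#' Groups of clusters sharing an identical TF code
#'
#' Partition of the non-unique clusters into identical-row groups (size at
#' least 2), sorted by smallest member id.
#'
#' @param code a `binary_code`.
#' @return List of character vectors of cluster ids.
#' @export
shared_code_groups <- function(code) {
  keys <- .code_keys(code)
  groups <- split(rownames(code$matrix), keys)
  groups <- groups[vapply(groups, length, integer(1)) >= 2]
  groups <- lapply(groups, function(g) g[order(suppressWarnings(
    ifelse(is.na(as.numeric(g)), Inf, as.numeric(g))), g)])
  first <- vapply(groups, `[`, character(1), 1)
  ord <- order(suppressWarnings(
    ifelse(is.na(as.numeric(first)), Inf, as.numeric(first))), first)
  unname(groups[ord])
}

#' Jaccard similarity between cluster TF codes
#'
#' `J(a, b) = |Sa intersect Sb| / |Sa union Sb|` over the clusters' "on"-TF
#' sets. A pair of clusters that are both empty has identical (empty) codes
#' and is defined as `J = 1`.
#'
#' @param code a `binary_code`.
#' @return Symmetric clusters x clusters matrix with unit diagonal.
#' @export
jaccard_matrix <- function(code) {
  m <- code$matrix
  inter <- tcrossprod(m)
  sz <- rowSums(m)
  uni <- outer(sz, sz, "+") - inter
  j <- ifelse(uni > 0, inter / uni, 1)
  diag(j) <- 1
  dimnames(j) <- list(rownames(m), rownames(m))
  j
}

#' Order clusters by Jaccard similarity
#'
#' Average-linkage hierarchical clustering on the distance `1 - J`; the
#' dendrogram leaf order is returned. Deterministic; clusters with identical
#' codes are adjacent in the order.
#'
#' @param jac a Jaccard matrix from [jaccard_matrix()].
#' @return Character vector of cluster ids in leaf order.
#' @export
order_by_similarity <- function(jac) {
  if (nrow(jac) < 2) .stopf("need at least 2 clusters to order")
  h <- stats::hclust(stats::as.dist(1 - jac), method = "average")
  rownames(jac)[h$order]
}
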