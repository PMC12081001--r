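# Embedding, graph clustering and one-vs-rest marker ranking.

#' Principal-component embedding of the scaled matrix
#'
#' Truncated PCA (via irlba for small component counts, exact SVD otherwise)
#' of the gene-scaled matrix. Deterministic given the seed; each component's
#' sign is fixed so that the loading with the largest magnitude is positive.
#'
#' @param scaled dense cells x genes matrix from [scale_genes()].
#' @param n_components number of components, must not exceed `min(dim)`.
#' @param seed integer seed (irlba initialization).
#' @return Dense cells x components score matrix.
#' @export
embed_pca <- function(scaled, n_components = 50, seed = 1) {
  d <- min(dim(scaled))
  if (n_components > d)
    .stopf("n_components = %d exceeds min(cells, genes) = %d", n_components, d)
  set.seed(seed)
  if (n_components <= d / 3 && d > 10) {
    fit <- irlba::prcomp_irlba(scaled, n = n_components, center = FALSE,
                               scale. = FALSE)
    scores <- fit$x
    rot <- fit$rotation
  } else {
    fit <- stats::prcomp(scaled, center = FALSE, scale. = FALSE)
    scores <- fit$x[, seq_len(n_components), drop = FALSE]
    rot <- fit$rotation[, seq_len(n_components), drop = FALSE]
  }
  # largest-loading-positive sign convention
  for (j in seq_len(ncol(scores))) {
    k <- which.max(abs(rot[, j]))
    if (rot[k, j] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- rownames(scaled)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  scores
}

#' Graph-based clustering of an embedding
#'
#' Builds a shared-nearest-neighbor graph (Jaccard-weighted, `k_neighbors`
#' neighbors) on the embedding and partitions it with Louvain modularity
#' community detection at the given resolution. Cluster ids are relabeled
#' `1..n_clusters` by decreasing size. Deterministic given the seed;
#' singleton communities are allowed.
#'
#' @param embedding cells x components matrix from [embed_pca()].
#' @param k_neighbors neighbors for the SNN graph.
#' @param resolution modularity resolution; larger values give more clusters.
#' @param seed integer seed.
#' @return Named integer vector of cluster ids (one per cell).
#' @export
cluster_cells <- function(embedding, k_neighbors = 15, resolution = 1.0,
                          seed = 1) {
  n <- nrow(embedding)
  if (n < k_neighbors + 1)
    .stopf("need at least k_neighbors + 1 = %d cells, have %d",
           k_neighbors + 1, n)
  if (all(embedding == rep(embedding[1, ], each = n))) {
    # zero-variance embedding: all cells identical, a single community
    return(stats::setNames(rep(1L, n), rownames(embedding)))
  }
  set.seed(seed)
  g <- bluster::makeSNNGraph(embedding, k = k_neighbors, type = "jaccard")
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(comm)
  sizes <- table(memb)
  relabel <- stats::setNames(seq_along(sizes),
                             names(sort(sizes, decreasing = TRUE)))
  out <- as.integer(relabel[as.character(memb)])
  names(out) <- rownames(embedding)
  out
}

# Exact two-sided rank-sum p-value by enumeration of all C(n, n1) group
# assignments over the observed (possibly tied) ranks. Used when both groups
# have at most 8 members.
.exact_ranksum_p <- function(ranks, n1) {
  n <- length(ranks)
  w_obs <- sum(ranks[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  dev <- abs(w_obs - mu)
  combos <- utils::combn(n, n1)
  w_all <- colSums(matrix(ranks[combos], nrow = n1))
  mean(abs(w_all - mu) >= dev - 1e-12)
}

# Tie-correction term sum(t^3 - t) per gene column of a sparse cells x genes
# matrix (ties among the nonzeros plus the block of zeros).
.tie_terms <- function(x) {
  n <- nrow(x)
  p <- x@p
  G <- ncol(x)
  out <- numeric(G)
  for (j in seq_len(G)) {
    nz <- p[j + 1] - p[j]
    n0 <- n - nz
    tt <- n0^3 - n0
    if (nz > 1) {
      v <- sort.int(x@x[(p[j] + 1):p[j + 1]], method = "quick")
      r <- rle(v)$lengths
      r <- r[r > 1]
      if (length(r)) tt <- tt + sum(r^3 - r)
    }
    out[j] <- tt
  }
  out
}

#' One-vs-rest Wilcoxon marker ranking
#'
#' For each cluster and each gene passing the prefilters, a two-sided
#' Wilcoxon rank-sum test of in-cluster vs all other cells on log-normalized
#' values, with Benjamini-Hochberg adjustment within each cluster over its
#' tested genes. The fold change is
#' `log2((mean(expm1(in)) + eps) / (mean(expm1(out)) + eps))` with
#' `eps = 1e-9`. In positive mode (the default) a gene is tested when
#' `pct_in >= min_pct` and `log2fc >= min_log2fc`; in signed mode when
#' either expressing fraction passes `min_pct` and `|log2fc| >= min_log2fc`.
#'
#' The normal approximation with tie correction and continuity correction is
#' used whenever either group exceeds 8 cells; below that the exact
#' enumeration distribution is used. Clusters with fewer than 3 cells are
#' skipped with a warning.
#'
#' @param norm log-normalized cells x genes matrix.
#' @param clusters per-cell cluster labels.
#' @param min_pct minimum expressing fraction prefilter.
#' @param min_log2fc minimum fold-change prefilter.
#' @param mode `"positive"` (enriched markers) or `"signed"` (both tails).
#' @return Data frame (`marker_table`) with columns `cluster`, `gene`,
#'   `log2fc`, `pct_in`, `pct_out`, `p_value`, `p_adj`, ordered by cluster
#'   then gene.
#' @export
rank_markers <- function(norm, clusters, min_pct = 0.1, min_log2fc = 0.25,
                         mode = c("positive", "signed")) {
  mode <- match.arg(mode)
  cl <- .as_clusters(clusters, rownames(norm))
  if (nlevels(cl) < 2) .stopf("rank_markers needs at least 2 clusters")
  x <- .as_dgc(norm)
  n <- nrow(x); G <- ncol(x)
  sizes <- as.vector(table(cl))
  small <- levels(cl)[sizes < 3]
  if (length(small))
    .warnf("skipping cluster(s) with fewer than 3 cells: %s",
           paste(small, collapse = ", "))

  ind <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(cl), x = 1,
                              dims = c(n, nlevels(cl)))
  e <- x; e@x <- expm1(e@x)
  sum_in <- as.matrix(Matrix::crossprod(ind, e))          # K x G
  tot <- Matrix::colSums(e)
  nz <- x; nz@x[] <- 1
  det_in <- as.matrix(Matrix::crossprod(ind, nz))
  det_tot <- Matrix::colSums(nz)

  ranks <- matrixStats::colRanks(as.matrix(x), ties.method = "average",
                                 preserveShape = TRUE)
  rank_in <- rowsum(ranks, as.integer(cl))                # K x G, rows 1..K
  ties <- .tie_terms(x)

  eps <- 1e-9
  out <- vector("list", nlevels(cl))
  for (k in seq_len(nlevels(cl))) {
    n1 <- sizes[k]
    if (n1 < 3) next
    n2 <- n - n1
    mean_in <- sum_in[k, ] / n1
    mean_out <- (tot - sum_in[k, ]) / n2
    pct_in <- det_in[k, ] / n1
    pct_out <- (det_tot - det_in[k, ]) / n2
    lfc <- log2((mean_in + eps) / (mean_out + eps))
    test <- if (mode == "positive") {
      pct_in >= min_pct & lfc >= min_log2fc
    } else {
      (pct_in >= min_pct | pct_out >= min_pct) & abs(lfc) >= min_log2fc
    }
    if (!any(test)) next
    jj <- which(test)
    if (n1 <= 8 && n2 <= 8) {
      pv <- vapply(jj, function(j) {
        r <- ranks[, j]
        in_first <- c(r[as.integer(cl) == k], r[as.integer(cl) != k])
        .exact_ranksum_p(in_first, n1)
      }, numeric(1))
    } else {
      w <- rank_in[k, jj]
      u <- w - n1 * (n1 + 1) / 2
      mu <- n1 * n2 / 2
      sig2 <- (n1 * n2 / 12) * ((n + 1) - ties[jj] / (n * (n - 1)))
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(pmax(sig2, 1e-300))
      z[sig2 <= 0] <- 0
      pv <- pmin(1, 2 * stats::pnorm(-abs(z)))
    }
    out[[k]] <- data.frame(cluster = levels(cl)[k], gene = colnames(x)[jj],
                           log2fc = lfc[jj], pct_in = pct_in[jj],
                           pct_out = pct_out[jj], p_value = pv,
                           p_adj = stats::p.adjust(pv, method = "BH"),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(cluster = character(0), gene = character(0),
                      log2fc = numeric(0), pct_in = numeric(0),
                      pct_out = numeric(0), p_value = numeric(0),
                      p_adj = numeric(0), stringsAsFactors = FALSE)
  res <- res[order(res$cluster, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("marker_table", "data.frame")
  res
}

#' Top markers per cluster
#'
#' Per cluster, genes sorted by ascending adjusted p-value, then descending
#' fold change, then gene id (a total order), returning the first `n`.
#'
#' @param table a marker table from [rank_markers()].
#' @param n markers per cluster.
#' @return Named list mapping cluster id to an ordered character vector of
#'   gene ids.
#' @export
top_markers <- function(table, n = 10) {
  if (!nrow(table)) .stopf("marker table is empty")
  split_tab <- split(table, table$cluster)
  lapply(split_tab, function(df) {
    df <- df[order(df$p_adj, -df$log2fc, df$gene), , drop = FALSE]
    utils::head(df$gene, n)
  })
}
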