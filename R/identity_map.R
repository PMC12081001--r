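# Cluster identity assignment: bulk-profile correlation, enhancer-gene
# co-expression, marker-constraint queries and glial marker panels.

#' Correlate cluster profiles with bulk reference profiles
#'
#' Pearson correlation between each cluster's mean log-normalized profile
#' and each bulk reference profile over a shared gene subset (by default the
#' `n_top_var` most variable genes across clusters). Zero-variance vectors
#' yield `NA` coefficients, flagged with a warning rather than dropped.
#'
#' @param cluster_profiles clusters x genes matrix of mean log-normalized
#'   expression (e.g. from cluster means of [log_normalize()] output).
#' @param reference a `bulk_reference` (see [generate_bulk_reference()]) or
#'   a genes x types numeric matrix.
#' @param gene_subset optional explicit gene subset.
#' @param n_top_var size of the most-variable-gene subset when
#'   `gene_subset` is `NULL`.
#' @return Clusters x types coefficient matrix.
#' @export
correlate_bulk <- function(cluster_profiles, reference, gene_subset = NULL,
                           n_top_var = 2000) {
  prof <- if (inherits(reference, "bulk_reference")) reference$profiles
          else reference
  shared <- intersect(colnames(cluster_profiles), rownames(prof))
  if (is.null(gene_subset)) {
    v <- matrixStats::colVars(cluster_profiles[, shared, drop = FALSE])
    gene_subset <- shared[order(-v)][seq_len(min(n_top_var, length(shared)))]
  } else {
    gene_subset <- intersect(gene_subset, shared)
  }
  if (length(gene_subset) < 3)
    .stopf("fewer than 3 shared genes after subsetting")
  a <- t(cluster_profiles[, gene_subset, drop = FALSE])  # genes x clusters
  b <- prof[gene_subset, , drop = FALSE]                 # genes x types
  sd_a <- .col_sds(a)
  sd_b <- .col_sds(b)
  out <- matrix(NA_real_, ncol(a), ncol(b),
                dimnames = list(colnames(a), colnames(b)))
  if (any(sd_a > 0) && any(sd_b > 0))
    out[sd_a > 0, sd_b > 0] <- stats::cor(a[, sd_a > 0, drop = FALSE],
                                          b[, sd_b > 0, drop = FALSE])
  if (any(sd_a == 0))
    .warnf("zero-variance cluster profile(s): %s",
           paste(colnames(a)[sd_a == 0], collapse = ", "))
  if (any(sd_b == 0))
    .warnf("zero-variance reference profile(s): %s",
           paste(colnames(b)[sd_b == 0], collapse = ", "))
  out
}

#' Assign cluster identities by maximal correlation
#'
#' Per cluster, the neuron type with the highest defined coefficient; exact
#' ties go to the earlier reference column (logged via warning). Multiple
#' clusters may share one type. Clusters whose coefficients are all
#' undefined are left unassigned with a warning.
#'
#' @param coefficients clusters x types matrix from [correlate_bulk()].
#' @return Data frame with `cluster_id`, `neuron_type`, `coefficient`,
#'   `method`.
#' @export
assign_identity_by_max <- function(coefficients) {
  out <- list()
  for (i in seq_len(nrow(coefficients))) {
    r <- coefficients[i, ]
    if (all(is.na(r))) {
      .warnf("cluster %s has no defined coefficient; unassigned",
             rownames(coefficients)[i])
      next
    }
    best <- which(r == max(r, na.rm = TRUE))
    if (length(best) > 1)
      .warnf("cluster %s: tie between %s; keeping the first",
             rownames(coefficients)[i],
             paste(colnames(coefficients)[best], collapse = ", "))
    j <- best[1]
    out[[length(out) + 1]] <- data.frame(
      cluster_id = rownames(coefficients)[i],
      neuron_type = colnames(coefficients)[j],
      coefficient = unname(r[j]), method = "bulk_correlation",
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(cluster_id = character(0), neuron_type = character(0),
               coefficient = numeric(0), method = character(0),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

.parse_driver_genes <- function(x) {
  if (is.list(x)) x else strsplit(x, ";", fixed = TRUE)
}

#' Map split-driver enhancer genes to candidate clusters
#'
#' A cluster is a candidate for a driver iff every enhancer gene of that
#' driver has scaled average expression > 0 in the cluster; candidates are
#' sorted by descending minimum scaled average over the driver's genes.
#' Adding a gene to a driver can only shrink its candidate set.
#'
#' @param scaled_avg clusters x genes matrix from
#'   [scaled_average_expression()].
#' @param drivers data frame with `driver_id`, `neuron_type` and
#'   `enhancer_genes` (semicolon-separated string or list of character
#'   vectors).
#' @return Named list mapping driver id to an ordered character vector of
#'   candidate cluster ids (empty when no cluster qualifies).
#' @export
map_enhancer_genes <- function(scaled_avg, drivers) {
  genes_by_driver <- .parse_driver_genes(drivers$enhancer_genes)
  out <- stats::setNames(vector("list", nrow(drivers)), drivers$driver_id)
  skipped <- logical(nrow(drivers))
  for (i in seq_len(nrow(drivers))) {
    g <- genes_by_driver[[i]]
    absent <- setdiff(g, colnames(scaled_avg))
    if (length(absent)) {
      .warnf("driver %s skipped: gene(s) absent from data: %s",
             drivers$driver_id[i], paste(absent, collapse = ", "))
      skipped[i] <- TRUE
      next
    }
    vals <- scaled_avg[, g, drop = FALSE]
    minv <- apply(vals, 1, min)
    cand <- rownames(scaled_avg)[minv > 0]
    out[[i]] <- cand[order(-minv[minv > 0], cand)]
  }
  out[!skipped]
}

#' Query clusters by signed marker constraints
#'
#' A cluster matches iff every `"+"` gene has scaled average expression > 0
#' and every `"-"` gene has scaled average <= 0. Optional `driver_genes` add
#' `"+"` constraints. An empty constraint list with no driver genes returns
#' all clusters with a warning.
#'
#' @param scaled_avg clusters x genes matrix from
#'   [scaled_average_expression()].
#' @param constraints data frame with columns `gene` and `sign` (`"+"` or
#'   `"-"`).
#' @param driver_genes optional genes added as `"+"` constraints.
#' @return Character vector of matching cluster ids, in deterministic
#'   cluster-id order.
#' @export
query_marker_constraints <- function(scaled_avg, constraints,
                                     driver_genes = NULL) {
  if (!is.null(driver_genes) && length(driver_genes)) {
    constraints <- rbind(constraints,
                         data.frame(gene = driver_genes, sign = "+",
                                    stringsAsFactors = FALSE))
  }
  if (is.null(constraints) || !nrow(constraints)) {
    .warnf("no constraints given; returning all clusters")
    return(rownames(scaled_avg))
  }
  if (!all(constraints$sign %in% c("+", "-")))
    .stopf("constraint signs must be '+' or '-'")
  absent <- setdiff(constraints$gene, colnames(scaled_avg))
  if (length(absent))
    .stopf("constraint gene(s) absent from data: %s",
           paste(absent, collapse = ", "))
  contradict <- intersect(constraints$gene[constraints$sign == "+"],
                          constraints$gene[constraints$sign == "-"])
  if (length(contradict)) {
    .warnf("contradictory constraints on gene(s): %s",
           paste(contradict, collapse = ", "))
    return(character(0))
  }
  ok <- rep(TRUE, nrow(scaled_avg))
  for (i in seq_len(nrow(constraints))) {
    v <- scaled_avg[, constraints$gene[i]]
    ok <- ok & if (constraints$sign[i] == "+") v > 0 else v <= 0
  }
  rownames(scaled_avg)[ok]
}

#' Select clusters positive for a single marker gene
#'
#' Clusters where the marker's mean log-normalized expression is at least
#' `min_mean` and the fraction of expressing cells at least `min_pct`; used
#' e.g. to subset repo+ clusters for glial re-clustering.
#'
#' @param norm log-normalized cells x genes matrix.
#' @param clusters per-cell cluster labels.
#' @param marker_gene marker gene id.
#' @param min_mean mean-expression cutoff.
#' @param min_pct expressing-fraction cutoff.
#' @return Character vector of selected cluster ids.
#' @export
select_marker_positive_clusters <- function(norm, clusters, marker_gene,
                                            min_mean = 1.0, min_pct = 0.5) {
  if (!marker_gene %in% colnames(norm))
    .stopf("marker gene '%s' not present", marker_gene)
  cl <- .as_clusters(clusters, rownames(norm))
  v <- norm[, marker_gene]
  mean_by <- tapply(v, cl, mean)
  pct_by <- tapply(v > 0, cl, mean)
  levels(cl)[mean_by >= min_mean & pct_by >= min_pct]
}

#' Annotate clusters by marker panels
#'
#' A cluster receives subtype S iff at least `min_positive_frac` of S's
#' panel genes have scaled average expression > 0 in the cluster. Multiple
#' qualifying subtypes are joined as `"A/B"` (overlapping identity); none
#' gives `"unannotated"`. Panel genes absent from the data are dropped from
#' their panel with a warning.
#'
#' @param scaled_avg clusters x genes matrix from
#'   [scaled_average_expression()].
#' @param panels named list mapping subtype to marker gene vector.
#' @param min_positive_frac fraction of panel genes that must be positive.
#' @return Named character vector mapping cluster id to subtype label.
#' @export
annotate_by_marker_panel <- function(scaled_avg, panels,
                                     min_positive_frac = 0.5) {
  if (!length(panels)) .stopf("panels must be nonempty")
  panels <- lapply(stats::setNames(names(panels), names(panels)), function(s) {
    g <- panels[[s]]
    absent <- setdiff(g, colnames(scaled_avg))
    if (length(absent))
      .warnf("panel '%s': dropping absent gene(s): %s", s,
             paste(absent, collapse = ", "))
    setdiff(g, absent)
  })
  panels <- panels[vapply(panels, length, integer(1)) > 0]
  out <- stats::setNames(rep("unannotated", nrow(scaled_avg)),
                         rownames(scaled_avg))
  for (cl in rownames(scaled_avg)) {
    hits <- names(panels)[vapply(panels, function(g)
      mean(scaled_avg[cl, g] > 0) >= min_positive_frac, logical(1))]
    if (length(hits)) out[cl] <- paste(hits, collapse = "/")
  }
  out
}
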