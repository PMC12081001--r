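# Neurotransmitter co-expression profiles and UpSet-style combination
# counting; cluster-defining neuropeptide selection; TF-neuropeptide
# correlation.

#' Classify cells by fast-acting neurotransmitter expression
#'
#' A cell carries a neurotransmitter role iff its expression of that role's
#' marker gene exceeds `threshold`. By default the threshold applies to
#' log-normalized values (the scale that defines the "none" class: no
#' transmitter with log-normalized expression above 2); setting
#' `scale = "scaled"` thresholds z-scored values instead.
#'
#' @param norm log-normalized cells x genes matrix.
#' @param genes gene annotation with an `nt_role` column naming the seven
#'   marker genes.
#' @param threshold expression threshold, default 2.0.
#' @param scale `"lognorm"` (default) or `"scaled"`.
#' @return An `nt_profile`: logical cells x roles matrix with the threshold
#'   and scale recorded as attributes.
#' @export
classify_neurotransmitters <- function(norm, genes, threshold = 2.0,
                                       scale = c("lognorm", "scaled")) {
  scale <- match.arg(scale)
  roles <- genes[genes$nt_role != "none", c("gene_id", "nt_role")]
  roles <- roles[match(.nt_roles, roles$nt_role), ]
  missing <- .nt_roles[is.na(roles$gene_id) |
                         !(roles$gene_id %in% colnames(norm))]
  if (length(missing))
    .stopf("missing neurotransmitter marker gene(s) for role(s): %s",
           paste(missing, collapse = ", "))
  x <- norm[, roles$gene_id, drop = FALSE]
  if (scale == "scaled") x <- scale_genes(x)
  prof <- as.matrix(x > threshold)
  colnames(prof) <- roles$nt_role
  rownames(prof) <- rownames(norm)
  structure(prof, threshold = threshold, scale = scale,
            class = c("nt_profile", class(prof)))
}

#' Count neurotransmitter co-expression combinations
#'
#' Exact count and percentage of cells per observed combination of
#' neurotransmitter roles (UpSet-style), including the empty combination,
#' labeled `"none"`. Rows are ordered by descending count, ties broken
#' lexicographically by combination label; percentages sum to 100.
#'
#' @param profile an `nt_profile` from [classify_neurotransmitters()].
#' @return Data frame with `combination`, `count`, `percentage`.
#' @export
coexpression_counts <- function(profile) {
  if (!nrow(profile)) .stopf("profile is empty")
  roles <- colnames(profile)
  combo <- apply(profile, 1, function(v) {
    s <- roles[v]
    if (!length(s)) "none" else paste(s, collapse = "+")
  })
  tab <- table(combo)
  df <- data.frame(combination = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df$percentage <- 100 * df$count / nrow(profile)
  df <- df[order(-df$count, df$combination), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Select cluster-defining neuropeptides
#'
#' A neuropeptide qualifies as cluster-defining iff it is a significant
#' positive marker (`p_adj < alpha`, `log2fc >= min_log2fc`) of at least one
#' and at most `max_clusters` clusters; enrichment in a small number of
#' clusters is what makes it usable as a cluster marker.
#'
#' @param markers a positive-mode marker table from [rank_markers()].
#' @param genes gene annotation with an `is_neuropeptide` flag.
#' @param max_clusters upper bound on qualifying clusters.
#' @param alpha adjusted-p cutoff.
#' @param min_log2fc fold-change cutoff.
#' @return Named list mapping each qualifying neuropeptide to its cluster
#'   ids.
#' @export
select_cluster_defining_np <- function(markers, genes, max_clusters = 5,
                                       alpha = 0.05, min_log2fc = 1) {
  nps <- genes$gene_id[genes$is_neuropeptide]
  sig <- markers[markers$gene %in% nps & markers$p_adj < alpha &
                   markers$log2fc >= min_log2fc, , drop = FALSE]
  out <- list()
  for (g in sort(unique(sig$gene))) {
    cls <- sort(unique(sig$cluster[sig$gene == g]))
    if (length(cls) >= 1 && length(cls) <= max_clusters) out[[g]] <- cls
  }
  out
}

#' Correlate transcription factors with neuropeptides across cells
#'
#' Correlation (Pearson by default) of each TF's log-normalized expression
#' vector with each neuropeptide's across all cells. TFs with zero variance
#' are excluded from the ranking; a zero-variance neuropeptide yields a row
#' of `NA` coefficients, flagged rather than dropped. Per neuropeptide the
#' `top_n` TFs by descending coefficient are reported, ties broken by gene
#' id.
#'
#' @param norm log-normalized cells x genes matrix (at least 3 cells).
#' @param genes gene annotation with `tf_class` and `is_neuropeptide`.
#' @param top_n TFs reported per neuropeptide.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A list of class `np_correlation`: `cor` (TF x NP coefficient
#'   matrix), `top` (data frame `neuropeptide`, `rank`, `tf`, `r`) and
#'   `undefined_np` (zero-variance neuropeptides).
#' @export
tf_np_correlation <- function(norm, genes, top_n = 5,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (nrow(norm) < 3) .stopf("need at least 3 cells")
  tfs <- intersect(genes$gene_id[genes$tf_class != "none"], colnames(norm))
  nps <- intersect(genes$gene_id[genes$is_neuropeptide], colnames(norm))
  if (!length(tfs) || !length(nps))
    .stopf("need at least 1 TF and 1 neuropeptide gene")
  tx <- as.matrix(norm[, tfs, drop = FALSE])
  nx <- as.matrix(norm[, nps, drop = FALSE])
  tf_sd <- .col_sds(tx)
  np_sd <- .col_sds(nx)
  keep_tf <- tf_sd > 0
  if (any(!keep_tf))
    .warnf("excluding zero-variance TF(s): %s",
           paste(tfs[!keep_tf], collapse = ", "))
  cmat <- matrix(NA_real_, length(tfs), length(nps),
                 dimnames = list(tfs, nps))
  if (any(keep_tf) && any(np_sd > 0)) {
    cmat[keep_tf, np_sd > 0] <-
      stats::cor(tx[, keep_tf, drop = FALSE],
                 nx[, np_sd > 0, drop = FALSE], method = method)
  }
  top <- list()
  for (g in nps) {
    r <- cmat[keep_tf, g]
    if (all(is.na(r))) next
    ord <- order(-r, names(r))
    sel <- utils::head(ord, top_n)
    top[[g]] <- data.frame(neuropeptide = g, rank = seq_along(sel),
                           tf = names(r)[sel], r = unname(r[sel]),
                           stringsAsFactors = FALSE)
  }
  top <- if (length(top)) do.call(rbind, top) else
    data.frame(neuropeptide = character(0), rank = integer(0),
               tf = character(0), r = numeric(0), stringsAsFactors = FALSE)
  rownames(top) <- NULL
  structure(list(cor = cmat, top = top, undefined_np = nps[np_sd == 0]),
            class = "np_correlation")
}
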