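# Transgene-based lineage assignment, sex-biased cluster detection and
# pseudobulk sex differential expression.

#' Assign T1/T2 lineage from transgene counts
#'
#' A cell is T2 iff any transgene (FLP, GFP, RFP) has a count of at least 1;
#' cells negative for all transgenes are T1 ("triple-negative"). Any UMI is
#' taken as evidence since nuclear transgene capture is sparse.
#'
#' @param matrix sparse cells x genes count matrix.
#' @param genes gene annotation with an `is_transgene` flag.
#' @return Named character vector of `"T1"` / `"T2"` per cell.
#' @export
assign_lineage <- function(matrix, genes) {
  tg <- genes$gene_id[genes$is_transgene]
  tg <- intersect(tg, colnames(matrix))
  if (!length(tg)) .stopf("no transgene genes present in the annotation/matrix")
  pos <- Matrix::rowSums(matrix[, tg, drop = FALSE] >= 1) > 0
  stats::setNames(ifelse(pos, "T2", "T1"), rownames(matrix))
}

#' Detect sex-biased clusters
#'
#' Cells from mixed-sex samples are excluded. With per-sex totals
#' `N_male` and `N_female`, the expected male proportion is
#' `q = N_male / (N_male + N_female)`; each cluster's male count is tested
#' against `q` with a two-sided exact binomial test, BH-adjusted over
#' clusters. Normalized counts scale the female count by `N_male / N_female`
#' (normalizing the number of input nuclei between the sexes), and
#' `log2_ratio = log2((n_male_norm + 0.5) / (n_female_norm + 0.5))`. A
#' cluster is called biased when `p_adj < alpha` and
#' `|log2_ratio| >= min_abs_log2_ratio`.
#'
#' @param annotation per-cell data frame with `cell_id` and `sex`
#'   (`"female"`, `"male"` or `"mixed"`).
#' @param clusters per-cell cluster labels (named vector or aligned to
#'   `annotation` rows).
#' @param alpha BH-adjusted significance level.
#' @param min_abs_log2_ratio fold cutoff on the normalized ratio.
#' @return Data frame with one row per cluster: raw and normalized counts,
#'   normalized male fraction, log2 ratio, p-values and the bias call.
#' @export
sex_bias_clusters <- function(annotation, clusters, alpha = 0.05,
                              min_abs_log2_ratio = 1.0) {
  cl <- .as_clusters(clusters, annotation$cell_id)
  keep <- annotation$sex %in% c("female", "male")
  if (!any(annotation$sex == "female") || !any(annotation$sex == "male"))
    .stopf("need at least one female-sample and one male-sample cell")
  sex <- annotation$sex[keep]
  cl <- droplevels(cl[keep])
  n_f_tot <- sum(sex == "female")
  n_m_tot <- sum(sex == "male")
  if (n_f_tot == 0 || n_m_tot == 0)
    .stopf("zero total cells in one sex after excluding mixed samples")
  q <- n_m_tot / (n_m_tot + n_f_tot)
  tab <- table(cl, sex)
  n_f <- as.vector(tab[, "female"])
  n_m <- as.vector(tab[, "male"])
  n_f_norm <- n_f * (n_m_tot / n_f_tot)
  n_m_norm <- n_m
  l2r <- log2((n_m_norm + 0.5) / (n_f_norm + 0.5))
  pv <- vapply(seq_along(n_m), function(i) {
    tot <- n_m[i] + n_f[i]
    if (tot == 0) return(1)
    stats::binom.test(n_m[i], tot, p = q)$p.value
  }, numeric(1))
  padj <- stats::p.adjust(pv, method = "BH")
  biased <- ifelse(padj < alpha & abs(l2r) >= min_abs_log2_ratio,
                   ifelse(l2r > 0, "male", "female"), "none")
  data.frame(cluster = levels(cl), n_female_raw = n_f, n_male_raw = n_m,
             n_female_norm = n_f_norm, n_male_norm = n_m_norm,
             male_fraction_norm = ifelse(n_m_norm + n_f_norm > 0,
                                         n_m_norm / (n_m_norm + n_f_norm), NA),
             log2_ratio = l2r, p_value = pv, p_adj = padj, biased = biased,
             stringsAsFactors = FALSE)
}

#' Pseudobulk differential expression between sexes
#'
#' Counts are summed per (cluster, sex) aggregate over female- and
#' male-sample cells (mixed samples excluded), converted to counts per
#' million within each aggregate, and compared per gene as the paired
#' per-cluster `log2((cpm_female + 1) / (cpm_male + 1))`. Genes are ranked
#' by the mean of this per-cluster fold change and tested with a two-sided
#' Wilcoxon signed-rank test across the paired clusters, BH-adjusted over
#' genes.
#'
#' @param matrix sparse cells x genes count matrix.
#' @param annotation per-cell data frame with `cell_id` and `sex`.
#' @param clusters per-cell cluster labels.
#' @return A list of class `pseudobulk_de`: `counts` (aggregate x gene sums,
#'   rownames `cluster:sex`), `cpm`, `log2fc` (cluster x gene female/male
#'   fold changes), and `genes` (per-gene `mean_log2fc`, `p_value`, `p_adj`).
#' @export
pseudobulk_sex_de <- function(matrix, annotation, clusters) {
  cl <- .as_clusters(clusters, annotation$cell_id)
  keep <- annotation$sex %in% c("female", "male")
  x <- matrix[keep, , drop = FALSE]
  sex <- annotation$sex[keep]
  cl <- droplevels(cl[keep])
  both <- levels(cl)[vapply(levels(cl), function(l)
    any(sex == "female" & cl == l) && any(sex == "male" & cl == l),
    logical(1))]
  if (length(both) < 2)
    .stopf("need at least 2 clusters containing both sexes, have %d",
           length(both))
  sel <- cl %in% both
  x <- x[sel, , drop = FALSE]
  sex <- sex[sel]
  cl <- droplevels(cl[sel])
  grp <- factor(paste(cl, sex, sep = ":"))
  ind <- Matrix::sparseMatrix(i = seq_len(nrow(x)), j = as.integer(grp), x = 1,
                              dims = c(nrow(x), nlevels(grp)))
  sums <- as.matrix(Matrix::crossprod(ind, x))
  rownames(sums) <- levels(grp)
  colnames(sums) <- colnames(x)
  cpm <- sums / rowSums(sums) * 1e6
  f_rows <- paste(both, "female", sep = ":")
  m_rows <- paste(both, "male", sep = ":")
  lfc <- log2((cpm[f_rows, , drop = FALSE] + 1) /
                (cpm[m_rows, , drop = FALSE] + 1))
  rownames(lfc) <- both
  mean_lfc <- colMeans(lfc)
  pv <- apply(lfc, 2, function(v) {
    if (all(v == 0)) return(1)
    suppressWarnings(stats::wilcox.test(v, mu = 0, exact = FALSE)$p.value)
  })
  pv[is.na(pv)] <- 1
  genes <- data.frame(gene = colnames(x), mean_log2fc = mean_lfc,
                      p_value = pv,
                      p_adj = stats::p.adjust(pv, method = "BH"),
                      stringsAsFactors = FALSE)
  rownames(genes) <- NULL
  structure(list(counts = sums, cpm = cpm, log2fc = lfc, genes = genes),
            class = "pseudobulk_de")
}
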