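# Shared fixtures, built in code and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

# Small atlas used by several module tests.
small_atlas <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- sim_config(n_cells = 2000, n_genes = 400, n_clusters = 10,
                      n_tf_per_class = c(zinc_finger = 6, helix_turn_helix = 4,
                                         homeodomain = 6, basic_domain = 4,
                                         unknown_dbd = 4, hmg = 2),
                      seed = 101)
    .fixture_env$small <- generate_atlas(cfg)
  }
  .fixture_env$small
}

# Full-scale recovery atlas: 9000 cells x 2000 genes, 30 clusters, the
# default generator conditions. Cached together with its processed layers.
recovery_atlas <- function() {
  if (is.null(.fixture_env$recovery)) {
    atlas <- generate_atlas(sim_config(seed = 20240101))
    qc <- compute_cell_qc(atlas$counts, atlas$genes)
    counts <- suppressWarnings(filter_cells(atlas$counts, qc))
    norm <- log_normalize(counts)
    truth_cl <- stats::setNames(atlas$truth$cell$cluster,
                                atlas$truth$cell$cell_id)[rownames(counts)]
    .fixture_env$recovery <- list(atlas = atlas, counts = counts, norm = norm,
                                  truth_clusters = truth_cl)
  }
  .fixture_env$recovery
}

# Positive-mode marker table on the planted clusters of the recovery atlas.
recovery_markers <- function() {
  if (is.null(.fixture_env$recovery_markers)) {
    r <- recovery_atlas()
    .fixture_env$recovery_markers <-
      suppressWarnings(rank_markers(r$norm, r$truth_clusters))
  }
  .fixture_env$recovery_markers
}

# Build a sparse cells x genes count matrix from a dense matrix with ids.
count_mat <- function(m, cells = NULL, genes = NULL) {
  cells <- cells %||% sprintf("c%02d", seq_len(nrow(m)))
  genes <- genes %||% sprintf("g%02d", seq_len(ncol(m)))
  dimnames(m) <- list(cells, genes)
  methods::as(methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                      "dMatrix"), "generalMatrix"),
              "CsparseMatrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal gene annotation data frame.
gene_ann <- function(gene_id, ...) {
  defaults <- list(is_mito = FALSE, is_transgene = FALSE, tf_class = "none",
                   nt_role = "none", is_neuropeptide = FALSE,
                   glial_panel = "none")
  extra <- list(...)
  for (nm in names(extra)) defaults[[nm]] <- extra[[nm]]
  do.call(data.frame, c(list(gene_id = gene_id, symbol = gene_id),
                        defaults, stringsAsFactors = FALSE))
}
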