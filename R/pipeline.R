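# Pipeline orchestration: simulate-or-load -> QC -> normalize -> cluster ->
# markers -> lineage/sex -> programs -> TF codes -> identity mapping, with a
# machine-readable report. All randomness flows from one root seed expanded
# into fixed per-stage seeds.

.known_keys <- list(
  input = c("simulate", "load"),
  qc = c("min_genes", "max_genes", "max_pct_mito"),
  normalization = c("scale_factor"),
  clustering = c("n_hvg", "n_components", "k_neighbors", "resolution"),
  markers = c("min_pct", "min_log2fc"),
  nt = c("threshold", "scale"),
  np = c("max_clusters", "alpha", "min_log2fc"),
  tf = c("alpha"),
  sex = c("alpha", "min_abs_log2_ratio"),
  glia = c("marker_gene", "min_mean", "min_pct", "min_positive_frac"),
  identity = c("n_top_var", "reference_clusters", "noise_sd"))

.pipeline_defaults <- function() {
  list(qc = list(min_genes = 200, max_genes = 2500, max_pct_mito = 5.0),
       normalization = list(scale_factor = 1e4),
       clustering = list(n_hvg = 1000, n_components = 50, k_neighbors = 15,
                         resolution = 1.0),
       markers = list(min_pct = 0.1, min_log2fc = 0.25),
       nt = list(threshold = 2.0, scale = "lognorm"),
       np = list(max_clusters = 5, alpha = 0.05, min_log2fc = 1),
       tf = list(alpha = 0.05),
       sex = list(alpha = 0.05, min_abs_log2_ratio = 1.0),
       glia = list(marker_gene = "repo", min_mean = 1.0, min_pct = 0.5,
                   min_positive_frac = 0.5),
       identity = list(n_top_var = 2000, reference_clusters = NULL,
                       noise_sd = 0.1))
}

#' Validate a pipeline configuration
#'
#' Parses a JSON config file (or takes a list), rejects unknown keys (no
#' silent typo acceptance), range-checks every threshold and fills in
#' documented defaults. The config must name an input: either
#' `input$simulate` (arguments for [sim_config()]; a seed is mandatory) or
#' `input$load` (a bundle directory for [read_mtx_bundle()]).
#'
#' @param config path to a JSON file or a nested list.
#' @return A validated config list of class `pipeline_config`; on invalid
#'   input an error listing every offending key.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) .stopf("config file not found: %s", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  errors <- character(0)
  bad_top <- setdiff(names(config), c(names(.known_keys), "seed"))
  if (length(bad_top))
    errors <- c(errors, sprintf("unknown key: %s", bad_top))
  for (sec in intersect(names(config), names(.known_keys))) {
    bad <- setdiff(names(config[[sec]]), .known_keys[[sec]])
    if (sec == "input") {
      if (length(bad))
        errors <- c(errors, sprintf("unknown key: input$%s", bad))
    } else if (length(bad)) {
      errors <- c(errors, sprintf("unknown key: %s$%s", sec, bad))
    }
  }
  if (is.null(config$input) ||
      (is.null(config$input$simulate) && is.null(config$input$load)))
    errors <- c(errors, "input must provide either simulate or load")
  if (!is.null(config$input$simulate) && is.null(config$input$simulate$seed) &&
      is.null(config$seed))
    errors <- c(errors, "a seed is mandatory when simulating")
  cfg <- utils::modifyList(.pipeline_defaults(), config)
  rng <- list(c("qc", "min_genes", 0, Inf), c("qc", "max_genes", 0, Inf),
              c("qc", "max_pct_mito", 0, 100),
              c("normalization", "scale_factor", 0, Inf),
              c("clustering", "n_hvg", 1, Inf),
              c("clustering", "n_components", 1, Inf),
              c("clustering", "k_neighbors", 1, Inf),
              c("clustering", "resolution", 0, Inf),
              c("markers", "min_pct", 0, 1),
              c("nt", "threshold", -Inf, Inf),
              c("np", "max_clusters", 1, Inf),
              c("np", "alpha", 0, 1), c("tf", "alpha", 0, 1),
              c("sex", "alpha", 0, 1),
              c("sex", "min_abs_log2_ratio", 0, Inf),
              c("identity", "n_top_var", 3, Inf))
  for (r in rng) {
    v <- cfg[[r[1]]][[r[2]]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) ||
        v < as.numeric(r[3]) || v > as.numeric(r[4]))
      errors <- c(errors, sprintf("%s$%s out of range", r[1], r[2]))
  }
  if (!cfg$nt$scale %in% c("lognorm", "scaled"))
    errors <- c(errors, "nt$scale must be lognorm or scaled")
  if (length(errors))
    .stopf("invalid pipeline config:\n  %s", paste(errors, collapse = "\n  "))
  cfg$seed <- as.integer(cfg$seed %||% config$input$simulate$seed %||% 1L)
  structure(cfg, class = "pipeline_config")
}

.stage <- function(name, expr, log = TRUE) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  if (log)
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full atlas analysis pipeline
#'
#' Executes simulate-or-load, QC filtering, log-normalization, lineage
#' assignment, scaling, PCA, SNN clustering, marker ranking,
#' neurotransmitter classification and co-expression counting,
#' cluster-defining neuropeptide selection, TF-neuropeptide correlation,
#' per-class TF code binarization with uniqueness/Jaccard analysis,
#' sex-bias and pseudobulk sex DE (when both sexes are present), glial
#' cluster selection and panel annotation, and (when reference clusters are
#' configured or a simulation provides them) bulk-correlation identity
#' mapping. Every artifact is written as TSV/JSON under `out_dir`; the
#' report reconciles counts across stages. Per-stage seeds are derived from
#' the root seed.
#'
#' @param config a `pipeline_config` from [validate_config()] (or a list /
#'   JSON path, validated on the fly).
#' @param out_dir output directory.
#' @return The run report (also written as `report.json`), invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(complete = FALSE, failed_stage = NULL)
  on.exit(jsonlite::write_json(manifest, file.path(out_dir, "MANIFEST.json"),
                               auto_unbox = TRUE, null = "null"), add = TRUE)

  truth <- NULL
  if (!is.null(cfg$input$simulate)) {
    sim_args <- cfg$input$simulate
    sim_args$seed <- sim_args$seed %||% cfg$seed
    if (!is.null(sim_args$n_tf_per_class))
      sim_args$n_tf_per_class <- unlist(sim_args$n_tf_per_class)
    atlas <- .stage("simulate", do.call(sim_config, sim_args))
    atlas <- .stage("simulate", generate_atlas(atlas), log = FALSE)
    counts <- atlas$counts; genes <- atlas$genes
    cells <- atlas$cells; truth <- atlas$truth
  } else {
    bundle <- .stage("load", read_mtx_bundle(cfg$input$load))
    counts <- bundle$counts; genes <- bundle$genes; cells <- bundle$cells
    if (is.null(cells))
      cells <- data.frame(cell_id = rownames(counts), sample_id = NA_character_,
                          sex = "unknown", stringsAsFactors = FALSE)
  }
  n_loaded <- nrow(counts)

  qc <- .stage("qc", compute_cell_qc(counts, genes))
  counts <- .stage("qc", filter_cells(counts, qc, cfg$qc$min_genes,
                                      cfg$qc$max_genes, cfg$qc$max_pct_mito),
                   log = FALSE)
  if (nrow(counts) == 0)
    .stopf("pipeline stage 'qc' failed: all cells removed by QC filters")
  n_kept <- nrow(counts)
  cells <- cells[match(rownames(counts), cells$cell_id), , drop = FALSE]
  write_tables(list(qc = qc), out_dir)

  lineage <- .stage("lineage", assign_lineage(counts, genes))
  norm <- .stage("normalize",
                 log_normalize(counts, cfg$normalization$scale_factor))
  hvg <- .stage("hvg", select_variable_genes(norm, cfg$clustering$n_hvg))
  scaled <- .stage("scale", scale_genes(norm[, hvg, drop = FALSE]))
  emb <- .stage("pca", embed_pca(scaled,
                                 min(cfg$clustering$n_components,
                                     min(dim(scaled))),
                                 seed = cfg$seed + 1L))
  clusters <- .stage("cluster", cluster_cells(emb, cfg$clustering$k_neighbors,
                                              cfg$clustering$resolution,
                                              seed = cfg$seed + 2L))
  utils::write.table(
    data.frame(cell_id = names(clusters), cluster = clusters,
               lineage = lineage[names(clusters)]),
    file.path(out_dir, "clusters.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  markers <- .stage("markers", rank_markers(norm, clusters,
                                            cfg$markers$min_pct,
                                            cfg$markers$min_log2fc))
  write_tables(list(markers = markers), out_dir)

  ntp <- .stage("nt", classify_neurotransmitters(norm, genes,
                                                 cfg$nt$threshold,
                                                 cfg$nt$scale))
  upset <- coexpression_counts(ntp)
  np_sel <- .stage("np", select_cluster_defining_np(markers, genes,
                                                    cfg$np$max_clusters,
                                                    cfg$np$alpha,
                                                    cfg$np$min_log2fc))
  npcorr <- .stage("np", tf_np_correlation(norm, genes), log = FALSE)
  write_tables(list(upset_counts = upset, tf_np_corr = npcorr$top), out_dir)

  classes <- intersect(tf_classes, unique(genes$tf_class))
  uniqueness <- list()
  codes <- list()
  for (tc in classes) {
    code <- binarize_tf_markers(markers, genes, tc, cfg$tf$alpha,
                                cluster_ids = sort(unique(clusters)))
    codes[[tc]] <- code
    u <- count_unique_codes(code)
    uniqueness[[tc]] <- list(n_unique = u$n_unique,
                             pct_unique = u$pct_unique,
                             shared_groups = shared_code_groups(code))
    write_tables(stats::setNames(list(code, jaccard_matrix(code)),
                                 paste0(c("binary_code_", "jaccard_"), tc)),
                 out_dir)
  }
  jsonlite::write_json(uniqueness, file.path(out_dir, "uniqueness_report.json"),
                       auto_unbox = TRUE, digits = NA)

  sexes_present <- c("female", "male") %in% cells$sex
  sex_bias <- NULL; pseudobulk <- NULL
  if (all(sexes_present)) {
    sex_bias <- .stage("sex", sex_bias_clusters(cells, clusters,
                                                cfg$sex$alpha,
                                                cfg$sex$min_abs_log2_ratio))
    pseudobulk <- tryCatch(
      pseudobulk_sex_de(counts, cells, clusters),
      error = function(e) NULL)
    write_tables(c(list(sex_bias = sex_bias),
                   if (!is.null(pseudobulk))
                     list(pseudobulk_de = pseudobulk$genes)), out_dir)
  }

  glial_sel <- NULL; glial_labels <- NULL
  if (cfg$glia$marker_gene %in% colnames(norm)) {
    glial_sel <- .stage("glia",
                        select_marker_positive_clusters(norm, clusters,
                                                        cfg$glia$marker_gene,
                                                        cfg$glia$min_mean,
                                                        cfg$glia$min_pct))
    panels <- split(genes$gene_id[!genes$glial_panel %in%
                                    c("none", "pan_glial")],
                    genes$glial_panel[!genes$glial_panel %in%
                                        c("none", "pan_glial")])
    if (length(panels) && length(glial_sel)) {
      sa <- scaled_average_expression(norm, clusters)
      glial_labels <- annotate_by_marker_panel(
        sa[glial_sel, , drop = FALSE], panels, cfg$glia$min_positive_frac)
    }
  }

  assignments <- NULL
  ref_clusters <- cfg$identity$reference_clusters
  if (is.null(ref_clusters) && !is.null(truth))
    ref_clusters <- utils::head(sort(unique(truth$cell$cluster)), 3)
  if (!is.null(ref_clusters) && length(ref_clusters)) {
    ref_clusters <- intersect(as.character(ref_clusters),
                              as.character(unique(clusters)))
  }
  if (!is.null(ref_clusters) && length(ref_clusters)) {
    ref <- .stage("identity",
                  generate_bulk_reference(norm, clusters, ref_clusters,
                                          cfg$identity$noise_sd,
                                          seed = cfg$seed + 3L))
    prof <- .cluster_means(norm, clusters)
    coefs <- correlate_bulk(prof, ref, n_top_var = cfg$identity$n_top_var)
    assignments <- assign_identity_by_max(coefs)
    write_tables(list(assignments = assignments), out_dir)
  }

  report <- list(
    package_version = as.character(utils::packageVersion("t2atlas")),
    seed = cfg$seed,
    n_cells_loaded = n_loaded,
    n_cells_filtered_out = n_loaded - n_kept,
    n_cells_kept = n_kept,
    n_t1 = sum(lineage == "T1"),
    n_t2 = sum(lineage == "T2"),
    n_clusters = length(unique(clusters)),
    uniqueness = lapply(uniqueness, function(u)
      u[c("n_unique", "pct_unique")]),
    nt_combinations = upset,
    cluster_defining_neuropeptides = np_sel,
    sex_biased_clusters = if (!is.null(sex_bias))
      sex_bias$cluster[sex_bias$biased != "none"] else character(0),
    glial_clusters = glial_sel,
    glial_labels = as.list(glial_labels %||% character(0)),
    identity_assignments = assignments,
    config = unclass(cfg))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "columns", force = TRUE)
  manifest$complete <- TRUE
  invisible(report)
}
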