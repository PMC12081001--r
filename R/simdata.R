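# Synthetic snRNA-seq atlas generator with planted ground truth.
#
# The generator emulates the statistical structure the downstream analyses
# assume: negative-binomial counts over lognormal per-cell depths, cluster
# expression programs (TF combinatorial codes, neurotransmitter, neuropeptide
# and glial marker panels), T2 lineage transgene labels, female/male/mixed
# samples with sex-effect genes, sex-biased cluster abundances, and
# mitochondrial content.

# ---- fixed gene-role universes -----------------------------------------------

#' Fast-acting neurotransmitter marker genes
#'
#' Named character vector mapping the seven neurotransmitter roles to their
#' marker genes: VGlut (glutamatergic), VAChT (cholinergic), Gad1 (GABAergic),
#' Tbh (tyraminergic), ple (dopaminergic), SerT (serotonergic) and Tdc2
#' (octopaminergic). The tyraminergic/octopaminergic labels follow the atlas
#' convention for Tbh and Tdc2.
#' @export
nt_marker_genes <- c(
  glutamatergic = "VGlut", cholinergic = "VAChT", GABAergic = "Gad1",
  tyraminergic = "Tbh", dopaminergic = "ple", serotonergic = "SerT",
  octopaminergic = "Tdc2")

#' Transcription factor structural classes
#'
#' The six TF classes used for combinatorial-code analysis.
#' @export
tf_classes <- c("zinc_finger", "helix_turn_helix", "homeodomain",
                "basic_domain", "unknown_dbd", "hmg")

.tf_class_prefix <- c(zinc_finger = "zf", helix_turn_helix = "hth",
                      homeodomain = "hd", basic_domain = "bd",
                      unknown_dbd = "udb", hmg = "hmg")

.transgene_genes <- c("FLP", "GFP", "RFP")

.sex_effect_default <- list(
  female = c(yp1 = 4, yp2 = 4, yp3 = 4, dsx = 2),
  male   = c("lncRNA:roX1" = 4, "lncRNA:roX2" = 4, fru = 2))

.np_genes_default <- c("AstA", "NPF", "Ms", "Tk", "AstC", "CCAP", "Proc",
                       "Dh31", "Dh44", "Mip", "sNPF", "Lk", "Burs")

.glial_panels_default <- list(
  astrocyte     = c("alrm", "Gat"),
  cortex        = c("Hoip", "wrapper"),
  ensheathing   = c("zyd", "trol"),
  perineurial   = c("Tret1-1", "vkg"),
  subperineurial = c("moody", "Mdr65"),
  chiasm        = c("Optix", "Sox102F"))

.nt_roles <- names(nt_marker_genes)

# ---- default cluster programs ------------------------------------------------

# Assign neurotransmitter roles to neuronal clusters with abundances shaped
# like an adult central-brain atlas: cholinergic most common, then
# glutamatergic and GABAergic, rare monoaminergic classes, a couple of
# dual-transmitter clusters, and a sizeable "none" fraction.
.default_nt_program <- function(neuronal_ids) {
  n <- length(neuronal_ids)
  singles <- c(rep("cholinergic", max(1, round(0.22 * n))),
               rep("glutamatergic", max(1, round(0.12 * n))),
               rep("GABAergic", max(1, round(0.08 * n))),
               "tyraminergic", "dopaminergic", "serotonergic", "octopaminergic")
  prog <- rep(list(character(0)), n)
  names(prog) <- as.character(neuronal_ids)
  k <- min(n, length(singles))
  for (i in seq_len(k)) prog[[i]] <- singles[i]
  # dual-transmitter clusters (excitatory+inhibitory and double-excitatory)
  if (n >= k + 2) {
    prog[[k + 1]] <- c("cholinergic", "GABAergic")
    prog[[k + 2]] <- c("glutamatergic", "cholinergic")
  }
  prog
}

# Neuropeptide programs: two neuropeptides co-expressed by the same two
# clusters, two neuropeptides each in two clusters, remaining neuropeptides
# in one cluster apiece (cycling if clusters run short).
.default_np_program <- function(neuronal_ids, np_genes) {
  n <- length(neuronal_ids)
  prog <- rep(list(character(0)), n)
  names(prog) <- as.character(neuronal_ids)
  if (n == 0 || length(np_genes) == 0) return(prog)
  pick <- function(i) ((i - 1) %% n) + 1
  # shared pair: first two NPs both in clusters pick(1), pick(2)
  if (length(np_genes) >= 2 && n >= 2) {
    for (i in 1:2) prog[[pick(i)]] <- c(prog[[pick(i)]], np_genes[1:2])
    rest <- np_genes[-(1:2)]
    slot <- 3
  } else {
    rest <- np_genes
    slot <- 1
  }
  # next two NPs span two clusters each
  two_cluster <- head(rest, 2)
  for (g in two_cluster) {
    for (j in 0:1) {
      prog[[pick(slot + j)]] <- c(prog[[pick(slot + j)]], g)
    }
    slot <- slot + 2
  }
  rest <- setdiff(rest, two_cluster)
  for (g in rest) {
    prog[[pick(slot)]] <- c(prog[[pick(slot)]], g)
    slot <- slot + 1
  }
  lapply(prog, unique)
}

# ---- configuration -----------------------------------------------------------

#' Build a simulation configuration
#'
#' Collects and validates every knob of the synthetic atlas generator.
#' Counts are negative binomial with mean `depth * p_gene` and variance
#' `mu + mu^2 / dispersion` (mean / inverse-dispersion parameterization);
#' per-cell depth is lognormal with expectation `depth_mean` and log-scale
#' sigma `depth_shape`.
#'
#' Two planted effect sizes are distinguished: `de_log2fc` drives the
#' TF-combinatorial-code genes (a statistical, Wilcoxon-detectable shift),
#' while `marker_log2fc` drives the dedicated marker genes (neurotransmitter,
#' neuropeptide, glial panel and sex-effect genes), which in real atlases are
#' near-binary with on/off ratios well above 100x. Marker genes keep a low
#' non-zero baseline in "off" cells so their detection stays statistical.
#'
#' @param n_cells total number of cells; when `samples` is supplied it must
#'   equal the sum of the per-sample cell counts.
#' @param n_genes total number of genes, at least the number of role genes.
#' @param n_clusters number of planted clusters (ids `1..n_clusters`).
#' @param cluster_proportions `"uniform"` or a simplex vector of length
#'   `n_clusters`.
#' @param depth_mean expected total counts per cell.
#' @param depth_shape lognormal sigma of the per-cell depth.
#' @param dispersion negative-binomial inverse dispersion (theta).
#' @param baseline_logmean_sd lognormal sd of baseline gene abundances.
#' @param de_log2fc planted log2 fold change of "on" TF-code genes.
#' @param marker_log2fc planted log2 on/off ratio of dedicated marker genes.
#' @param frac_mito_genes fraction of genes flagged mitochondrial.
#' @param mito_rate_per_cell expected fraction of each cell's counts assigned
#'   to mitochondrial genes.
#' @param samples data frame with columns `sample_id`, `sex` (one of
#'   `"female"`, `"male"`, `"mixed"`) and `n_cells`; defaults to a
#'   female/male/mixed split of 16/32/52 percent of cells, mirroring typical
#'   pooled sorting rounds.
#' @param frac_t2 fraction of cells carrying the T2 lineage label.
#' @param transgene_rate per-transgene capture probability in T2 cells.
#' @param n_tf_per_class named integer vector, TFs per structural class.
#' @param code_density probability a TF is "on" in a cluster's planted code.
#' @param nt_program list mapping cluster id to a subset of the seven
#'   neurotransmitter roles; `NULL` for the built-in default.
#' @param np_program list mapping cluster id to a subset of `np_genes`;
#'   `NULL` for the built-in default.
#' @param np_genes neuropeptide gene universe.
#' @param sex_effect_genes list with `female` and `male` named numeric
#'   vectors of log2 effects.
#' @param sex_biased_clusters named character vector mapping cluster id to
#'   `"female"` or `"male"`; `NULL` plants two female- and one male-enriched
#'   cluster when `n_clusters >= 8`.
#' @param sex_bias_log2_ratio planted log2 abundance ratio of biased clusters.
#' @param frac_glial_clusters fraction of clusters that are glial (repo+).
#' @param glial_panels list of glial subtype marker panels.
#' @param seed integer random seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 9000, n_genes = 2000, n_clusters = 30,
                       cluster_proportions = "uniform",
                       depth_mean = 2000, depth_shape = 0.35, dispersion = 2,
                       baseline_logmean_sd = 1, de_log2fc = 2,
                       marker_log2fc = 9,
                       frac_mito_genes = 0.01, mito_rate_per_cell = 0.02,
                       samples = NULL, frac_t2 = 0.5, transgene_rate = 0.75,
                       n_tf_per_class = c(zinc_finger = 25,
                                          helix_turn_helix = 15,
                                          homeodomain = 25, basic_domain = 15,
                                          unknown_dbd = 15, hmg = 5),
                       code_density = 0.3,
                       nt_program = NULL, np_program = NULL,
                       np_genes = .np_genes_default,
                       sex_effect_genes = .sex_effect_default,
                       sex_biased_clusters = NULL, sex_bias_log2_ratio = 2,
                       frac_glial_clusters = 0.1,
                       glial_panels = .glial_panels_default,
                       seed = 1) {
  chk_frac <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
      .stopf("invalid config: %s must be a fraction in [0, 1]", nm)
  }
  chk_pos <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0)
      .stopf("invalid config: %s must be a positive number", nm)
  }
  if (!is.numeric(n_cells) || n_cells < 1)
    .stopf("invalid config: n_cells must be a positive integer")
  if (!is.numeric(n_genes) || n_genes < 1)
    .stopf("invalid config: n_genes must be a positive integer")
  if (!is.numeric(n_clusters) || n_clusters < 1)
    .stopf("invalid config: n_clusters must be a positive integer")
  n_cells <- as.integer(n_cells); n_genes <- as.integer(n_genes)
  n_clusters <- as.integer(n_clusters)
  for (nm in c("depth_mean", "depth_shape", "dispersion",
               "baseline_logmean_sd", "de_log2fc", "marker_log2fc"))
    chk_pos(get(nm), nm)
  for (nm in c("frac_mito_genes", "mito_rate_per_cell", "frac_t2",
               "transgene_rate", "code_density", "frac_glial_clusters"))
    chk_frac(get(nm), nm)

  if (is.character(cluster_proportions) &&
      identical(cluster_proportions, "uniform")) {
    cluster_proportions <- rep(1 / n_clusters, n_clusters)
  }
  if (length(cluster_proportions) != n_clusters ||
      abs(sum(cluster_proportions) - 1) > 1e-9 ||
      any(cluster_proportions < 0))
    .stopf("invalid config: cluster_proportions must be a simplex vector of length n_clusters")

  if (is.null(samples)) {
    n_f <- round(0.16 * n_cells); n_m <- round(0.32 * n_cells)
    samples <- data.frame(
      sample_id = c("female_1", "male_1", "mixed_1"),
      sex = c("female", "male", "mixed"),
      n_cells = c(n_f, n_m, n_cells - n_f - n_m),
      stringsAsFactors = FALSE)
    samples <- samples[samples$n_cells > 0, , drop = FALSE]
  }
  if (!all(c("sample_id", "sex", "n_cells") %in% names(samples)))
    .stopf("invalid config: samples needs columns sample_id, sex, n_cells")
  if (!all(samples$sex %in% c("female", "male", "mixed")))
    .stopf("invalid config: sample sex must be female, male or mixed")
  if (sum(samples$n_cells) != n_cells)
    .stopf("invalid config: sample cell counts sum to %d, not n_cells = %d",
           sum(samples$n_cells), n_cells)

  if (is.null(names(n_tf_per_class)) ||
      !all(names(n_tf_per_class) %in% tf_classes))
    .stopf("invalid config: n_tf_per_class must be named by TF classes")
  n_tf_per_class <- n_tf_per_class[n_tf_per_class > 0]

  n_glial <- round(frac_glial_clusters * n_clusters)
  glial_ids <- if (n_glial > 0) seq.int(n_clusters - n_glial + 1, n_clusters)
               else integer(0)
  neuronal_ids <- setdiff(seq_len(n_clusters), glial_ids)

  if (is.null(nt_program)) nt_program <- .default_nt_program(neuronal_ids)
  if (is.null(np_program))
    np_program <- .default_np_program(neuronal_ids, np_genes)
  bad_nt <- setdiff(unlist(nt_program), .nt_roles)
  if (length(bad_nt))
    .stopf("invalid config: unknown neurotransmitter role(s): %s",
           paste(bad_nt, collapse = ", "))
  bad_np <- setdiff(unlist(np_program), np_genes)
  if (length(bad_np))
    .stopf("invalid config: neuropeptide program references unknown gene(s): %s",
           paste(bad_np, collapse = ", "))
  bad_cl <- setdiff(as.integer(c(names(nt_program), names(np_program))),
                    seq_len(n_clusters))
  if (length(bad_cl))
    .stopf("invalid config: program references unknown cluster(s): %s",
           paste(bad_cl, collapse = ", "))

  if (!all(c("female", "male") %in% names(sex_effect_genes)))
    .stopf("invalid config: sex_effect_genes needs female and male entries")

  if (is.null(sex_biased_clusters)) {
    sex_biased_clusters <- if (n_clusters >= 8)
      c(`3` = "male", `5` = "female", `7` = "female") else character(0)
  }
  if (length(sex_biased_clusters)) {
    if (!all(sex_biased_clusters %in% c("female", "male")))
      .stopf("invalid config: sex_biased_clusters directions must be female or male")
    if (!all(as.integer(names(sex_biased_clusters)) %in% seq_len(n_clusters)))
      .stopf("invalid config: sex_biased_clusters references unknown cluster")
  }

  # glial subtype assignment: panels cycle over glial clusters; the first
  # glial cluster carries two panels (an overlapping-identity cluster).
  glial_subtypes <- list()
  if (length(glial_ids)) {
    pn <- names(glial_panels)
    for (i in seq_along(glial_ids)) {
      glial_subtypes[[as.character(glial_ids[i])]] <-
        pn[((i - 1) %% length(pn)) + 1]
    }
    if (length(pn) >= 2 && length(glial_ids) >= 1) {
      first <- as.character(glial_ids[1])
      glial_subtypes[[first]] <- unique(c(glial_subtypes[[first]], pn[2]))
    }
  }

  cfg <- list(n_cells = n_cells, n_genes = n_genes, n_clusters = n_clusters,
              cluster_proportions = cluster_proportions,
              depth_mean = depth_mean, depth_shape = depth_shape,
              dispersion = dispersion,
              baseline_logmean_sd = baseline_logmean_sd,
              de_log2fc = de_log2fc, marker_log2fc = marker_log2fc,
              frac_mito_genes = frac_mito_genes,
              mito_rate_per_cell = mito_rate_per_cell,
              samples = samples, frac_t2 = frac_t2,
              transgene_rate = transgene_rate,
              n_tf_per_class = n_tf_per_class, code_density = code_density,
              nt_program = nt_program, np_program = np_program,
              np_genes = np_genes, sex_effect_genes = sex_effect_genes,
              sex_biased_clusters = sex_biased_clusters,
              sex_bias_log2_ratio = sex_bias_log2_ratio,
              glial_ids = glial_ids, glial_subtypes = glial_subtypes,
              glial_panels = glial_panels, seed = as.integer(seed))
  # the gene universe must fit
  ann <- .build_gene_annotation(cfg)
  if (nrow(ann) > n_genes)
    .stopf("invalid config: n_genes = %d is smaller than the %d role genes",
           n_genes, nrow(ann))
  structure(cfg, class = "sim_config")
}

# ---- gene annotation ---------------------------------------------------------

# Role genes only (no filler); generate_atlas pads with filler genes.
.build_gene_annotation <- function(cfg) {
  row <- function(symbol, is_mito = FALSE, is_transgene = FALSE,
                  tf_class = "none", nt_role = "none",
                  is_neuropeptide = FALSE, glial_panel = "none") {
    data.frame(gene_id = symbol, symbol = symbol, is_mito = is_mito,
               is_transgene = is_transgene, tf_class = tf_class,
               nt_role = nt_role, is_neuropeptide = is_neuropeptide,
               glial_panel = glial_panel, stringsAsFactors = FALSE)
  }
  out <- list()
  for (g in .transgene_genes) out[[length(out) + 1]] <- row(g, is_transgene = TRUE)
  for (r in .nt_roles)
    out[[length(out) + 1]] <- row(nt_marker_genes[[r]], nt_role = r)
  for (g in names(cfg$sex_effect_genes$female)) out[[length(out) + 1]] <- row(g)
  for (g in names(cfg$sex_effect_genes$male)) out[[length(out) + 1]] <- row(g)
  for (g in cfg$np_genes) out[[length(out) + 1]] <- row(g, is_neuropeptide = TRUE)
  out[[length(out) + 1]] <- row("repo", glial_panel = "pan_glial")
  for (p in names(cfg$glial_panels))
    for (g in cfg$glial_panels[[p]])
      out[[length(out) + 1]] <- row(g, glial_panel = p)
  for (cl in names(cfg$n_tf_per_class)) {
    for (i in seq_len(cfg$n_tf_per_class[[cl]])) {
      out[[length(out) + 1]] <-
        row(sprintf("%s.%02d", .tf_class_prefix[[cl]], i), tf_class = cl)
    }
  }
  n_mito <- max(1, round(cfg$frac_mito_genes * cfg$n_genes))
  for (i in seq_len(n_mito))
    out[[length(out) + 1]] <- row(sprintf("mt:ND%02d", i), is_mito = TRUE)
  ann <- do.call(rbind, out)
  if (anyDuplicated(ann$symbol))
    .stopf("invalid config: duplicate role gene symbols")
  ann
}

# ---- atlas generation --------------------------------------------------------

#' Generate a synthetic snRNA-seq atlas
#'
#' Draws a sparse cells x genes count matrix plus cell metadata, gene
#' annotation and a full ground-truth record under the model described in
#' [sim_config()]. Deterministic for a fixed config (including seed).
#'
#' Transgene (FLP/GFP/RFP) counts are possible only in T2 cells: each
#' transgene is captured independently with probability `transgene_rate`,
#' and T1 cells are guaranteed all-zero for the three transgenes.
#'
#' @param config a [sim_config()] object.
#' @return A list of class `sim_atlas` with elements `counts` (sparse
#'   cells x genes integer matrix), `cells` (per-cell sample/sex metadata),
#'   `genes` (gene annotation data frame) and `truth` (planted programs,
#'   codes and labels; class `atlas_truth`).
#' @export
generate_atlas <- function(config) {
  if (!inherits(config, "sim_config"))
    .stopf("config must be built with sim_config()")
  cfg <- config
  set.seed(cfg$seed)

  ## gene table: role genes + filler
  ann <- .build_gene_annotation(cfg)
  n_fill <- cfg$n_genes - nrow(ann)
  if (n_fill > 0) {
    fill <- data.frame(gene_id = sprintf("CG%05d", seq_len(n_fill)),
                       symbol = sprintf("CG%05d", seq_len(n_fill)),
                       is_mito = FALSE, is_transgene = FALSE,
                       tf_class = "none", nt_role = "none",
                       is_neuropeptide = FALSE, glial_panel = "none",
                       stringsAsFactors = FALSE)
    ann <- rbind(ann, fill)
  }
  G <- nrow(ann)
  gene_ids <- ann$gene_id

  ## baseline relative abundances; at default depth (2000) and gene number,
  ## a weight of 1 is ~0.6 mean counts/cell. Dedicated marker genes are
  ## near-binary: ~3% ambient detection off, tens of counts on. TF-code
  ## genes sit at a detectable baseline so the planted fold change is a
  ## statistical, not degenerate, signal.
  marker_base <- 0.05   # off-state weight of dedicated marker genes
  tf_base <- 2          # baseline weight of TF-code genes
  w0 <- numeric(G)
  is_filler <- !ann$is_transgene & !ann$is_mito & ann$tf_class == "none" &
    ann$nt_role == "none" & !ann$is_neuropeptide & ann$glial_panel == "none" &
    !(ann$symbol %in% c(names(cfg$sex_effect_genes$female),
                        names(cfg$sex_effect_genes$male)))
  w0[is_filler] <- stats::rlnorm(sum(is_filler), 0, cfg$baseline_logmean_sd)
  w0[ann$tf_class != "none"] <- tf_base
  w0[ann$nt_role != "none" | ann$is_neuropeptide |
       ann$glial_panel != "none"] <- marker_base
  w0[ann$symbol %in% c(names(cfg$sex_effect_genes$female),
                       names(cfg$sex_effect_genes$male))] <- marker_base
  w0[ann$is_transgene] <- 0
  mito_idx <- which(ann$is_mito)
  w0[mito_idx] <- 0

  ## planted TF codes
  codes <- list()
  for (cl in names(cfg$n_tf_per_class)) {
    tfs <- ann$gene_id[ann$tf_class == cl]
    codes[[cl]] <- matrix(
      stats::rbinom(cfg$n_clusters * length(tfs), 1, cfg$code_density),
      nrow = cfg$n_clusters,
      dimnames = list(as.character(seq_len(cfg$n_clusters)), tfs))
  }

  ## cells: sample, labeled sex, sex program, cluster, lineage, depth
  n <- cfg$n_cells
  cell_ids <- sprintf("cell_%05d", seq_len(n))
  sample_id <- rep(cfg$samples$sample_id, cfg$samples$n_cells)
  sex_label <- rep(cfg$samples$sex, cfg$samples$n_cells)
  sex_prog <- sex_label
  mixed <- sex_prog == "mixed"
  sex_prog[mixed] <- ifelse(stats::rbinom(sum(mixed), 1, 0.5) == 1,
                            "female", "male")

  bias_mult <- function(sex) {
    w <- cfg$cluster_proportions
    for (j in seq_along(cfg$sex_biased_clusters)) {
      id <- as.integer(names(cfg$sex_biased_clusters)[j])
      d <- cfg$sex_biased_clusters[[j]]
      h <- 2^(cfg$sex_bias_log2_ratio / 2)
      w[id] <- if (sex == d) w[id] * h else w[id] / h
    }
    w / sum(w)
  }
  cluster <- integer(n)
  for (s in c("female", "male")) {
    idx <- which(sex_prog == s)
    if (length(idx))
      cluster[idx] <- sample.int(cfg$n_clusters, length(idx), replace = TRUE,
                                 prob = bias_mult(s))
  }
  lineage <- ifelse(stats::rbinom(n, 1, cfg$frac_t2) == 1, "T2", "T1")
  depth <- stats::rlnorm(n, log(cfg$depth_mean) - cfg$depth_shape^2 / 2,
                         cfg$depth_shape)

  ## per-(cluster, sex-program) gene rate vectors
  gi <- function(sym) match(sym, ann$symbol)
  rate_vec <- function(cl_id, sex) {
    w <- w0
    for (tc in names(codes)) {
      on <- colnames(codes[[tc]])[codes[[tc]][cl_id, ] == 1]
      if (length(on)) w[gi(on)] <- w[gi(on)] * 2^cfg$de_log2fc
    }
    key <- as.character(cl_id)
    roles <- cfg$nt_program[[key]]
    if (length(roles)) {
      g <- nt_marker_genes[roles]
      w[gi(g)] <- w[gi(g)] * 2^cfg$marker_log2fc
    }
    nps <- cfg$np_program[[key]]
    if (length(nps)) w[gi(nps)] <- w[gi(nps)] * 2^cfg$marker_log2fc
    if (cl_id %in% cfg$glial_ids) {
      pg <- unique(c("repo",
                     unlist(cfg$glial_panels[cfg$glial_subtypes[[key]]])))
      w[gi(pg)] <- w[gi(pg)] * 2^cfg$marker_log2fc
    }
    eff <- cfg$sex_effect_genes[[sex]]
    w[gi(names(eff))] <- w[gi(names(eff))] * 2^eff
    # mitochondrial mass fixed at mito_rate_per_cell of the total
    r <- cfg$mito_rate_per_cell
    if (r > 0) w[mito_idx] <- (r / (1 - r)) * sum(w) / length(mito_idx)
    w / sum(w)
  }

  counts <- matrix(0L, n, G)
  for (cl_id in seq_len(cfg$n_clusters)) {
    for (s in c("female", "male")) {
      idx <- which(cluster == cl_id & sex_prog == s)
      if (!length(idx)) next
      p <- rate_vec(cl_id, s)
      mu <- outer(depth[idx], p)
      y <- stats::rnbinom(length(mu), size = cfg$dispersion, mu = mu)
      counts[idx, ] <- as.integer(y)
    }
  }

  ## transgenes: detected per T2 cell with probability transgene_rate
  t2 <- which(lineage == "T2")
  for (g in .transgene_genes) {
    j <- gi(g)
    if (length(t2) && cfg$transgene_rate > 0) {
      det <- stats::rbinom(length(t2), 1, cfg$transgene_rate)
      cnt <- det * (1L + stats::rpois(length(t2), 1))
      counts[t2, j] <- as.integer(cnt)
    }
  }

  dimnames(counts) <- list(cell_ids, gene_ids)
  counts <- .as_dgc(Matrix::Matrix(counts, sparse = TRUE))

  cells <- data.frame(cell_id = cell_ids, sample_id = sample_id,
                      sex = sex_label, stringsAsFactors = FALSE)
  truth <- structure(list(
    cell = data.frame(cell_id = cell_ids, sample_id = sample_id,
                      sex = sex_label, sex_program = sex_prog,
                      lineage = lineage, cluster = cluster,
                      stringsAsFactors = FALSE),
    codes = codes,
    nt_program = cfg$nt_program,
    np_program = cfg$np_program,
    sex_biased_clusters = cfg$sex_biased_clusters,
    glial_ids = cfg$glial_ids,
    glial_subtypes = cfg$glial_subtypes,
    mito_rate_per_cell = cfg$mito_rate_per_cell,
    seed = cfg$seed), class = "atlas_truth")

  structure(list(counts = counts, cells = cells, genes = ann, truth = truth),
            class = "sim_atlas")
}

# ---- bulk reference ----------------------------------------------------------

#' Generate synthetic bulk reference profiles from chosen clusters
#'
#' Builds one bulk expression profile per chosen cluster as the cluster's
#' mean log-normalized expression plus independent Gaussian noise per gene,
#' labeling each profile with a synthetic neuron-type name recorded in the
#' returned mapping. With `noise_sd = 0` the profile equals the cluster mean
#' exactly.
#'
#' @param norm log-normalized cells x genes matrix (see [log_normalize()]).
#' @param clusters per-cell cluster labels (named vector or factor), or an
#'   `atlas_truth` object.
#' @param chosen_clusters cluster ids to profile.
#' @param noise_sd standard deviation of the added Gaussian noise.
#' @param seed integer seed.
#' @return A list of class `bulk_reference` with `profiles` (genes x types
#'   matrix) and `type_cluster` (named vector mapping type to source cluster).
#' @export
generate_bulk_reference <- function(norm, clusters, chosen_clusters,
                                    noise_sd = 0.1, seed = 1) {
  if (inherits(clusters, "atlas_truth"))
    clusters <- stats::setNames(clusters$cell$cluster, clusters$cell$cell_id)
  if (!length(chosen_clusters)) .stopf("chosen_clusters must be nonempty")
  cl <- .as_clusters(clusters, rownames(norm))
  missing <- setdiff(as.character(chosen_clusters), levels(cl))
  if (length(missing))
    .stopf("unknown cluster id(s): %s", paste(missing, collapse = ", "))
  set.seed(seed)
  means <- .cluster_means(norm, cl)
  types <- sprintf("synNeuron%s", chosen_clusters)
  prof <- t(means[as.character(chosen_clusters), , drop = FALSE])
  colnames(prof) <- types
  if (noise_sd > 0)
    prof <- prof + matrix(stats::rnorm(length(prof), 0, noise_sd),
                          nrow = nrow(prof))
  structure(list(profiles = prof,
                 type_cluster = stats::setNames(chosen_clusters, types)),
            class = "bulk_reference")
}
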