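# t2atlas

Analysis toolkit for single-nucleus RNA-seq atlases of adult insect
central-brain neurons and glia derived from type 2 (T2) neuroblasts — the
stem cells whose progeny build most of the central complex. The package is
aimed at researchers who have (or simulate) a 10x-style count bundle with
per-cell sample/sex metadata and want the downstream characterization done
reproducibly:

* **Lineage assignment** — a nucleus is T2-derived iff any lineage-trace
  transgene (FLP, GFP, RFP) has a count ≥ 1; triple-negative nuclei are T1.
* **Neurotransmitter co-expression** — a cell carries a transmitter role iff
  the role's marker gene (VGlut, VAChT, Gad1, Tbh, ple, SerT, Tdc2) exceeds
  log-normalized expression 2; every observed role combination is counted
  exactly (UpSet-style).
* **Sex-biased clusters** — with per-sex input totals `N_f`, `N_m` (mixed
  samples excluded), each cluster's male count is tested against
  `q = N_m/(N_m+N_f)` by an exact binomial test (BH over clusters) with a
  fold gate on the input-normalized ratio
  `log2((n_m + 0.5)/(n_f·N_m/N_f + 0.5))`; pseudobulk sex DE treats
  clusters as paired replicates of per-cluster `log2((cpm_f+1)/(cpm_m+1))`.
* **TF combinatorial codes** — one-vs-rest Wilcoxon markers binarized per TF
  structural class (entry 1 iff `p_adj < 0.05`), per-class uniqueness
  (`pct_unique = 100·n_unique/n_clusters`), shared-code groups, Jaccard
  similarity `J = |S_a ∩ S_b| / |S_a ∪ S_b|` and average-linkage similarity
  ordering.
* **Cluster identity mapping** — Pearson correlation of cluster profiles
  against bulk references (assignment by highest coefficient), split-driver
  enhancer-gene queries and signed marker-constraint queries on scaled
  average expression, and glial marker-panel annotation with overlapping
  identities.
* **A synthetic atlas generator** (`sim_config()` / `generate_atlas()`) that
  plants all of the above — negative-binomial counts over lognormal depths,
  cluster TF codes, transmitter/neuropeptide programs, sex programs and
  biased clusters, transgene labels — with full ground truth, so every
  analysis is testable by parameter recovery.

See `vignettes/t2atlas-methods.Rmd` for the models, defaults and their
rationale.

## Worked example

```r
library(t2atlas)

cfg   <- sim_config(n_cells = 3000, n_genes = 600, n_clusters = 12, seed = 42)
atlas <- generate_atlas(cfg)

qc     <- compute_cell_qc(atlas$counts, atlas$genes)
counts <- filter_cells(atlas$counts, qc)          # 200-2500 genes, <=5% mito
norm   <- log_normalize(counts)

table(assign_lineage(counts, atlas$genes))
#>   T1   T2
#> 1557 1442

hvg <- select_variable_genes(norm, 300)
emb <- embed_pca(scale_genes(norm[, hvg]), 30, seed = 1)
cl  <- cluster_cells(emb, resolution = 2, seed = 1)
length(unique(cl))
#> [1] 12

mk <- rank_markers(norm, cl)
head(as.data.frame(mk), 3)
#>   cluster  gene    log2fc    pct_in   pct_out      p_value        p_adj
#> 1       1 bd.02 1.1701874 0.9689266 0.8759924 2.443076e-58 7.517158e-58
#> 2       1 bd.05 1.0682740 0.9802260 0.8793951 2.468788e-52 5.808913e-52
#> 3       1 bd.07 0.9245246 0.9858757 0.8914934 3.536126e-49 7.858058e-49

count_unique_codes(binarize_tf_markers(mk, atlas$genes, "homeodomain"))
#> $n_unique
#> [1] 12
#> $pct_unique
#> [1] 100

head(coexpression_counts(classify_neurotransmitters(norm, atlas$genes)), 3)
#>     combination count percentage
#> 1   cholinergic   441  14.704902
#> 2          none   418  13.937979
#> 3 glutamatergic   323  10.770257
```

Reading the output: all 3,000 simulated nuclei split into transgene-positive
(T2) and triple-negative (T1) fractions near the configured 50%; graph
clustering recovers the 12 planted clusters; the marker table lists each
cluster's enriched genes with fold changes and BH-adjusted rank-sum
p-values; every cluster here has a unique homeodomain code (100%
uniqueness); and the co-expression table counts cells per transmitter
combination with percentages that sum to 100.

The same analysis runs as one orchestrated pipeline with
`run_pipeline(config, out_dir)` (JSON config, TSV/JSON artifacts, a
reconciling report); `inst/scripts/t2atlas-pipeline.R` wraps it for shell
use.

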