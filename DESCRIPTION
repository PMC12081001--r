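Package: t2atlas
Title: Simulation and Analysis of a T2-Neuroblast-Derived Brain snRNA-seq Atlas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize single-nucleus RNA-seq atlases of adult
    insect central-brain neurons and glia derived from type 2 neuroblasts.
    Provides a negative-binomial atlas simulator with planted ground truth
    (clusters, transgene lineage labels, sex programs, neurotransmitter and
    neuropeptide programs, transcription-factor combinatorial codes), cell QC
    and log-normalization, shared-nearest-neighbor graph clustering,
    one-vs-rest Wilcoxon marker ranking, transgene-based lineage assignment,
    sex-biased cluster detection and pseudobulk sex differential expression,
    neurotransmitter co-expression (UpSet) counting, cluster-defining
    neuropeptide selection, binarized TF combinatorial-code analysis with
    Jaccard similarity, and correlation-based cluster-to-bulk identity
    mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    igraph,
    bluster,
    scran,
    irlba,
    matrixStats,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
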