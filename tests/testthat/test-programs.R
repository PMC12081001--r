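nt_ann <- function() {
  gene_ann(unname(t2atlas::nt_marker_genes),
           nt_role = names(t2atlas::nt_marker_genes))
}

test_that("neurotransmitter classification applies the threshold rule", {
  genes <- nt_ann()
  vals <- matrix(0, 3, 7, dimnames = list(sprintf("c%02d", 1:3),
                                          genes$gene_id))
  vals["c01", "VAChT"] <- 2.5
  vals["c03", c("VGlut", "Gad1")] <- c(3, 2.1)
  prof <- classify_neurotransmitters(Matrix::Matrix(vals, sparse = TRUE),
                                     genes)
  expect_equal(colnames(prof)[prof["c01", ]], "cholinergic")
  expect_false(any(prof["c02", ]))  # all below threshold -> empty set
  expect_setequal(colnames(prof)[prof["c03", ]],
                  c("glutamatergic", "GABAergic"))
  # missing marker gene is reported
  expect_error(classify_neurotransmitters(
    Matrix::Matrix(vals[, -2], sparse = TRUE), genes), "cholinergic")
})

test_that("raising the threshold never enlarges any role set", {
  r <- recovery_atlas()
  p2 <- classify_neurotransmitters(r$norm, r$atlas$genes, threshold = 2)
  p3 <- classify_neurotransmitters(r$norm, r$atlas$genes, threshold = 3)
  expect_true(all(p2 | !p3))  # p3 subset of p2 cellwise
})

test_that("co-expression counts are exact with conserved totals", {
  genes <- nt_ann()
  vals <- matrix(0, 4, 7, dimnames = list(sprintf("c%02d", 1:4),
                                          genes$gene_id))
  vals[1, "VAChT"] <- 3; vals[2, "VAChT"] <- 3
  vals[4, c("VGlut", "Gad1")] <- 3
  prof <- classify_neurotransmitters(Matrix::Matrix(vals, sparse = TRUE),
                                     genes)
  cc <- coexpression_counts(prof)
  expect_equal(cc$combination[1], "cholinergic")
  expect_equal(cc$count[1], 2)
  expect_equal(cc$percentage[1], 50)
  expect_setequal(cc$combination, c("cholinergic", "none",
                                    "glutamatergic+GABAergic"))
  expect_equal(cc$count[cc$combination == "none"], 1)
  expect_equal(sum(cc$percentage), 100)
  expect_equal(sum(cc$count), 4)

  all_empty <- classify_neurotransmitters(
    Matrix::Matrix(vals * 0, sparse = TRUE), genes)
  cc0 <- coexpression_counts(all_empty)
  expect_equal(cc0$combination, "none")
  expect_equal(cc0$percentage, 100)
})

test_that("classification conserves cell number through counting", {
  r <- recovery_atlas()
  prof <- classify_neurotransmitters(r$norm, r$atlas$genes)
  cc <- coexpression_counts(prof)
  expect_equal(sum(cc$count), nrow(r$norm))
  expect_equal(sum(cc$percentage), 100, tolerance = 1e-9)
})

test_that("cluster-defining neuropeptide selection applies both bounds", {
  genes <- gene_ann(c("NPx", "NPy", "NPz", "tf1"),
                    is_neuropeptide = c(TRUE, TRUE, TRUE, FALSE))
  mk <- data.frame(
    cluster = c("1", "2", "1", "2", "3", "4", "5", "6", "7"),
    gene = c("NPx", "NPx", rep("NPy", 7)),
    log2fc = 2, pct_in = 1, pct_out = 0, p_value = 1e-6, p_adj = 1e-5,
    stringsAsFactors = FALSE)
  sel <- select_cluster_defining_np(mk, genes, max_clusters = 5)
  expect_equal(sel$NPx, c("1", "2"))      # in exactly 2 clusters: included
  expect_null(sel$NPy)                     # in max_clusters + 2: excluded
  expect_null(sel$NPz)                     # marker of no cluster: excluded
  # non-significant rows do not count
  mk2 <- mk[1:2, ]; mk2$p_adj <- 0.2
  expect_length(select_cluster_defining_np(mk2, genes), 0)
})

test_that("TF-neuropeptide correlation matches the direct formula", {
  vals <- cbind(np1 = c(0, 1, 2, 3), tf1 = c(1, 2, 4, 4),
                tf2 = c(5, 5, 5, 5), np2 = c(1, 1, 1, 1),
                tfc = c(0, 1, 2, 3))
  rownames(vals) <- sprintf("c%02d", 1:4)
  genes <- gene_ann(colnames(vals),
                    tf_class = c("none", "homeodomain", "homeodomain",
                                 "none", "zinc_finger"),
                    is_neuropeptide = c(TRUE, FALSE, FALSE, TRUE, FALSE))
  res <- suppressWarnings(
    tf_np_correlation(Matrix::Matrix(vals, sparse = TRUE), genes))
  direct <- sum((vals[, "np1"] - mean(vals[, "np1"])) *
                  (vals[, "tf1"] - mean(vals[, "tf1"]))) /
    ((4 - 1) * sd(vals[, "np1"]) * sd(vals[, "tf1"]))
  expect_equal(res$cor["tf1", "np1"], direct, tolerance = 1e-12)
  # perfectly collinear TF ranks first
  expect_equal(res$cor["tfc", "np1"], 1, tolerance = 1e-12)
  top1 <- res$top[res$top$neuropeptide == "np1", ]
  expect_equal(top1$tf[1], "tfc")
  # constant TF excluded, constant NP flagged undefined (not dropped)
  expect_false("tf2" %in% res$top$tf)
  expect_equal(res$undefined_np, "np2")
  expect_true(all(is.na(res$cor[, "np2"])))
  # symmetry under swapping vector roles
  expect_equal(res$cor["tf1", "np1"],
               cor(vals[, "np1"], vals[, "tf1"]), tolerance = 1e-12)
})
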