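test_that("bulk correlation matches the direct covariance formula", {
  prof <- rbind(cl1 = c(1, 2, 3, 4), cl2 = c(4, 3, 2, 1), cl3 = c(1, 3, 2, 4))
  colnames(prof) <- sprintf("g%d", 1:4)
  ref <- cbind(typeA = c(1.1, 2.2, 2.9, 4.1), typeB = c(2, 2, 2, 2))
  rownames(ref) <- colnames(prof)
  res <- suppressWarnings(correlate_bulk(prof, ref, gene_subset = colnames(prof)))
  for (i in 1:3) {
    expect_equal(res[i, "typeA"], cor(prof[i, ], ref[, "typeA"]),
                 tolerance = 1e-12)
  }
  # zero-variance reference column flagged undefined
  expect_true(all(is.na(res[, "typeB"])))
  # reference equal to a cluster mean gives r = 1
  ref2 <- cbind(self = prof["cl1", ])
  expect_equal(suppressWarnings(
    correlate_bulk(prof, ref2, gene_subset = colnames(prof)))["cl1", "self"],
    1, tolerance = 1e-12)
  expect_error(correlate_bulk(prof[, 1:2], ref[1:2, , drop = FALSE],
                              gene_subset = c("g1", "g2")),
               "fewer than 3")
})

test_that("identity assignment takes the maximal coefficient with tie rules", {
  co <- rbind(`1` = c(a = 0.9, b = 0.2), `2` = c(a = 0.5, b = 0.5),
              `3` = c(a = NA, b = NA))
  expect_warning(expect_warning(res <- assign_identity_by_max(co), "tie"),
                 "unassigned")
  expect_equal(res$neuron_type[res$cluster_id == "1"], "a")
  expect_equal(res$neuron_type[res$cluster_id == "2"], "a")  # first column
  expect_false("3" %in% res$cluster_id)
  expect_equal(res$method, rep("bulk_correlation", 2))
  # single reference: every cluster assigned to it
  one <- assign_identity_by_max(rbind(`1` = c(x = 0.3), `2` = c(x = -0.2)))
  expect_equal(one$neuron_type, c("x", "x"))
})

test_that("planted row maxima are recovered exactly", {
  set.seed(12)
  co <- matrix(runif(30, -1, 0.5), 6, 5,
               dimnames = list(1:6, sprintf("t%d", 1:5)))
  planted <- c(2, 4, 1, 5, 3, 2)
  for (i in 1:6) co[i, planted[i]] <- 0.9
  res <- assign_identity_by_max(co)
  expect_equal(res$neuron_type, colnames(co)[planted])
})

test_that("enhancer-gene mapping requires all genes positive", {
  sa <- rbind(`148` = c(wnt10 = 0.5, lmpt = -0.1, other = 1),
              `149` = c(wnt10 = 1.2, lmpt = 0.8, other = -1),
              `150` = c(wnt10 = -0.3, lmpt = 0.4, other = 0.2))
  drivers <- data.frame(driver_id = c("SS65380", "SSmiss"),
                        neuron_type = c("FB2A", "X"),
                        enhancer_genes = c("wnt10;lmpt", "wnt10;nope"),
                        stringsAsFactors = FALSE)
  expect_warning(res <- map_enhancer_genes(sa, drivers), "skipped")
  expect_equal(res$SS65380, "149")     # only cluster with both genes > 0
  expect_false("SSmiss" %in% names(res))
  # no qualifying cluster -> empty list entry
  sa0 <- sa; sa0[, "wnt10"] <- -1
  res0 <- map_enhancer_genes(sa0, drivers[1, , drop = FALSE])
  expect_length(res0$SS65380, 0)
  # single-gene driver: all positive clusters, ranked by value
  d1 <- data.frame(driver_id = "d", neuron_type = "y",
                   enhancer_genes = "wnt10", stringsAsFactors = FALSE)
  expect_equal(map_enhancer_genes(sa, d1)$d, c("149", "148"))
  # monotonicity: adding a gene never enlarges the candidate set
  d2 <- data.frame(driver_id = "d", neuron_type = "y",
                   enhancer_genes = "wnt10;lmpt", stringsAsFactors = FALSE)
  expect_true(all(map_enhancer_genes(sa, d2)$d %in%
                    map_enhancer_genes(sa, d1)$d))
})

test_that("marker-constraint queries evaluate signed predicates", {
  set.seed(3)
  sa <- matrix(runif(15, -1, 1), 5, 3,
               dimnames = list(as.character(c(38, 66, 105, 130, 149)),
                               c("toy", "runt", "Gg30A")))
  sa[, "toy"] <- c(0.5, -0.2, 0.8, -0.9, 0.1)
  sa[, "runt"] <- c(-0.1, 0.7, 0.2, 0.4, -0.5)
  sa[, "Gg30A"] <- c(0.3, 0.6, -0.2, 0.9, 0.1)
  cons <- data.frame(gene = c("toy", "runt"), sign = c("-", "+"),
                     stringsAsFactors = FALSE)
  res <- query_marker_constraints(sa, cons, driver_genes = "Gg30A")
  expect_equal(res, c("66", "130"))  # Toy-, Runt+, driver gene positive
  # brute-force predicate evaluation over all clusters
  brute <- rownames(sa)[sa[, "toy"] <= 0 & sa[, "runt"] > 0 &
                          sa[, "Gg30A"] > 0]
  expect_equal(res, brute)
  # contradictory constraints give an empty result with a warning
  bad <- rbind(cons, data.frame(gene = "runt", sign = "-"))
  expect_warning(res2 <- query_marker_constraints(sa, bad), "contradictory")
  expect_length(res2, 0)
  # no constraints at all returns everything with a warning
  expect_warning(res3 <- query_marker_constraints(sa, cons[0, ]), "all clusters")
  expect_equal(res3, rownames(sa))
})

test_that("repo-positive cluster selection recovers planted glial clusters", {
  a <- small_atlas()
  norm <- log_normalize(a$counts)
  cl <- stats::setNames(a$truth$cell$cluster, a$truth$cell$cell_id)
  sel <- select_marker_positive_clusters(norm, cl, "repo")
  expect_setequal(sel, as.character(a$truth$glial_ids))
  # subset conserves cell count
  cells_sel <- names(cl)[as.character(cl) %in% sel]
  expect_equal(length(cells_sel), sum(table(cl)[sel]))
  expect_error(select_marker_positive_clusters(norm, cl, "nogene"),
               "not present")
})

test_that("panel annotation assigns single and overlapping identities", {
  sa <- rbind(`1` = c(alrm = 1, Gat = 0.5, zyd = -1, trol = -0.5),
              `2` = c(alrm = 0.8, Gat = 0.2, zyd = 0.9, trol = 0.4),
              `3` = c(alrm = -1, Gat = -0.2, zyd = -0.3, trol = -0.8))
  panels <- list(astrocyte = c("alrm", "Gat"), ensheathing = c("zyd", "trol"))
  lab <- annotate_by_marker_panel(sa, panels)
  expect_equal(unname(lab["1"]), "astrocyte")
  expect_equal(unname(lab["2"]), "astrocyte/ensheathing")
  expect_equal(unname(lab["3"]), "unannotated")
  # absent panel genes are dropped with a warning
  panels2 <- list(astrocyte = c("alrm", "missing"))
  expect_warning(lab2 <- annotate_by_marker_panel(sa, panels2), "absent")
  expect_equal(unname(lab2["1"]), "astrocyte")
  expect_error(annotate_by_marker_panel(sa, list()), "nonempty")
})

test_that("planted glial subtypes are recovered from scaled averages", {
  a <- small_atlas()
  norm <- log_normalize(a$counts)
  cl <- stats::setNames(a$truth$cell$cluster, a$truth$cell$cell_id)
  sa <- scaled_average_expression(norm, cl)
  panels <- split(a$genes$gene_id[!a$genes$glial_panel %in%
                                    c("none", "pan_glial")],
                  a$genes$glial_panel[!a$genes$glial_panel %in%
                                        c("none", "pan_glial")])
  glial <- as.character(a$truth$glial_ids)
  lab <- annotate_by_marker_panel(sa[glial, , drop = FALSE], panels)
  # every planted subtype is recovered (panels planted nowhere in the data
  # carry only z-score noise, so the call list may contain extras)
  for (g in glial) {
    expect_true(all(a$truth$glial_subtypes[[g]] %in%
                      strsplit(lab[[g]], "/")[[1]]))
  }
})
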