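bc <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("tf%02d", seq_len(ncol(m)))
  new_binary_code(m, "homeodomain")
}

test_that("binarization marks significant positive TF markers", {
  genes <- gene_ann(c("hd.01", "hd.02", "zf.01"),
                    tf_class = c("homeodomain", "homeodomain", "zinc_finger"))
  mk <- data.frame(cluster = c("2", "5", "2"),
                   gene = c("hd.01", "hd.01", "hd.02"),
                   log2fc = 1, pct_in = 1, pct_out = 0,
                   p_value = c(1e-6, 1e-6, 0.5),
                   p_adj = c(1e-5, 1e-5, 0.9), stringsAsFactors = FALSE)
  code <- binarize_tf_markers(mk, genes, "homeodomain",
                              cluster_ids = as.character(1:5))
  expect_equal(unname(code$matrix[, "hd.01"]), c(0L, 1L, 0L, 0L, 1L))
  # non-significant entry stays 0; never-significant TF kept as zero column
  expect_equal(sum(code$matrix[, "hd.02"]), 0L)
  expect_equal(colnames(code$matrix), c("hd.01", "hd.02"))
  expect_error(binarize_tf_markers(mk, genes, "hmg"), "no TFs")
  # empty marker table -> all-zero matrix
  code0 <- binarize_tf_markers(mk[0, ], genes, "homeodomain",
                               cluster_ids = as.character(1:3))
  expect_equal(sum(code0$matrix), 0L)
})

test_that("uniqueness counting matches pairwise brute force", {
  brute_unique <- function(m) {
    u <- 0
    for (i in seq_len(nrow(m))) {
      dup <- FALSE
      for (j in seq_len(nrow(m))) {
        if (i != j && all(m[i, ] == m[j, ])) dup <- TRUE
      }
      if (!dup) u <- u + 1
    }
    u
  }
  set.seed(33)
  for (rep in 1:20) {
    m <- matrix(rbinom(20 * 6, 1, 0.4), 20, 6)
    code <- bc(m)
    res <- count_unique_codes(code)
    expect_equal(res$n_unique, brute_unique(m))
    expect_equal(res$pct_unique, round(100 * res$n_unique / 20, 1))
  }
  all_same <- bc(matrix(1L, 4, 3))
  expect_equal(count_unique_codes(all_same),
               list(n_unique = 0L, pct_unique = 0))
})

test_that("shared-code groups partition the non-unique clusters", {
  m <- rbind(A = c(1, 0), B = c(1, 0), C = c(0, 1), D = c(0, 1),
             E = c(1, 1))
  colnames(m) <- c("t1", "t2")
  code <- new_binary_code(m, "homeodomain")
  groups <- shared_code_groups(code)
  expect_equal(groups, list(c("A", "B"), c("C", "D")))
  expect_equal(length(shared_code_groups(bc(diag(3)))), 0)
  # conservation: n_unique + sum of group sizes = n_clusters
  set.seed(7)
  for (rep in 1:10) {
    mm <- matrix(rbinom(15 * 4, 1, 0.5), 15, 4)
    cd <- bc(mm)
    expect_equal(count_unique_codes(cd)$n_unique +
                   sum(lengths(shared_code_groups(cd))), 15L)
  }
})

test_that("Jaccard matrix matches set enumeration", {
  m <- rbind(c(1, 1, 0, 0), c(1, 0, 1, 0))
  code <- bc(m)
  j <- jaccard_matrix(code)
  expect_equal(j[1, 2], 1 / 3)  # intersection 1, union 3
  expect_equal(diag(j), c(`1` = 1, `2` = 1))
  ident <- bc(rbind(c(1, 0), c(1, 0)))
  expect_equal(jaccard_matrix(ident)[1, 2], 1)
  disjoint <- bc(rbind(c(1, 0), c(0, 1)))
  expect_equal(jaccard_matrix(disjoint)[1, 2], 0)
  both_empty <- bc(rbind(c(0, 0), c(0, 0)))
  expect_equal(jaccard_matrix(both_empty)[1, 2], 1)  # identical empty codes
})

test_that("uniqueness is recoverable from the Jaccard matrix alone", {
  set.seed(5)
  m <- matrix(rbinom(12 * 5, 1, 0.4), 12, 5)
  code <- bc(m)
  j <- jaccard_matrix(code)
  # J(a,b) = 1 with equal set sizes <=> identical rows (both-empty included)
  sz <- rowSums(m)
  dup_from_j <- sapply(1:12, function(i)
    any(j[i, -i] == 1 & sz[-i] == sz[i]))
  expect_equal(12 - sum(dup_from_j), count_unique_codes(code)$n_unique)
})

test_that("similarity ordering keeps similar clusters adjacent", {
  m <- rbind(A = c(1, 1, 0, 0), B = c(1, 1, 0, 0), C = c(0, 0, 1, 1))
  colnames(m) <- sprintf("t%d", 1:4)
  ord <- order_by_similarity(jaccard_matrix(new_binary_code(m, "hmg")))
  expect_equal(abs(diff(match(c("A", "B"), ord))), 1)  # identical pair adjacent
  # block-diagonal similarity: each block contiguous
  blocks <- rbind(a1 = c(1, 1, 0, 0, 0, 0), a2 = c(1, 0, 0, 0, 0, 0),
                  a3 = c(1, 1, 1, 0, 0, 0), b1 = c(0, 0, 0, 1, 1, 0),
                  b2 = c(0, 0, 0, 1, 0, 1), b3 = c(0, 0, 0, 0, 1, 1))
  colnames(blocks) <- sprintf("t%d", 1:6)
  ord2 <- order_by_similarity(jaccard_matrix(new_binary_code(blocks, "hmg")))
  pos_a <- sort(match(c("a1", "a2", "a3"), ord2))
  expect_equal(pos_a, pos_a[1]:(pos_a[1] + 2))
  # relabeling clusters permutes the order consistently
  perm <- c(3, 1, 2, 6, 4, 5)
  blocks_p <- blocks[perm, ]
  ord3 <- order_by_similarity(jaccard_matrix(new_binary_code(blocks_p, "hmg")))
  expect_setequal(ord3, rownames(blocks))
  expect_equal(sort(match(c("a1", "a2", "a3"), ord3)) -
                 min(match(c("a1", "a2", "a3"), ord3)), 0:2)
})
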