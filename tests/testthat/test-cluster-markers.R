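test_that("PCA embedding captures constructed geometry deterministically", {
  set.seed(1)
  # rank-1 data: one direction carries ~all variance
  u <- rnorm(60); v <- rnorm(20)
  x1 <- outer(u, v) + matrix(rnorm(1200, sd = 1e-3), 60)
  x1 <- scale(x1, scale = FALSE)
  emb1 <- embed_pca(x1, 3, seed = 1)
  expect_gt(var(emb1[, 1]) / sum(apply(emb1, 2, var)), 0.99)

  # two orthogonal blobs separate on PC1 (silhouette > 0.8)
  grp <- rep(c(0, 1), each = 40)
  x2 <- cbind(matrix(rnorm(80 * 5, sd = 0.2), 80) + outer(grp, rep(5, 5)),
              matrix(rnorm(80 * 5, sd = 0.2), 80))
  x2 <- scale(x2)
  emb2 <- embed_pca(x2, 2, seed = 1)
  sil <- function(p, g) {
    d <- as.matrix(dist(p))
    mean(sapply(seq_along(g), function(i) {
      a <- mean(d[i, g == g[i]][-which(which(g == g[i]) == i)])
      b <- mean(d[i, g != g[i]])
      (b - a) / max(a, b)
    }))
  }
  expect_gt(sil(emb2[, 1, drop = FALSE], grp), 0.8)

  expect_identical(embed_pca(x2, 2, seed = 7), embed_pca(x2, 2, seed = 7))
  expect_error(embed_pca(x2, 100, seed = 1), "exceeds")
})

test_that("graph clustering recovers well-separated blobs", {
  set.seed(2)
  centers <- rbind(c(10, 0), c(-10, 0))
  g <- rep(1:2, each = 60)
  emb <- centers[g, ] + matrix(rnorm(240, sd = 0.5), 120)
  rownames(emb) <- sprintf("c%03d", 1:120)
  cl <- cluster_cells(emb, k_neighbors = 30, seed = 1)
  expect_equal(length(unique(cl)), 2)
  expect_equal(mclust::adjustedRandIndex(cl, g), 1)
  expect_identical(cl, cluster_cells(emb, k_neighbors = 30, seed = 1))
  expect_error(cluster_cells(emb[1:5, ], k_neighbors = 10), "at least")
})

test_that("identical points collapse to one cluster", {
  emb <- matrix(1, 30, 2, dimnames = list(sprintf("c%02d", 1:30), NULL))
  cl <- suppressWarnings(cluster_cells(emb, k_neighbors = 5, seed = 1))
  expect_equal(length(unique(cl)), 1)
})

# independent oracle: enumerate all group assignments over bitmasks
oracle_ranksum_p <- function(x_in, x_out) {
  r <- rank(c(x_in, x_out))
  n <- length(r); n1 <- length(x_in)
  mu <- n1 * (n + 1) / 2
  obs <- abs(sum(r[seq_len(n1)]) - mu)
  hits <- 0; total <- 0
  for (mask in 0:(2^n - 1)) {
    if (sum(bitwAnd(mask, 2^(0:(n - 1))) > 0) != n1) next
    total <- total + 1
    w <- sum(r[bitwAnd(mask, 2^(0:(n - 1))) > 0])
    if (abs(w - mu) >= obs - 1e-12) hits <- hits + 1
  }
  hits / total
}

test_that("marker ranking matches the exact rank-sum distribution for small
           groups", {
  # gene expressed only in one cluster, 5 vs 5 cells: smallest achievable p
  vals <- c(rep(2, 5), rep(0, 5))
  m <- count_mat(cbind(vals, c(1:5, 1:5)), genes = c("gX", "gY"))
  cl <- stats::setNames(rep(c(1, 2), each = 5), rownames(m))
  tab <- rank_markers(m, cl, min_pct = 0, min_log2fc = 0)
  p_gx <- tab$p_value[tab$cluster == "1" & tab$gene == "gX"]
  expect_equal(p_gx, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(p_gx, oracle_ranksum_p(vals[1:5], vals[6:10]),
               tolerance = 1e-12)
})

test_that("genes with identical distributions are prefiltered out", {
  m <- count_mat(cbind(rep(3, 10), c(rep(4, 5), rep(0, 5))),
                 genes = c("same", "diff"))
  cl <- stats::setNames(rep(c(1, 2), each = 5), rownames(m))
  tab <- rank_markers(m, cl)
  expect_false("same" %in% tab$gene)  # log2fc = 0 prefiltered
  expect_true("diff" %in% tab$gene)
})

test_that("BH adjustment is monotone and bounded within clusters", {
  mk <- recovery_markers()
  for (k in unique(mk$cluster)[1:5]) {
    sub <- mk[mk$cluster == k, ]
    ord <- order(sub$p_value)
    expect_true(all(diff(sub$p_adj[ord]) >= -1e-12))
    expect_true(all(sub$p_adj <= 1 & sub$p_adj >= sub$p_value - 1e-12))
  }
})

test_that("top_markers applies the documented total order", {
  tab <- data.frame(
    cluster = "1", gene = c("b", "a", "c", "d"),
    log2fc = c(2, 2, 3, 1), pct_in = 1, pct_out = 0,
    p_value = c(0.01, 0.01, 0.01, 0.2),
    p_adj = c(0.02, 0.02, 0.02, 0.4), stringsAsFactors = FALSE)
  top <- top_markers(tab, n = 10)
  # brute-force sort: p_adj asc, log2fc desc, gene id
  expect_equal(top[["1"]], c("c", "a", "b", "d"))
  expect_equal(top_markers(tab, n = 2)[["1"]], c("c", "a"))
  # fewer markers than n returns all
  expect_length(top_markers(tab[1:3, ], n = 10)[["1"]], 3)
})

test_that("normal-approximation p-values agree with R's wilcox.test", {
  set.seed(9)
  vals <- c(rpois(30, 2), rpois(70, 4))
  m <- count_mat(cbind(vals, rpois(100, 1) + 1), genes = c("g1", "g2"))
  cl <- stats::setNames(rep(c(1, 2), c(30, 70)), rownames(m))
  tab <- rank_markers(m, cl, min_pct = 0, min_log2fc = 0, mode = "signed")
  ref <- suppressWarnings(stats::wilcox.test(
    vals[1:30], vals[31:100], exact = FALSE, correct = TRUE))
  p_pkg <- tab$p_value[tab$cluster == "1" & tab$gene == "g1"]
  expect_equal(p_pkg, ref$p.value, tolerance = 1e-10)
})
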