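test_that("the outlier filter is strict, per-channel by default, idempotent", {
  mfi <- rbind(rep(10, 3), c(3000, 10, 10), c(3001, 10, 10))
  x <- manual_secretome(mfi)
  xf <- filter_outlier_cells(x)
  expect_equal(nrow(xf$cells), 2)    # only the 3001 cell removed
  rep <- attr(xf, "removal_report")
  expect_equal(rep$n_removed, 1)
  # idempotent
  xff <- filter_outlier_cells(xf)
  expect_equal(xff$cells, xf$cells)

  # total mode sums across the panel
  xt <- filter_outlier_cells(x, mode = "total", threshold = 3020)
  expect_equal(nrow(xt$cells), 2)    # 3001+20 > 3020 removed
})

test_that("planted outliers are removed exactly", {
  m <- three_pop_model(outlier_rate = 0.01)
  x <- simulate_cohort(small_design(cells = 1000), m, seed = 17)
  tr <- truth_labels(x)
  xf <- filter_outlier_cells(x)
  expect_setequal(setdiff(x$cells$cell_id, xf$cells$cell_id),
                  tr$cell_id[tr$outlier])
})

test_that("log normalization matches its closed form and is monotone", {
  mfi <- rbind(c(0, 0, 0), c(80, 0, 0), c(10, 20, 40))
  x <- manual_secretome(mfi)
  norm <- normalize_log(x, scale_factor = 1e4)
  # all-zero cell stays zero and is flagged
  expect_true(all(norm[1, ] == 0))
  expect_equal(attr(norm, "zero_cells"), 1L)
  # single nonzero channel maps to ln(1 + scale_factor)
  expect_equal(norm[2, 1], log1p(1e4))
  # within-cell monotonicity
  expect_true(norm[3, 1] < norm[3, 2] && norm[3, 2] < norm[3, 3])
})

test_that("variable-feature ranking puts constant features last", {
  set.seed(2)
  norm <- cbind(matrix(rnorm(100 * 3), 100, 3), rep(1, 100))
  colnames(norm) <- c("v1", "v2", "v3", "flat")
  top <- select_variable_features(norm, 4)
  expect_length(top, 4)
  rk <- attr(top, "ranking")
  expect_equal(rk$feature[4], "flat")
  expect_equal(sort(select_variable_features(norm, 3)),
               sort(c("v1", "v2", "v3")))
})

test_that("signature cytokines rank above background in variability", {
  x <- simulate_cohort(small_design(cells = 400), separated_model(2),
                       seed = 23)
  norm <- normalize_log(x)
  rk <- attr(select_variable_features(norm), "ranking")
  sig <- c("IFNg", "TNFa", "MIP-1b", "IL8", "IL4", "IL10", "IL13", "TGFb1")
  expect_true(all(match(sig, rk$feature) <= 8))
})

test_that("PCA recovers a planted rank-1 direction", {
  set.seed(14)
  dir <- rnorm(20)
  dir <- dir / sqrt(sum(dir^2))
  scores_true <- rnorm(500, 0, 5)
  dat <- outer(scores_true, dir) + matrix(rnorm(500 * 20, 0, 0.1), 500)
  pcs <- run_pca(dat, 3)
  loading <- attr(pcs, "rotation")[, 1]
  expect_gt(abs(sum(loading * dir)), 0.99)
  # duplicated rows get identical scores
  dat2 <- rbind(dat[1:10, ], dat[1:10, ])
  pcs2 <- run_pca(dat2, 2)
  expect_equal(pcs2[1:10, ], pcs2[11:20, ], ignore_attr = TRUE)
})

test_that("isotropic data spreads variance evenly across PCs", {
  set.seed(21)
  dat <- matrix(rnorm(3000 * 8), 3000, 8)
  pcs <- run_pca(dat, 8)
  sdev <- attr(pcs, "sdev")
  expect_lt(max(sdev) / min(sdev), 1.25)
})

test_that("batch correction removes a pure shift but not biology", {
  set.seed(9)
  base <- matrix(rnorm(1500 * 5), 1500, 5)
  batch <- rep(c("a", "b"), length.out = 1500)
  shift <- c(4, -3, 2, 0, 0)
  shifted <- base + outer(batch == "b", shift) * 1
  pre <- sqrt(sum((colMeans(shifted[batch == "a", ]) -
                   colMeans(shifted[batch == "b", ]))^2))
  corr <- correct_batch(shifted, batch, seed = 3)
  post <- sqrt(sum((colMeans(corr[batch == "a", ]) -
                    colMeans(corr[batch == "b", ]))^2))
  expect_lt(post, 0.1 * pre)
  expect_gte(batch_mixing_entropy(corr, batch, 20),
             batch_mixing_entropy(shifted, batch, 20))

  # single batch: identity
  expect_equal(correct_batch(base, rep("a", 1500)), base)
})

test_that("composition-confounded batches are not over-corrected", {
  skip_if_not_installed("mclust")
  set.seed(4)
  # the same two populations in both batches, at confounded proportions
  # (70/30 vs 30/70) and with no batch shift: the batch centroids differ
  # by composition alone, and naive centering would split both
  # populations
  mk <- function(center, n) {
    sweep(matrix(rnorm(n * 5), n, 5), 2, center, `+`)
  }
  pops <- rbind(mk(c(6, 0, 0, 0, 0), 700), mk(c(0, 6, 0, 0, 0), 300),
                mk(c(6, 0, 0, 0, 0), 300), mk(c(0, 6, 0, 0, 0), 700))
  truth <- c(rep(1, 700), rep(2, 300), rep(1, 300), rep(2, 700))
  batch <- rep(c("a", "b"), each = 1000)
  corr <- correct_batch(pops, batch, seed = 3)
  km0 <- stats::kmeans(pops, 2, nstart = 10)$cluster
  km1 <- stats::kmeans(corr, 2, nstart = 10)$cluster
  ari0 <- mclust::adjustedRandIndex(km0, truth)
  ari1 <- mclust::adjustedRandIndex(km1, truth)
  expect_gt(ari1, ari0 - 0.1)
})

test_that("kNN graph matches a brute-force construction", {
  set.seed(6)
  pts <- matrix(rnorm(200 * 4), 200, 4)
  k <- 10
  g <- build_knn_graph(pts, k)
  d <- as.matrix(dist(pts))
  diag(d) <- Inf
  adj_brute <- matrix(FALSE, 200, 200)
  for (i in 1:200) {
    nn <- order(d[i, ])[1:k]
    adj_brute[i, nn] <- TRUE
  }
  adj_brute <- adj_brute | t(adj_brute)
  adj_g <- as.matrix(igraph::as_adjacency_matrix(g)) > 0
  expect_equal(unname(adj_g), unname(adj_brute))
})

test_that("collinear points and duplicates give reproducible graphs", {
  pts <- cbind(c(0, 1, 2), 0)
  g <- build_knn_graph(pts, 1)
  adj <- as.matrix(igraph::as_adjacency_matrix(g))
  expect_equal(sum(adj[2, ]), 2)   # middle point connected to both ends

  dup <- matrix(rep(c(0, 0, 1, 1), each = 6), ncol = 2)
  g1 <- build_knn_graph(dup, 3)
  g2 <- build_knn_graph(dup, 3)
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
})

test_that("two disconnected cliques yield exactly two clusters", {
  g <- igraph::disjoint_union(igraph::make_full_graph(10),
                              igraph::make_full_graph(12))
  cl <- cluster_graph(g, 0.8, seed = 1)
  expect_equal(length(unique(cl)), 2)
  expect_equal(sort(unique(cl)), c(0, 1))
  # size-ordered labels: the larger clique is cluster 0
  expect_equal(unique(cl[11:22]), 0)
  expect_identical(cl, cluster_graph(g, 0.8, seed = 1))
})

test_that("clustering at low resolution recovers separated populations", {
  skip_if_not_installed("mclust")
  x <- simulate_cohort(small_design(cells = 300), separated_model(3),
                       seed = 30)
  norm <- normalize_log(x)
  pcs <- run_pca(norm, 10)
  g <- build_knn_graph(pcs, 20)
  cl <- cluster_graph(g, 0.1, seed = 2)
  ari <- mclust::adjustedRandIndex(cl, truth_labels(x)$population)
  expect_gt(ari, 0.9)
})

test_that("UMAP is reproducible and separates planted populations", {
  x <- simulate_cohort(small_design(n_patients = 2, cells = 150,
                                    availability = c("PB:baseline" = 2)),
                       separated_model(2), seed = 3)
  pcs <- run_pca(normalize_log(x), 5)
  u1 <- run_umap(pcs, seed = 42)
  u2 <- run_umap(pcs, seed = 42)
  expect_identical(u1, u2)
  tr <- truth_labels(x)$population
  cent <- rowsum(u1, tr) / as.vector(table(tr))
  between <- sqrt(sum((cent[1, ] - cent[2, ])^2))
  within <- mean(sqrt(rowSums((u1 - cent[tr, ])^2)))
  expect_gt(between, within)
})

test_that("UMAP survives degenerate identical inputs", {
  pts <- matrix(1, 10, 4)
  u <- run_umap(pts, seed = 1)
  expect_true(all(is.finite(u)))
  expect_equal(dim(u), c(10, 2))
})

test_that("the pipeline is reproducible end to end and filter-stable", {
  x <- simulate_cohort(small_design(cells = 120),
                       three_pop_model(outlier_rate = 0.01), seed = 44)
  cfg <- pipeline_config(knn_k = 10, seed = 5)
  e1 <- run_pipeline(x, cfg)
  e2 <- run_pipeline(x, cfg)
  expect_identical(e1$clusters, e2$clusters)
  expect_equal(e1$corrected_pcs, e2$corrected_pcs)
  expect_identical(e1$umap, e2$umap)
  # filtering is part of the pipeline: filtered input gives same result
  e3 <- run_pipeline(filter_outlier_cells(x, cfg), cfg)
  expect_identical(e1$clusters, e3$clusters)
})
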