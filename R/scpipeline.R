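#' Configuration of the single-cell embedding pipeline
#'
#' @param outlier_threshold MFI above which a cell is an outlier
#'   (default 3000, strict inequality).
#' @param outlier_mode `"any_channel"` (a cell is removed iff any single
#'   cytokine exceeds the threshold) or `"total"` (iff the summed MFI
#'   does).
#' @param scale_factor Global scaling constant of the log normalization
#'   (default 10,000).
#' @param n_variable_features Number of variable cytokines retained
#'   (default all 32; the ranking machinery exists for larger panels).
#' @param n_pcs Number of principal components (default 10).
#' @param knn_k Neighbors per cell in the kNN graph (default 20).
#' @param cluster_resolution Leiden modularity resolution (default 0.8).
#' @param seed Integer seed for the stochastic stages (clustering, UMAP,
#'   neighborhood sampling).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(outlier_threshold = 3000,
                            outlier_mode = c("any_channel", "total"),
                            scale_factor = 1e4,
                            n_variable_features = 32,
                            n_pcs = 10, knn_k = 20,
                            cluster_resolution = 0.8, seed = 1) {
  outlier_mode <- match.arg(outlier_mode)
  stopifnot(outlier_threshold > 0, scale_factor > 0, n_pcs >= 1,
            knn_k >= 2, cluster_resolution > 0)
  structure(list(outlier_threshold = outlier_threshold,
                 outlier_mode = outlier_mode,
                 scale_factor = scale_factor,
                 n_variable_features = n_variable_features,
                 n_pcs = n_pcs, knn_k = knn_k,
                 cluster_resolution = cluster_resolution,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Remove high-MFI outlier cells
#'
#' Removes cells whose MFI exceeds the configured threshold — per channel
#' (`any_channel`, default: max over cytokines > threshold) or summed
#' over the panel (`total`). The comparison is strict, so a cell exactly
#' at the threshold is kept. Idempotent.
#'
#' @param x A `secretome`.
#' @param config A `pipeline_config` (or use `threshold`/`mode`
#'   directly).
#' @param threshold,mode Shortcuts overriding `config`.
#' @return The filtered `secretome`; attribute `removal_report` holds a
#'   per-sample tibble of removed/kept counts.
#' @export
filter_outlier_cells <- function(x, config = pipeline_config(),
                                 threshold = config$outlier_threshold,
                                 mode = config$outlier_mode) {
  stopifnot(inherits(x, "secretome"))
  m <- mfi_matrix(x)
  stat <- if (mode == "any_channel") {
    apply(m, 1, max)
  } else {
    rowSums(m)
  }
  drop <- stat > threshold
  report <- x$cells |>
    dplyr::mutate(.drop = drop) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(n_removed = sum(.data$.drop),
                     n_kept = sum(!.data$.drop), .groups = "drop")
  out <- filter_cells(x, !drop)
  attr(out, "removal_report") <- report
  out
}

#' Global-scaling log normalization
#'
#' Per cell, maps each value to `ln(1 + value / cell_total *
#' scale_factor)` — the standard single-cell global-scaling log
#' transform. Cells with zero total MFI map to all-zero rows and are
#' flagged in the `zero_cells` attribute.
#'
#' @param x A `secretome` or a nonnegative matrix.
#' @param scale_factor Scaling constant (default 10,000).
#' @return Normalized matrix (same shape; rownames = cell ids).
#' @export
normalize_log <- function(x, scale_factor = 1e4) {
  m <- if (inherits(x, "secretome")) mfi_matrix(x) else as.matrix(x)
  tot <- rowSums(m)
  zero <- tot == 0
  scl <- ifelse(zero, 0, scale_factor / tot)
  out <- log1p(m * scl)
  attr(out, "zero_cells") <- unname(which(zero))
  out
}

#' Rank cytokines by standardized variance
#'
#' Ranks features by the variance left after removing the mean-variance
#' trend across features (loess of log variance on log mean, the
#' standard variable-feature heuristic). With only 32 cytokines the
#' default pipeline keeps all features; the ranking exists for larger
#' panels and for inspection.
#'
#' @param normalized Normalized matrix from [normalize_log()].
#' @param n Number of features to retain.
#' @return Character vector of the top `n` feature names; attribute
#'   `ranking` holds the full tibble (mean, variance, standardized
#'   variance).
#' @export
select_variable_features <- function(normalized, n = ncol(normalized)) {
  stopifnot(n >= 1, n <= ncol(normalized))
  mu <- colMeans(normalized)
  v <- apply(normalized, 2, stats::var)
  pos <- v > 0 & mu > 0
  std_var <- rep(-Inf, length(v))   # constant features rank last
  if (sum(pos) >= 4) {
    fit <- stats::loess(log10(v[pos]) ~ log10(mu[pos]), span = 1,
                        degree = 2)
    std_var[pos] <- log10(v[pos]) - stats::fitted(fit)
  } else {
    std_var[pos] <- v[pos]
  }
  ord <- order(std_var, decreasing = TRUE)
  ranking <- tibble::tibble(feature = colnames(normalized)[ord],
                            mean = mu[ord], variance = v[ord],
                            standardized_variance = std_var[ord])
  out <- ranking$feature[seq_len(n)]
  attr(out, "ranking") <- ranking
  out
}

#' Principal component scores
#'
#' Feature-centered (unscaled) PCA. Deterministic; the sign of each
#' component is fixed by making its largest-magnitude loading positive.
#'
#' @param normalized Matrix (cells x features).
#' @param n_pcs Number of components.
#' @param seed Accepted for interface uniformity; the computation is
#'   deterministic.
#' @return Scores matrix (cells x `n_pcs`); attribute `sdev` holds the
#'   component standard deviations, `rotation` the loadings.
#' @export
run_pca <- function(normalized, n_pcs = 10, seed = NULL) {
  rk <- min(nrow(normalized) - 1L, ncol(normalized))
  if (n_pcs > rk) {
    warning("n_pcs reduced to rank ", rk)
    n_pcs <- rk
  }
  pc <- stats::prcomp(normalized, center = TRUE, scale. = FALSE,
                      rank. = n_pcs)
  flip <- apply(pc$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, `*`)
  rownames(scores) <- rownames(normalized)
  attr(scores, "sdev") <- pc$sdev[seq_len(n_pcs)]
  attr(scores, "rotation") <- sweep(pc$rotation, 2, flip, `*`)
  scores
}

#' kNN batch-mixing entropy
#'
#' Average over cells of the entropy (natural log) of batch labels among
#' each cell's k nearest neighbors — higher means better mixed. Batches
#' with fewer cells than `k` are excluded from the average (their cells
#' cannot be fully surrounded by same-batch neighbors).
#'
#' @param pcs Embedding matrix (cells x dims).
#' @param batch Batch label per cell.
#' @param k Neighbors (default 20).
#' @return Mean entropy (scalar).
#' @export
batch_mixing_entropy <- function(pcs, batch, k = 20) {
  batch <- as.character(batch)
  k <- min(k, nrow(pcs) - 1)
  nn <- RANN::nn2(pcs, k = k + 1)$nn.idx[, -1, drop = FALSE]
  keep <- batch %in% names(which(table(batch) >= k))
  ent <- vapply(which(keep), function(i) {
    p <- table(batch[nn[i, ]]) / k
    -sum(p * log(p))
  }, 0)
  mean(ent)
}

#' Patient-level batch correction in PC space
#'
#' Iterative soft-clustering correction: alternately (a) assign cells
#' softly to `nclust` centroids with a diversity penalty that rewards
#' batch-mixed clusters, and (b) remove, per cluster, the batch-specific
#' centroid offsets (each cell is shifted by the responsibility-weighted
#' difference between its batch's within-cluster centroid and the
#' cluster centroid). Iterations stop when the maximum centroid shift
#' drops below `tol` or after `max_iter` rounds.
#'
#' Contract (verified on synthetic data): pure batch shifts with shared
#' biology are removed (post-correction batch centroid distance under
#' 10% of pre-correction), while genuinely distinct populations confined
#' to different batches are left essentially intact, because a
#' batch-pure cluster's batch centroid coincides with its cluster
#' centroid.
#'
#' The corrected embedding is accepted only when it does not reduce the
#' kNN batch-mixing entropy of the input; otherwise the input is
#' returned unchanged (attribute `accepted` reports which happened).
#' This guards against the translation artifact where per-batch shifts
#' estimated from composition noise locally sort well-mixed data by
#' batch.
#'
#' @param pcs PC scores (cells x dims).
#' @param batch Batch (patient) label per cell; >= 2 batches required
#'   for any correction (a single batch returns the input).
#' @param nclust Number of soft clusters (default 30, capped at n/50).
#' @param theta Diversity-penalty strength (default 1; 0 disables).
#' @param max_iter,tol Stopping rule.
#' @param seed Seed for centroid initialization.
#' @param entropy_k Neighborhood size of the acceptance entropy check.
#' @return Corrected matrix, same shape as `pcs`.
#' @export
correct_batch <- function(pcs, batch, nclust = 30, theta = 1,
                          max_iter = 10, tol = 1e-3, seed = 1,
                          entropy_k = 20) {
  batch <- as.character(batch)
  stopifnot(nrow(pcs) == length(batch))
  batches <- unique(batch)
  if (length(batches) < 2) return(pcs)
  n <- nrow(pcs)
  nclust <- max(2L, min(as.integer(nclust), n %/% 50L, n - 1L))
  set.seed(seed)
  z <- pcs
  km <- stats::kmeans(z, centers = nclust, nstart = 5, iter.max = 50)
  centers <- km$centers
  bmat <- outer(batch, batches, `==`) * 1  # cells x batches indicator
  prop_b <- colMeans(bmat)
  band_within <- max(km$tot.withinss / n, 1e-12)
  band_global <- max(sum(apply(pcs, 2, stats::var)), band_within)

  for (it in seq_len(max_iter)) {
    # anneal the assignment bandwidth from global to within-cluster
    # scale: early iterations act like global batch centering (able to
    # bridge large shifts), later ones refine per-cluster offsets
    band <- max(band_within, band_global / 2^(it - 1))
    d2 <- outer(rowSums(z^2), rowSums(centers^2), `+`) -
      2 * z %*% t(centers)
    r <- exp(-(d2 - apply(d2, 1, min)) / band)
    # diversity penalty: down-weight joining clusters already dominated
    # by the cell's own batch
    o <- t(bmat) %*% r + 1e-8                  # batches x clusters observed
    e <- outer(prop_b, colSums(r)) + 1e-8      # expected under mixing
    pen <- (e / o)^theta                       # batches x clusters
    r <- r * (bmat %*% pen)
    r <- r / rowSums(r)

    new_centers <- (t(r) %*% z) / colSums(r)
    # per-cluster, per-batch offset removal
    corr <- matrix(0, n, ncol(z))
    for (c in seq_len(nclust)) {
      rc <- r[, c]
      mu_c <- colSums(z * rc) / sum(rc)
      for (b in seq_along(batches)) {
        sel <- bmat[, b] == 1
        wb <- rc[sel]
        if (sum(wb) < 1e-6) next
        mu_cb <- colSums(z[sel, , drop = FALSE] * wb) / sum(wb)
        corr[sel, ] <- corr[sel, ] +
          outer(wb, mu_cb - mu_c)
      }
    }
    z <- z - corr
    shift <- max(sqrt(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (shift < tol) break
  }
  dimnames(z) <- dimnames(pcs)
  pre <- batch_mixing_entropy(pcs, batch, entropy_k)
  post <- batch_mixing_entropy(z, batch, entropy_k)
  if (is.nan(pre) || is.nan(post) || post >= pre) {
    attr(z, "accepted") <- TRUE
    z
  } else {
    out <- pcs
    attr(out, "accepted") <- FALSE
    out
  }
}

#' Build an exact kNN graph
#'
#' Undirected graph with an edge iff either endpoint lists the other
#' among its `k` Euclidean nearest neighbors (self excluded); ties are
#' broken by cell index, so the graph is reproducible.
#'
#' @param pcs Embedding matrix (cells x dims), rownames = cell ids.
#' @param k Neighbors per cell.
#' @return An `igraph` graph; vertex names are cell ids, graph attribute
#'   `nn_index` holds the raw cells x k neighbor-index matrix and
#'   `nn_dist` the matching distances.
#' @export
build_knn_graph <- function(pcs, k = 20) {
  n <- nrow(pcs)
  stopifnot(k < n)
  nn <- RANN::nn2(pcs, k = k + 1, eps = 0)
  idx <- nn$nn.idx
  dst <- nn$nn.dists
  # drop self (guaranteed somewhere in the first columns under ties)
  nn_index <- matrix(0L, n, k)
  nn_dist <- matrix(0, n, k)
  for (i in seq_len(n)) {
    row <- idx[i, ]
    self <- match(i, row)
    keep <- if (is.na(self)) seq_len(k) else setdiff(seq_len(k + 1), self)[seq_len(k)]
    nn_index[i, ] <- row[keep]
    nn_dist[i, ] <- dst[i, keep]
  }
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nn_index)))
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  edges <- unique(cbind(pmin(edges[, 1], edges[, 2]),
                        pmax(edges[, 1], edges[, 2])))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::V(g)$name <- rownames(pcs) %||% as.character(seq_len(n))
  g <- igraph::set_graph_attr(g, "nn_index", nn_index)
  g <- igraph::set_graph_attr(g, "nn_dist", nn_dist)
  g
}

#' Leiden community detection on the kNN graph
#'
#' Modularity-based Leiden clustering at the configured resolution.
#' Labels are relabeled by decreasing cluster size and are contiguous
#' integers starting at 0 (the single-cell convention). Deterministic
#' given `seed`.
#'
#' @param knn An `igraph` graph from [build_knn_graph()].
#' @param resolution Modularity resolution (default 0.8).
#' @param seed Integer seed.
#' @return Integer vector of cluster labels (0-based), one per vertex.
#' @export
cluster_graph <- function(knn, resolution = 0.8, seed = 1) {
  set.seed(seed)
  cl <- igraph::cluster_leiden(knn, objective_function = "modularity",
                               resolution = resolution,
                               n_iterations = 5)
  memb <- igraph::membership(cl)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  unname(relabel[as.character(memb)])
}

#' Sweep the clustering resolution
#'
#' Runs [cluster_graph()] over a grid of resolutions and reports the
#' number of communities found at each, to guide the choice of
#' resolution: low values recover broad populations, high values finer
#' functional states.
#'
#' @param knn An `igraph` graph from [build_knn_graph()].
#' @param resolutions Numeric grid (default `c(0.1, 0.2, 0.4, 0.8, 1.2)`).
#' @param seed Integer seed.
#' @return Tibble: `resolution`, `n_clusters`.
#' @export
sweep_resolution <- function(knn, resolutions = c(0.1, 0.2, 0.4, 0.8, 1.2),
                             seed = 1) {
  tibble::tibble(
    resolution = resolutions,
    n_clusters = vapply(resolutions, function(r) {
      length(unique(cluster_graph(knn, r, seed)))
    }, 0L))
}

#' UMAP embedding for visualization
#'
#' Two-dimensional UMAP of the corrected PCs, deterministic given
#' `seed`. The coordinates are for visualization only; no downstream
#' statistic in this package consumes them.
#'
#' @param pcs Embedding matrix (>= 10 cells).
#' @param seed Integer seed.
#' @param n_neighbors UMAP neighborhood size (default 15, capped at
#'   n - 1).
#' @return Cells x 2 coordinate matrix.
#' @export
run_umap <- function(pcs, seed = 1, n_neighbors = 15) {
  stopifnot(nrow(pcs) >= 10)
  set.seed(seed)
  nb <- min(n_neighbors, nrow(pcs) - 1)
  um <- tryCatch(
    uwot::umap(pcs, n_neighbors = nb, n_threads = 1, n_sgd_threads = 0,
               init = "spectral"),
    error = function(e) {
      set.seed(seed)
      uwot::umap(pcs, n_neighbors = nb, n_threads = 1, n_sgd_threads = 0,
                 init = "random")
    })
  rownames(um) <- rownames(pcs)
  colnames(um) <- c("UMAP1", "UMAP2")
  um
}

#' Run the full embedding pipeline
#'
#' Outlier filter, log normalization, variable features, PCA,
#' patient-level batch correction, kNN graph, Leiden clustering and UMAP
#' in one call. Clustering operates on corrected PCs, never on UMAP
#' coordinates.
#'
#' @param x A `secretome` (typically one T-cell subset; see
#'   [filter_cells()]).
#' @param config A `pipeline_config`.
#' @param batch_correct Set FALSE to skip the correction stage (e.g.
#'   single-patient data).
#' @param umap Set FALSE to skip UMAP.
#' @return An object of class `secretome_embedding`: list with `cells`
#'   (post-filter metadata tibble + `cluster` column), `normalized`,
#'   `pcs`, `corrected_pcs`, `knn`, `clusters`, `umap`, `config`,
#'   `secretome` (the filtered cohort).
#' @export
run_pipeline <- function(x, config = pipeline_config(),
                         batch_correct = TRUE, umap = TRUE) {
  stopifnot(inherits(x, "secretome"))
  xf <- filter_outlier_cells(x, config)
  norm <- normalize_log(xf, config$scale_factor)
  feats <- select_variable_features(norm, config$n_variable_features)
  pcs <- run_pca(norm[, feats, drop = FALSE], config$n_pcs,
                 seed = config$seed)
  cpcs <- if (batch_correct &&
              dplyr::n_distinct(xf$cells$patient_id) > 1) {
    correct_batch(pcs, xf$cells$patient_id, seed = config$seed)
  } else {
    pcs
  }
  knn <- build_knn_graph(cpcs, config$knn_k)
  clusters <- cluster_graph(knn, config$cluster_resolution, config$seed)
  um <- if (umap) run_umap(cpcs, config$seed) else NULL
  cells <- dplyr::mutate(
    xf$cells[, setdiff(names(xf$cells), x$panel$cytokines)],
    cluster = clusters)
  structure(list(cells = cells, normalized = norm, features = feats,
                 pcs = pcs, corrected_pcs = cpcs, knn = knn,
                 clusters = clusters, umap = um, config = config,
                 secretome = xf),
            class = "secretome_embedding")
}

#' @export
print.secretome_embedding <- function(x, ...) {
  cat("<secretome_embedding> ", nrow(x$cells), " cells, ",
      ncol(x$pcs), " PCs, ", dplyr::n_distinct(x$clusters),
      " clusters (resolution ", x$config$cluster_resolution, ")\n",
      sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
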