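#' Sample overlapping kNN neighborhoods
#'
#' Samples a fraction of cells as seeds, refines each seed to the member
#' of its kNN closest to the neighborhood's mean PC position (the
#' standard index-cell refinement), deduplicates index cells, and
#' defines each neighborhood as the index cell plus its k nearest
#' neighbors. Neighborhoods partially overlap by construction.
#'
#' @param embedding A `secretome_embedding` (uses its kNN index and
#'   corrected PCs), or an `igraph` from [build_knn_graph()] together
#'   with `pcs`.
#' @param proportion Fraction of cells sampled as seeds (default 0.1).
#' @param seed Integer seed.
#' @param pcs Corrected PC matrix; taken from `embedding` when it is a
#'   `secretome_embedding`.
#' @return An object of class `neighborhood_set`: list with
#'   `index_cells` (integer positions), `members` (list of integer
#'   vectors, index cell included), `kth_distance` (per-neighborhood kth
#'   nearest-neighbor distance of the index cell) and `cell_ids`.
#' @export
sample_neighborhoods <- function(embedding, proportion = 0.1, seed = 1,
                                 pcs = NULL) {
  if (inherits(embedding, "secretome_embedding")) {
    knn <- embedding$knn
    pcs <- embedding$corrected_pcs
  } else {
    knn <- embedding
    stopifnot(!is.null(pcs))
  }
  stopifnot(proportion > 0, proportion <= 1)
  nn_index <- igraph::graph_attr(knn, "nn_index")
  nn_dist <- igraph::graph_attr(knn, "nn_dist")
  n <- nrow(nn_index)
  k <- ncol(nn_index)
  n_seed <- ceiling(proportion * n)
  if (n_seed < 1) stop("proportion too small: no neighborhoods sampled",
                       call. = FALSE)
  set.seed(seed)
  seeds <- sample.int(n, n_seed)
  refined <- vapply(seeds, function(i) {
    mem <- c(i, nn_index[i, ])
    ctr <- colMeans(pcs[mem, , drop = FALSE])
    d2 <- rowSums(sweep(pcs[mem, , drop = FALSE], 2, ctr)^2)
    mem[which.min(d2)]   # which.min breaks ties by position, stable
  }, 0L)
  index_cells <- sort(unique(refined))
  members <- lapply(index_cells, function(i) sort(c(i, nn_index[i, ])))
  structure(list(index_cells = index_cells, members = members,
                 kth_distance = nn_dist[index_cells, k],
                 cell_ids = igraph::V(knn)$name),
            class = "neighborhood_set")
}

#' @export
print.neighborhood_set <- function(x, ...) {
  cat("<neighborhood_set> ", length(x$index_cells),
      " neighborhoods, sizes ",
      paste(range(lengths(x$members)), collapse = "-"), "\n", sep = "")
  invisible(x)
}

#' Count neighborhood members per sample
#'
#' @param nhoods A `neighborhood_set`.
#' @param cell_meta Per-cell tibble with `sample_id`, rows aligned with
#'   the cells the neighborhoods index.
#' @return Integer matrix neighborhoods x samples; row sums equal
#'   neighborhood sizes.
#' @export
count_cells <- function(nhoods, cell_meta) {
  stopifnot(inherits(nhoods, "neighborhood_set"))
  samp <- as.character(cell_meta$sample_id)
  lev <- unique(samp)
  counts <- t(vapply(nhoods$members, function(mem) {
    tabulate(match(samp[mem], lev), nbins = length(lev))
  }, integer(length(lev))))
  colnames(counts) <- lev
  counts
}

# Method-of-moments NB dispersion for one neighborhood: Pearson-style
# estimate phi with Var = mu + phi mu^2, from a Poisson fit's fitted
# values. Negative estimates (under-dispersion) floor at 0.
.mom_dispersion <- function(y, mu) {
  num <- sum((y - mu)^2 - mu)
  den <- sum(mu^2)
  max(0, num / den)
}

#' Per-neighborhood differential abundance test
#'
#' Fits, per neighborhood, a negative-binomial log-linear model
#' `count ~ timepoint` with an offset of log total cells per sample, and
#' tests the timepoint coefficient (post-IO vs baseline) with a
#' two-sided Wald z test. Dispersions are estimated by method of
#' moments and shrunk
#' halfway toward the cross-neighborhood median (stabilizing the many
#' small-count fits). Neighborhoods with all-zero counts or with cells
#' in only one timepoint arm are flagged untestable.
#'
#' @param counts Neighborhoods x samples matrix from [count_cells()].
#' @param design Tibble with `sample_id`, `timepoint` and optionally
#'   `total` (total cells per sample; computed from `counts` column
#'   sums of the full cell complement via `totals` if absent).
#' @param totals Optional named vector of total cells per sample,
#'   overriding `design$total`.
#' @param shrink Weight of the median in the dispersion shrinkage
#'   (default 0.5).
#' @return Tibble of class `da_result` rows aligned with `counts`:
#'   `nhood`, `log_fold_change` (natural log, post-IO vs baseline),
#'   `p_value`, `note`.
#' @export
test_da <- function(counts, design, totals = NULL, shrink = 0.5) {
  design <- tibble::as_tibble(design)
  stopifnot(all(colnames(counts) %in% design$sample_id))
  design <- design[match(colnames(counts), design$sample_id), ]
  tp <- factor(design$timepoint, levels = c("baseline", "post_IO"))
  if (nlevels(droplevels(tp)) < 2) {
    stop("both timepoints must be present in the design", call. = FALSE)
  }
  tot <- if (!is.null(totals)) {
    unname(totals[colnames(counts)])
  } else if ("total" %in% names(design)) {
    design$total
  } else {
    pmax(colSums(counts), 1)
  }
  off <- log(tot)
  xmat <- stats::model.matrix(~tp)

  n_nh <- nrow(counts)
  # first pass: Poisson fits for moments dispersion
  disp <- rep(NA_real_, n_nh)
  fits <- vector("list", n_nh)
  for (i in seq_len(n_nh)) {
    y <- counts[i, ]
    if (sum(y) == 0) next
    f <- suppressWarnings(stats::glm.fit(xmat, y, offset = off,
                                         family = stats::poisson()))
    fits[[i]] <- f
    disp[i] <- .mom_dispersion(y, f$fitted.values)
  }
  med <- stats::median(disp, na.rm = TRUE)
  if (!is.finite(med)) med <- 0
  disp_shrunk <- (1 - shrink) * disp + shrink * med

  out <- purrr::map_dfr(seq_len(n_nh), function(i) {
    y <- counts[i, ]
    if (sum(y) == 0) {
      return(tibble::tibble(nhood = i, log_fold_change = NA_real_,
                            p_value = NA_real_,
                            note = "untestable: all-zero counts"))
    }
    if (min(tapply(y, tp, sum)) == 0 && sum(y) < 3) {
      return(tibble::tibble(nhood = i, log_fold_change = NA_real_,
                            p_value = NA_real_,
                            note = "untestable: too few cells"))
    }
    phi <- disp_shrunk[i]
    fam <- if (phi <= 1e-8) {
      stats::poisson()
    } else {
      MASS::negative.binomial(theta = 1 / phi)
    }
    f <- suppressWarnings(stats::glm.fit(xmat, y, offset = off,
                                         family = fam))
    beta <- f$coefficients[2]
    # Wald SE from the weighted information matrix
    w <- f$weights
    xtwx <- t(xmat) %*% (xmat * w)
    cov <- tryCatch(solve(xtwx), error = function(e) NULL)
    if (is.null(cov) || !is.finite(beta)) {
      return(tibble::tibble(nhood = i, log_fold_change = unname(beta),
                            p_value = NA_real_,
                            note = "untestable: singular fit"))
    }
    se <- sqrt(cov[2, 2])
    p <- 2 * stats::pnorm(abs(beta / se), lower.tail = FALSE)
    tibble::tibble(nhood = i, log_fold_change = unname(beta),
                   se = se, p_value = p, note = NA_character_)
  })
  class(out) <- c("da_result", class(out))
  out
}

#' Spatially weighted FDR over overlapping neighborhoods
#'
#' Weighted Benjamini-Hochberg adjustment with weights proportional to
#' the reciprocal of each neighborhood's kth-nearest-neighbor distance,
#' so that dense regions (many overlapping neighborhoods) are not
#' over-penalized. With equal distances this reduces exactly to plain
#' BH. Zero distances are capped at the smallest positive distance (all
#' distances zero degrades to equal weights).
#'
#' @param p_values Numeric vector of p values (`NA` allowed, passed
#'   through).
#' @param distances Matching vector of kth-NN distances.
#' @return Vector of adjusted values in `[0, 1]`.
#' @export
spatial_fdr <- function(p_values, distances) {
  stopifnot(length(p_values) == length(distances))
  ok <- !is.na(p_values)
  p <- p_values[ok]
  d <- distances[ok]
  if (!length(p)) return(p_values)
  if (any(d <= 0)) {
    cap <- if (any(d > 0)) min(d[d > 0]) else 1
    d[d <= 0] <- cap
  }
  w <- 1 / d
  o <- order(p)
  adj <- numeric(length(p))
  adj[o] <- rev(cummin(rev(sum(w) * p[o] / cumsum(w[o]))))
  out <- p_values
  out[ok] <- pmin(adj, 1)
  out
}

#' Classify neighborhoods by timepoint exclusivity
#'
#' A neighborhood is `baseline_only` iff all its member cells come from
#' baseline samples, `post_only` iff all come from post-IO samples, and
#' `mixed` otherwise. Classification is test-free: it depends only on
#' membership and timepoints.
#'
#' @param nhoods A `neighborhood_set`.
#' @param cell_meta Per-cell tibble with `timepoint`, aligned with the
#'   indexed cells.
#' @return Character vector of labels, one per neighborhood.
#' @export
classify_exclusivity <- function(nhoods, cell_meta) {
  stopifnot(inherits(nhoods, "neighborhood_set"))
  tp <- as.character(cell_meta$timepoint)
  vapply(nhoods$members, function(mem) {
    u <- unique(tp[mem])
    if (identical(u, "baseline")) "baseline_only"
    else if (identical(u, "post_IO")) "post_only"
    else "mixed"
  }, "")
}

# one decimal, except values below 1% to two decimals
.format_pct <- function(x) ifelse(x < 1, round(x, 2), round(x, 1))

#' Summarize exclusivity classes
#'
#' Counts and percentages of baseline-only / post-only / mixed
#' neighborhoods over all neighborhoods, and separately the counts
#' restricted to spatially adjusted FDR below `fdr_threshold`.
#' Percentages are reported to one decimal place (two decimals below
#' 1%).
#'
#' @param exclusivity Character vector from [classify_exclusivity()].
#' @param spatial_fdr Optional vector of adjusted values per
#'   neighborhood for the FDR-restricted counts.
#' @param fdr_threshold Significance cut (default 0.1).
#' @return Tibble: `class`, `n`, `pct`, and (when `spatial_fdr` given)
#'   `n_fdr` restricted counts.
#' @export
summarize_exclusivity <- function(exclusivity, spatial_fdr = NULL,
                                  fdr_threshold = 0.1) {
  lev <- c("baseline_only", "post_only", "mixed")
  total <- length(exclusivity)
  n_class <- unname(vapply(lev, function(l) sum(exclusivity == l), 0L))
  out <- tibble::tibble(
    class = lev,
    n = n_class,
    pct = .format_pct(100 * n_class / total))
  if (!is.null(spatial_fdr)) {
    sig <- !is.na(spatial_fdr) & spatial_fdr < fdr_threshold
    out$n_fdr <- unname(vapply(lev, function(l)
      sum(exclusivity == l & sig), 0L))
  }
  attr(out, "total") <- total
  out
}

#' Neighborhood-level export for beeswarm plots
#'
#' Joins, per neighborhood, the cluster of its index cell with its DA
#' statistics and exclusivity label — a plotting-ready long table; no
#' computation beyond joins.
#'
#' @param da_result A `da_result` with a `spatial_fdr` column (see
#'   [run_da()]), or the bare [test_da()] output.
#' @param nhoods The matching `neighborhood_set`.
#' @param clusters Per-cell cluster labels aligned with the indexed
#'   cells.
#' @return Tibble: `nhood`, `cluster`, `log_fold_change`, `p_value`,
#'   `spatial_fdr` (if present), `exclusivity` (if present).
#' @export
beeswarm_export <- function(da_result, nhoods, clusters) {
  stopifnot(inherits(nhoods, "neighborhood_set"))
  out <- tibble::as_tibble(da_result)
  out$cluster <- clusters[nhoods$index_cells[out$nhood]]
  cols <- intersect(c("nhood", "cluster", "log_fold_change", "p_value",
                      "spatial_fdr", "exclusivity"), names(out))
  out[, cols]
}

#' Neighborhood differential abundance, end to end
#'
#' Samples neighborhoods on an embedded cohort, counts member cells per
#' sample, tests each neighborhood's abundance against timepoint,
#' applies the spatial FDR and classifies timepoint exclusivity.
#'
#' @param embedding A `secretome_embedding`.
#' @param proportion Seed-cell fraction (default 0.1).
#' @param seed Integer seed (default: the pipeline config seed).
#' @param fdr_threshold Spatial-FDR significance cut (default 0.1).
#' @return List of class `da_analysis`: `nhoods`
#'   (`neighborhood_set`), `counts`, `result` (tibble: `nhood`,
#'   `cluster`, `log_fold_change`, `p_value`, `spatial_fdr`,
#'   `exclusivity`, `note`), `summary` (from
#'   [summarize_exclusivity()]).
#' @export
run_da <- function(embedding, proportion = 0.1, seed = NULL,
                   fdr_threshold = 0.1) {
  stopifnot(inherits(embedding, "secretome_embedding"))
  if (is.null(seed)) seed <- embedding$config$seed
  cells <- embedding$cells
  nhoods <- sample_neighborhoods(embedding, proportion, seed)
  counts <- count_cells(nhoods, cells)
  totals <- table(cells$sample_id)[colnames(counts)]
  design <- dplyr::distinct(cells, .data$sample_id, .data$timepoint)
  res <- test_da(counts, design, totals = c(totals))
  res$spatial_fdr <- spatial_fdr(res$p_value, nhoods$kth_distance)
  res$exclusivity <- classify_exclusivity(nhoods, cells)
  res <- beeswarm_export(res, nhoods, embedding$clusters) |>
    dplyr::left_join(res[, c("nhood", "note")], by = "nhood")
  summ <- summarize_exclusivity(res$exclusivity, res$spatial_fdr,
                                fdr_threshold)
  structure(list(nhoods = nhoods, counts = counts, result = res,
                 summary = summ, fdr_threshold = fdr_threshold),
            class = "da_analysis")
}

#' @export
print.da_analysis <- function(x, ...) {
  cat("<da_analysis> ", nrow(x$result), " neighborhoods\n", sep = "")
  print(x$summary)
  invisible(x)
}
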