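#' Cluster-level cytokine signatures
#'
#' Per-cluster mean of the normalized MFI per cytokine, plus a per-
#' cytokine z-scored version (across clusters) and Ward-linkage
#' dendrograms over clusters and cytokines for heatmap ordering and
#' group derivation. A constant cytokine z-scores to 0 by convention; a
#' single-cluster signature has no dendrograms.
#'
#' @param embedding A `secretome_embedding`, or a per-cell cluster
#'   vector together with `normalized`.
#' @param normalized Normalized matrix; taken from `embedding` when it
#'   is a `secretome_embedding`.
#' @return An object of class `cluster_signature`: list with `means`
#'   (clusters x cytokines), `z` (row-standardized per cytokine),
#'   `row_dendrogram`, `col_dendrogram` (hclust or NULL), `n_cells`
#'   (per cluster, clusters with < 2 cells flagged in `small_clusters`).
#' @export
cluster_centroids <- function(embedding, normalized = NULL) {
  if (inherits(embedding, "secretome_embedding")) {
    clusters <- embedding$clusters
    normalized <- embedding$normalized
  } else {
    clusters <- embedding
    stopifnot(!is.null(normalized))
  }
  stopifnot(length(clusters) == nrow(normalized))
  lev <- sort(unique(clusters))
  means <- t(vapply(lev, function(cl) {
    colMeans(normalized[clusters == cl, , drop = FALSE])
  }, numeric(ncol(normalized))))
  rownames(means) <- as.character(lev)
  # Per-cytokine z across clusters, with the SD floored at the mean SD
  # over cytokines: raw z-scoring would inflate the sampling noise of
  # near-constant cytokines to the same scale as genuine signal (any
  # set of k means has SD-1 z-scores, however tiny the differences).
  sds <- apply(means, 2, stats::sd)
  sds[!is.finite(sds)] <- 0
  floor_sd <- mean(sds)
  z <- if (floor_sd > 0) {
    sweep(sweep(means, 2, colMeans(means)), 2, pmax(sds, floor_sd), "/")
  } else {
    matrix(0, nrow(means), ncol(means), dimnames = dimnames(means))
  }
  if (length(lev) == 1) z <- matrix(0, 1, ncol(means),
                                    dimnames = dimnames(means))
  rownames(z) <- rownames(means)
  row_d <- if (nrow(means) >= 2) {
    stats::hclust(stats::dist(z), method = "ward.D2")
  }
  col_d <- if (ncol(means) >= 2) {
    stats::hclust(stats::dist(t(z)), method = "ward.D2")
  }
  n_cells <- vapply(lev, function(cl) sum(clusters == cl), 0L)
  structure(list(means = means, z = z, row_dendrogram = row_d,
                 col_dendrogram = col_d, clusters = lev,
                 n_cells = n_cells,
                 small_clusters = lev[n_cells < 2]),
            class = "cluster_signature")
}

#' Derive de novo polyfunctional groups
#'
#' Cuts the cluster dendrogram of a `cluster_signature` into `k_groups`
#' branches; each branch of clusters becomes a functional group
#' (labelled G1, G2, ... in dendrogram order). A group's signature
#' cytokines are those whose group-mean z-score exceeds
#' `signature_threshold` (default +0.5). Deterministic.
#'
#' @param signature A `cluster_signature`.
#' @param k_groups Number of groups (<= number of clusters).
#' @param signature_threshold z-score above which a cytokine belongs to
#'   a group's signature.
#' @return An object of class `group_assignment`: list with `groups`
#'   (tibble `cluster`, `group`) and `signatures` (named list of
#'   character vectors).
#' @export
derive_groups <- function(signature, k_groups,
                          signature_threshold = 0.5) {
  stopifnot(inherits(signature, "cluster_signature"))
  n_cl <- length(signature$clusters)
  if (k_groups > n_cl) {
    stop("k_groups (", k_groups, ") exceeds the number of clusters (",
         n_cl, ")", call. = FALSE)
  }
  if (n_cl == 1) {
    memb <- stats::setNames(1L, rownames(signature$z))
  } else {
    memb <- stats::cutree(signature$row_dendrogram, k = k_groups)
  }
  # relabel in dendrogram (left-to-right) order for stable G1..Gk names
  ord <- if (n_cl == 1) 1L else signature$row_dendrogram$order
  first_seen <- unique(memb[ord])
  relabel <- stats::setNames(seq_along(first_seen), first_seen)
  glab <- paste0("G", relabel[as.character(memb)])
  groups <- tibble::tibble(cluster = signature$clusters,
                           group = glab)
  # group signature from the cell-weighted mean of member-cluster
  # z-profiles, so small clusters do not dominate the group's block
  w <- signature$n_cells
  names(w) <- rownames(signature$z)
  signatures <- lapply(split(names(memb), glab), function(rows) {
    zg <- colSums(signature$z[rows, , drop = FALSE] * w[rows]) /
      sum(w[rows])
    colnames(signature$z)[zg > signature_threshold]
  })
  structure(list(groups = groups, signatures = signatures,
                 k_groups = k_groups,
                 signature_threshold = signature_threshold),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat("<group_assignment> ", x$k_groups, " groups over ",
      nrow(x$groups), " clusters\n", sep = "")
  for (g in names(x$signatures)) {
    cl <- x$groups$cluster[x$groups$group == g]
    cat("  ", g, " (clusters ", paste(cl, collapse = ","),
        "): ", paste(x$signatures[[g]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Per-sample functional-group proportions
#'
#' Fraction of each sample's cells falling in the clusters of each
#' derived group. Rows sum to 1; empty samples are omitted with a
#' warning.
#'
#' @param assignment A `group_assignment`.
#' @param cells Per-cell tibble with `sample_id` and `cluster`.
#' @return Tibble: `sample_id`, one column per group, proportions
#'   summing to 1 per row.
#' @export
group_proportions <- function(assignment, cells) {
  stopifnot(inherits(assignment, "group_assignment"),
            all(c("sample_id", "cluster") %in% names(cells)))
  map <- stats::setNames(assignment$groups$group,
                         assignment$groups$cluster)
  unknown <- setdiff(unique(cells$cluster), assignment$groups$cluster)
  if (length(unknown)) {
    stop("cells reference cluster(s) outside the assignment: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  lev <- sort(unique(assignment$groups$group))
  out <- cells |>
    dplyr::mutate(group = map[as.character(.data$cluster)]) |>
    dplyr::count(.data$sample_id, .data$group) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(prop = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::select(-"n") |>
    tidyr::pivot_wider(names_from = "group", values_from = "prop",
                       values_fill = 0)
  miss <- setdiff(lev, names(out))
  for (g in miss) out[[g]] <- 0
  out[, c("sample_id", lev)]
}

#' Test group proportions against therapy response
#'
#' Per derived group within each tissue (at baseline by default):
#' two-sided Wilcoxon rank-sum test of per-sample proportions, complete
#' responders vs nonresponders; raw p and BH q within the family.
#'
#' @param proportions Tibble from [group_proportions()].
#' @param samples Per-sample metadata with `tissue`, `timepoint`,
#'   `response`.
#' @param tissue Restrict to one tissue (`NULL`: all tissues as
#'   strata).
#' @param timepoint Samples compared (default `"baseline"`).
#' @param min_per_arm Minimum samples per arm for a testable stratum.
#' @return Tibble of class `secretome_contrast`: `tissue`, `group`,
#'   `n_CR`, `n_NR`, `estimate` (median CR - median NR), `statistic`,
#'   `p_value`, `q_value`, `note`.
#' @export
compare_response <- function(proportions, samples, tissue = NULL,
                             timepoint = "baseline", min_per_arm = 2) {
  long <- proportions |>
    tidyr::pivot_longer(-"sample_id", names_to = "group",
                        values_to = "prop") |>
    dplyr::inner_join(samples, by = "sample_id") |>
    dplyr::filter(.data$timepoint == !!timepoint)
  if (!is.null(tissue)) {
    long <- long |> dplyr::filter(.data$tissue == !!tissue)
  }
  out <- long |>
    dplyr::group_by(.data$tissue, .data$group) |>
    dplyr::group_modify(function(d, g) {
      cr <- d$prop[d$response == "CR"]
      nr <- d$prop[d$response == "NR"]
      if (length(cr) < min_per_arm || length(nr) < min_per_arm) {
        return(tibble::tibble(n_CR = length(cr), n_NR = length(nr),
                              estimate = NA_real_, statistic = NA_real_,
                              p_value = NA_real_,
                              note = "untestable: insufficient samples"))
      }
      if (stats::sd(c(cr, nr)) == 0) {
        return(tibble::tibble(n_CR = length(cr), n_NR = length(nr),
                              estimate = 0, statistic = NA_real_,
                              p_value = 1,
                              note = "degenerate: constant proportions"))
      }
      ht <- stats::wilcox.test(cr, nr, exact = FALSE)
      tibble::tibble(n_CR = length(cr), n_NR = length(nr),
                     estimate = stats::median(cr) - stats::median(nr),
                     statistic = unname(ht$statistic),
                     p_value = ht$p.value, note = NA_character_)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(q_value = stats::p.adjust(.data$p_value, "BH"))
  class(out) <- c("secretome_contrast", class(out))
  attr(out, "contrast") <- "CR_vs_NR"
  attr(out, "test") <- "wilcoxon"
  out
}
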