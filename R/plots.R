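#' Boxplots of PSI by functional group
#'
#' @param psi_table A `psi_table`.
#' @param samples Optional sample metadata to facet/color by a
#'   condition column.
#' @param color_by Sample column mapped to fill (e.g. `"tissue"`),
#'   requires `samples`.
#' @return A ggplot object.
#' @export
plot_psi <- function(psi_table, samples = NULL, color_by = NULL) {
  dat <- tibble::as_tibble(psi_table)
  if (!is.null(samples)) {
    dat <- dplyr::inner_join(dat, samples, by = "sample_id")
  }
  aes <- if (is.null(color_by)) {
    ggplot2::aes(x = .data$group, y = .data$psi)
  } else {
    ggplot2::aes(x = .data$group, y = .data$psi,
                 fill = .data[[color_by]])
  }
  ggplot2::ggplot(dat, aes) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~subset) +
    ggplot2::labs(x = NULL, y = "PSI") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' UMAP scatter of an embedded cohort
#'
#' @param object A `secretome_embedding` with UMAP coordinates.
#' @param color_by Cell column mapped to color (default `"cluster"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.secretome_embedding <- function(object, color_by = "cluster",
                                         ...) {
  stopifnot(!is.null(object$umap))
  dat <- dplyr::bind_cols(object$cells,
                          tibble::as_tibble(object$umap))
  dat$cluster <- factor(dat$cluster)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$UMAP1, y = .data$UMAP2,
                                    color = .data[[color_by]])) +
    ggplot2::geom_point(size = 0.4, alpha = 0.7) +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Beeswarm-style plot of neighborhood log fold-changes by cluster
#'
#' @param da An object from [run_da()] or its tidied result tibble.
#' @param fdr_threshold Neighborhoods above this spatial FDR are drawn
#'   hollow.
#' @return A ggplot object.
#' @export
plot_da_beeswarm <- function(da, fdr_threshold = 0.1) {
  dat <- if (inherits(da, "da_analysis")) da$result else
    tibble::as_tibble(da)
  dat$cluster <- factor(dat$cluster)
  dat$significant <- !is.na(dat$spatial_fdr) &
    dat$spatial_fdr < fdr_threshold
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$cluster,
                                    y = .data$log_fold_change)) +
    ggplot2::geom_jitter(ggplot2::aes(color = .data$log_fold_change,
                                      alpha = .data$significant),
                         width = 0.25, size = 0.8) +
    ggplot2::scale_color_gradient2(low = "#b2182b", mid = "grey85",
                                   high = "#2166ac") +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.25)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(y = "log fold-change (post-IO vs baseline)",
                  x = "cluster") +
    ggplot2::theme_bw()
}

#' Heatmap of cluster-level cytokine signatures
#'
#' Tile heatmap of the z-scored cluster signature matrix, rows and
#' columns ordered by their Ward dendrograms, optionally annotated with
#' derived-group boundaries.
#'
#' @param signature A `cluster_signature`.
#' @param assignment Optional `group_assignment` for row annotation.
#' @return A ggplot object.
#' @export
plot_signature_heatmap <- function(signature, assignment = NULL) {
  stopifnot(inherits(signature, "cluster_signature"))
  z <- signature$z
  row_ord <- if (!is.null(signature$row_dendrogram)) {
    signature$row_dendrogram$order
  } else seq_len(nrow(z))
  col_ord <- if (!is.null(signature$col_dendrogram)) {
    signature$col_dendrogram$order
  } else seq_len(ncol(z))
  dat <- tibble::as_tibble(z, rownames = "cluster") |>
    tidyr::pivot_longer(-"cluster", names_to = "cytokine",
                        values_to = "z") |>
    dplyr::mutate(cluster = factor(.data$cluster,
                                   levels = rownames(z)[row_ord]),
                  cytokine = factor(.data$cytokine,
                                    levels = colnames(z)[col_ord]))
  if (!is.null(assignment)) {
    map <- stats::setNames(assignment$groups$group,
                           assignment$groups$cluster)
    dat$group <- map[as.character(dat$cluster)]
  }
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$cytokine,
                                         y = .data$cluster,
                                         fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::labs(x = NULL, y = "cluster", fill = "z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1,
                                                       vjust = 0.5))
  if (!is.null(assignment)) {
    p <- p + ggplot2::facet_grid(rows = ggplot2::vars(.data$group),
                                 scales = "free_y", space = "free_y")
  }
  p
}
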